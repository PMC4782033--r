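test_that("two-sided Fisher p agrees with exhaustive enumeration", {
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3)$p_value, 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5)$p_value, 2 / 252)
  f <- fisher_exact_two_sided(0, 5, 0, 5)
  expect_identical(f$p_value, 1)
  expect_true(f$degenerate)
  set.seed(21)
  for (i in 1:300) {
    tot <- sample(4:30, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]; c <- cuts[3] - cuts[2]
    d <- tot - cuts[3]
    got <- fisher_exact_two_sided(a, b, c, d)
    if (got$degenerate) next
    expect_equal(got$p_value, fisher_enum(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("Fisher direction tracks the proportions and row swaps", {
  f <- fisher_exact_two_sided(8, 2, 10, 40)
  expect_identical(f$direction, "over")
  g <- fisher_exact_two_sided(10, 40, 8, 2)  # rows swapped
  expect_identical(g$direction, "under")
  expect_equal(f$p_value, g$p_value)
  expect_identical(fisher_exact_two_sided(1, 9, 10, 40)$direction, "under")
  expect_identical(fisher_exact_two_sided(1, 1, 5, 5)$direction, "none")
})

test_that("M1 handles empty strata per contract", {
  maps <- list(map_of(90, 200, "histone_broad"))
  da <- locus_of(100, 130, source = "disease")
  expect_error(m1_run(da, da[0, ], maps), "empty background")
  expect_warning(r <- m1_run(da[0, ], da, maps), "empty foreground")
  expect_identical(nrow(r), 0L)
})

test_that("binomial tails match the closed forms", {
  locus <- locus_of(1000, 1030, source = "disease")
  bg <- tnr_loci("chr1", 100000 + (1:10) * 1000,
                 100000 + (1:10) * 1000 + 30, "CAG")
  # maps covering the locus always, background half the time
  maps <- lapply(1:10, function(i) {
    st <- c(locus$start - 5,
            bg$start[seq_len(5) * 2 - (i %% 2)] - 5)
    epi_map(data.frame(chrom = "chr1", start = st, end = st + 10),
            "H3K4me3", paste0("CT", i), "histone_broad")
  })
  r <- m2_run(locus, bg, maps)
  expect_identical(r$k, 10L)
  expect_identical(r$n, 10L)
  expect_equal(r$p_hat, 0.5)
  expect_equal(r$p_raw, 0.5^10)
  expect_identical(r$direction, "over")
  # lower tail by symmetry: locus never covered
  far <- locus_of(9000, 9030, source = "disease")
  r2 <- m2_run(far, bg, maps)
  expect_identical(r2$k, 0L)
  expect_equal(r2$p_raw, 0.5^10)
  expect_identical(r2$direction, "under")
})

test_that("binomial tail is monotone in k and modest at the expectation", {
  tail_at <- function(k, n, p) {
    if (k / n > p) pbinom(k - 1, n, p, lower.tail = FALSE)
    else pbinom(k, n, p)
  }
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    up <- vapply(0:20, function(k)
      pbinom(k - 1, 20, p, lower.tail = FALSE), numeric(1))
    expect_true(all(diff(up) <= 1e-12))  # non-increasing in k
    for (n in c(1, 5, 10, 25, 50, 100)) {
      expect_gt(tail_at(round(n * p), n, p), 0.05)
    }
  }
})

test_that("degenerate pooled rates are flagged", {
  locus <- locus_of(1000, 1030, source = "disease")
  bg <- tnr_loci("chr1", 100000 + (1:5) * 1000,
                 100000 + (1:5) * 1000 + 30, "CAG")
  maps <- lapply(1:4, function(i) {
    epi_map(data.frame(chrom = "chr1", start = locus$start - 5,
                       end = locus$start + 5),
            "H3K4me3", paste0("CT", i), "histone_broad")
  })
  r <- m2_run(locus, bg, maps)  # p_hat = 0 but k = 4
  expect_identical(r$p_raw, 0)
  expect_true(r$degenerate)
  expect_error(m2_run(locus, bg[0, ], maps), "empty matched background")
})

test_that("distance profiles transform and guard as specified", {
  bg <- tnr_loci("chr1", c(1000, 20000, 50000), c(1030, 20030, 50030),
                 "CAG")
  # nearest marks at center distances 9, 99, 999
  ctr <- (bg$start + bg$end) %/% 2L
  pos <- ctr + c(9L, 99L, 999L)
  map <- map_of(pos - 5, pos + 5, "histone_broad")
  prof <- build_distance_profile(bg, map)
  expect_equal(sort(prof$log_distances), c(1, 2, 3))
  expect_identical(prof$n, 3L)
  # constant distances: bandwidth falls back to the floor
  pos2 <- ctr + 99L
  prof2 <- build_distance_profile(bg, map_of(pos2 - 5, pos2 + 5,
                                             "histone_broad"))
  expect_equal(prof2$bandwidth, 1e-3)
  expect_error(build_distance_profile(bg[1, ], map),
               class = "tnr_invalid_profile")
  empty <- map_of(integer(), integer(), "histone_broad")
  expect_error(build_distance_profile(bg, empty),
               class = "tnr_invalid_profile")
})

test_that("KDE left-tail area matches quadrature and the empirical CDF", {
  # observed at the single background distance: half the mass is left
  bg <- tnr_loci("chr1", c(1000, 2000), c(1030, 2030), "CAG")
  ctr <- (bg$start + bg$end) %/% 2L
  map <- map_of(ctr + 95, ctr + 105, "histone_broad")  # distance 100
  prof <- build_distance_profile(bg, map)
  locus <- locus_of(5000, 5030)  # center 5015, mark center 5115
  map1 <- map_of(c(ctr + 95, 5110), c(ctr + 105, 5120), "histone_broad")
  r <- m3_test(locus, build_distance_profile(bg, map1), map1)
  expect_equal(r$distance, 100)
  expect_equal(r$p_left, 0.5)
  # quadrature oracle on random profiles
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(40, mean = 3, sd = 0.5)
    h <- 1.06 * sd(x) * length(x)^(-0.2)
    prof <- structure(list(log_distances = x, bandwidth = h,
                           n = length(x)), class = "distance_profile")
    x_obs <- runif(1, 1, 5)
    kde <- function(t) vapply(t, function(u)
      mean(dnorm((u - x) / h)) / h, numeric(1))
    want <- integrate(kde, -20, x_obs, rel.tol = 1e-10)$value
    got <- mean(pnorm((x_obs - x) / h))
    expect_equal(got, want, tolerance = 1e-6)
  }
  # bandwidth -> 0 recovers the empirical CDF (+ half the ties)
  x <- log10(c(9, 99, 99, 999) + 1)
  for (x_obs in c(1.5, 2, 2.5)) {
    tiny <- structure(list(log_distances = x, bandwidth = 1e-9,
                           n = length(x)), class = "distance_profile")
    want <- (sum(x < x_obs) + sum(x == x_obs) / 2) / length(x)
    expect_equal(mean(pnorm((x_obs - x) / 1e-9)), want)
  }
  # monotone in the observed value, strictly inside (0, 1)
  xs <- seq(0, 5, by = 0.25)
  prof <- structure(list(log_distances = rnorm(20, 2.5, 0.4),
                         bandwidth = 0.3, n = 20),
                    class = "distance_profile")
  ps <- vapply(xs, function(u)
    mean(pnorm((u - prof$log_distances) / prof$bandwidth)), numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_true(all(ps > 0 & ps < 1))
})

test_that("an absent observed distance yields no proximity result", {
  bg <- tnr_loci("chr1", c(1000, 2000), c(1030, 2030), "CAG")
  ctr <- (bg$start + bg$end) %/% 2L
  map <- map_of(ctr + 95, ctr + 105, "histone_broad")
  prof <- build_distance_profile(bg, map)
  off <- locus_of(100, 130, chrom = "chr9")
  expect_identical(nrow(m3_test(off, prof, map)), 0L)
})
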