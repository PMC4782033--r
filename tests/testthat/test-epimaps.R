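test_that("packaged assay metadata matches the study design", {
  md <- assay_metadata()
  expect_identical(nrow(md), 9L)
  expect_identical(sum(md$n_cell_types), 758L)
  expect_setequal(md$mark_group[md$assay %in%
                                  c("H3K4me1", "H3K4me3", "H3K9ac",
                                    "H3K27ac")], "active")
  expect_setequal(md$mark_group[md$assay %in%
                                  c("H3K9me3", "H3K27me3", "H3K36me3")],
                  "repressive")
  expect_identical(md$category[md$assay == "DNAm"], "dnam_cpg")
  expect_identical(md$category[md$assay == "DNase"],
                   "accessibility_narrow")
})

test_that("matching rules follow each assay category", {
  locus <- locus_of(100, 130)
  # broad peaks: an endpoint must fall inside the peak
  expect_true(matches_m1(locus, map_of(90, 200, "histone_broad")))
  # a peak strictly inside the repeat touches neither endpoint
  inner <- map_of(110, 120, "histone_broad")
  expect_false(matches_m1(locus, inner))
  expect_true(matches_m1(locus, inner, strict_intersection = TRUE))
  expect_true(matches_m1(locus, map_of(120, 135, "histone_broad")))
  # methylated CpG within 200 bp of an endpoint
  cpg <- map_of(300, 301, "dnam_cpg")
  expect_true(matches_m1(locus, cpg))            # gap 170
  expect_false(matches_m1(locus, cpg, dnam_window = 150))
  far <- map_of(331, 332, "dnam_cpg")            # gap 201
  expect_false(matches_m1(locus, far))
  expect_true(matches_m1(locus, far, dnam_window = 201))
  # narrow peaks: plain intersection
  expect_true(matches_m1(locus, map_of(125, 140, "accessibility_narrow")))
  expect_false(matches_m1(locus, map_of(130, 140, "accessibility_narrow")))
})

test_that("CpG matching is monotone in the window", {
  set.seed(3)
  loci <- tnr_loci("chr1", (1:50) * 1000, (1:50) * 1000 + 30, "CAG")
  sites <- sort(sample(0:60000, 40))
  map <- map_of(sites, sites + 2, "dnam_cpg")
  prev <- rep(FALSE, 50)
  for (w in c(0, 50, 100, 200, 400, 1000)) {
    cur <- matches_m1(loci, map, dnam_window = w)
    expect_true(all(prev <= cur))
    prev <- cur
  }
})

test_that("nearest-mark distances match a linear-scan oracle", {
  expect_equal(distance_to_nearest(locus_of(100, 130),
                                   map_of(200, 300, "histone_broad")), 135)
  expect_equal(distance_to_nearest(locus_of(100, 130),
                                   map_of(85, 145, "histone_broad")), 0)
  # equidistant peaks need no tie-break
  two <- map_of(c(0, 200), c(30, 230), "histone_broad")
  expect_equal(distance_to_nearest(locus_of(100, 130), two), 100)
  set.seed(11)
  for (rep in 1:20) {
    st <- sort(sample(0:100000, 50)); en <- st + sample(1:80, 50, TRUE)
    map <- map_of(st, en, "histone_broad")
    ls <- sample(0:100000, 50); le <- ls + 30
    loci <- tnr_loci("chr1", ls, le, "CAG")
    got <- distance_to_nearest(loci, map)
    # oracle works on the merged intervals the map stores
    iv <- map$intervals
    want <- vapply(seq_len(50), function(i)
      nearest_linear(ls[i], le[i], iv$start, iv$end), numeric(1))
    expect_equal(got, want)
  }
  # absent chromosome -> NA, and narrow-overlap implies bounded distance
  empty <- map_of(integer(), integer(), "histone_broad")
  expect_true(is.na(distance_to_nearest(locus_of(1, 31), empty)))
})

test_that("maps merge on load and tolerate peak-format columns", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\tp1\t100\t.\t1.5\t2.0\t-1\t5",
               "chr1\t5\t20\tp2\t200\t.\t1.5\t2.0\t-1\t5"), f)
  m <- load_map(f, "DNase")
  expect_identical(m$intervals$start, 0L)
  expect_identical(m$intervals$end, 20L)
  expect_identical(m$category, "accessibility_narrow")
  writeLines(character(), f)
  e <- load_map(f, "H3K4me3")
  expect_identical(nrow(e$intervals), 0L)
  expect_true(is.na(distance_to_nearest(locus_of(1, 31), e)))
  expect_error(load_map(f, "H3K4mysteryMark"), "unknown assay")
})

test_that("mark-group unions merge intervals and respect categories", {
  a <- map_of(0, 10, "histone_broad", assay = "H3K4me3")
  b <- map_of(5, 20, "histone_broad", assay = "H3K9ac")
  u <- mark_group_union(list(a, b))
  expect_identical(u$intervals$start, 0L)
  expect_identical(u$intervals$end, 20L)
  uu <- mark_group_union(list(a, a))
  expect_identical(uu$intervals, a$intervals)  # idempotent
  cg <- map_of(100, 102, "dnam_cpg", assay = "DNAm")
  expect_error(mark_group_union(list(a, cg)), "categories")
  b$cell_type <- "CT2"
  expect_error(mark_group_union(list(a, b)), "cell type")
})

test_that("a union can be enriched where its parts are not", {
  # foreground starts covered half by one map, half by the other
  da <- tnr_loci("chr1", (1:10) * 1000, (1:10) * 1000 + 30, "CAG",
                 source = "disease")
  bg <- tnr_loci("chr1", 50000 + (1:40) * 1000, 50000 + (1:40) * 1000 + 30,
                 "CAG")
  m1 <- map_of(da$start[1:5] - 5, da$start[1:5] + 5, "histone_broad",
               assay = "H3K4me3")
  m2 <- map_of(da$start[6:10] - 5, da$start[6:10] + 5, "histone_broad",
               assay = "H3K9ac")
  p_single <- fisher_exact_two_sided(5, 5, 0, 40)$p_value
  u <- mark_group_union(list(m1, m2))
  p_union <- fisher_exact_two_sided(sum(matches_m1(da, u)),
                                    sum(!matches_m1(da, u)), 0, 40)$p_value
  expect_true(sum(matches_m1(da, u)) == 10)
  expect_lt(p_union, p_single)
})
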