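#' Two-sided Fisher exact test on a 2x2 enrichment table
#'
#' The contingency table counts foreground (disease) repeats versus
#' background repeats that match versus do not match an epigenetic mark.
#' The two-sided p-value follows the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table.  The direction
#' is reported separately from the observed proportions.  A zero row or
#' column margin carries no evidence: p = 1, flagged degenerate.
#'
#' @param a Foreground repeats matching the mark.
#' @param b Foreground repeats not matching.
#' @param c Background repeats matching.
#' @param d Background repeats not matching.
#' @return List with `p_value`, `direction` (`"over"`, `"under"`,
#'   `"none"`), and `degenerate`.
#' @examples
#' fisher_exact_two_sided(3, 1, 1, 3)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  fg <- a + b; bg <- c + d
  direction <- if (fg == 0 || bg == 0 || a / fg == c / bg) "none"
    else if (a / fg > c / bg) "over" else "under"
  if (fg == 0 || bg == 0 || a + c == 0 || b + d == 0) {
    return(list(p_value = 1, direction = "none", degenerate = TRUE))
  }
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
  list(p_value = min(p, 1), direction = direction, degenerate = FALSE)
}

#' Per-cell-type Fisher tests on one stratum (M1)
#'
#' For one assay, runs the Fisher test independently in every cell type:
#' counts of foreground versus background repeats of one stratum that
#' match the mark under the category's matching rule.  P-values are left
#' uncorrected so trends can be read across cell types.
#'
#' @param da Foreground repeats (one stratum).
#' @param bg Background repeats (same stratum); must be non-empty.
#' @param maps List of `epi_map` objects, one per cell type, same assay.
#' @param dnam_window,strict_intersection Matching options, see
#'   [matches_m1()].
#' @param exclude_da_from_bg Drop background repeats whose coordinates
#'   coincide with a foreground repeat (default `FALSE`: the background
#'   is all repeats, not distinguishing).
#' @return Tibble with one row per cell type: counts `a`,`b`,`c`,`d`,
#'   `p_value`, `direction`, `degenerate`.
#' @export
m1_run <- function(da, bg, maps, dnam_window = 200,
                   strict_intersection = FALSE,
                   exclude_da_from_bg = FALSE) {
  if (nrow(bg) == 0L) stop("empty background stratum")
  if (exclude_da_from_bg) {
    key <- function(x) paste(x$chrom, x$start, x$end)
    bg <- bg[!key(bg) %in% key(da), ]
    if (nrow(bg) == 0L) stop("empty background stratum after exclusion")
  }
  if (nrow(da) == 0L) {
    warning("empty foreground stratum: no tests run")
    return(tibble::tibble(assay = character(), cell_type = character(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), p_value = numeric(),
                          direction = character(),
                          degenerate = logical()))
  }
  rows <- lapply(maps, function(map) {
    dm <- matches_m1(da, map, dnam_window, strict_intersection)
    bm <- matches_m1(bg, map, dnam_window, strict_intersection)
    ft <- fisher_exact_two_sided(sum(dm), sum(!dm), sum(bm), sum(!bm))
    tibble::tibble(assay = map$assay,
                   cell_type = as.character(map$cell_type),
                   a = sum(dm), b = sum(!dm), c = sum(bm), d = sum(!bm),
                   p_value = ft$p_value, direction = ft$direction,
                   degenerate = ft$degenerate)
  })
  do.call(rbind, rows)
}

#' Summarize M1 results across cell types
#'
#' @param results Output of [m1_run()] (possibly several assays bound
#'   together).
#' @param alpha Significance threshold (default 0.05).
#' @return Tibble per assay: `n_cell_types`, `pct_over`, `pct_under` —
#'   the percentage of cell types over-/under-enriched at `p <= alpha`.
#' @export
m1_summary <- function(results, alpha = 0.05) {
  out <- lapply(split(results, results$assay), function(d) {
    sig <- d$p_value <= alpha
    tibble::tibble(assay = d$assay[1], n_cell_types = nrow(d),
                   pct_over = 100 * mean(sig & d$direction == "over"),
                   pct_under = 100 * mean(sig & d$direction == "under"))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-locus binomial test pooled across cell types (M2)
#'
#' Counts the cell types in which one repeat matches the mark and
#' compares that count with the pooled background match rate — the
#' fraction of (matched background repeat, cell type) pairs that match.
#' The reported tail is the upper tail P(X >= k) when the observed rate
#' exceeds the pooled rate, otherwise the lower tail P(X <= k).
#'
#' @param locus One-row repeat locus tibble.
#' @param matched_bg Background repeats with the same unit class and an
#'   identical genic label set (see [matched_background()]); non-empty.
#' @param maps List of `epi_map` objects for one assay, one per cell
#'   type.
#' @param dnam_window Window for the CpG rule.
#' @param uniform_window If non-`NULL`, use the uniform within-window
#'   rule ([matches_within_window()]) for all categories with this
#'   window instead of the per-category rules.
#' @return One-row tibble: `assay`, `k`, `n`, `p_hat`, `p_raw`,
#'   `direction`, `degenerate`.
#' @export
m2_run <- function(locus, matched_bg, maps, dnam_window = 200,
                   uniform_window = NULL) {
  stopifnot(nrow(locus) == 1L, length(maps) >= 1L)
  if (nrow(matched_bg) == 0L) stop("empty matched background")
  match_fun <- if (is.null(uniform_window)) {
    function(x, map) matches_m1(x, map, dnam_window)
  } else {
    function(x, map) matches_within_window(x, map, uniform_window)
  }
  n <- length(maps)
  k <- sum(vapply(maps, function(m) match_fun(locus, m), logical(1)))
  bg_hits <- sum(vapply(maps, function(m) sum(match_fun(matched_bg, m)),
                        numeric(1)))
  p_hat <- bg_hits / (nrow(matched_bg) * n)
  direction <- if (k / n >= p_hat) "over" else "under"
  degenerate <- (p_hat == 0 && k > 0) || (p_hat == 1 && k < n)
  p_raw <- if (k / n > p_hat) {
    stats::pbinom(k - 1, n, p_hat, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, p_hat)
  }
  tibble::tibble(assay = maps[[1]]$assay, k = k, n = n, p_hat = p_hat,
                 p_raw = p_raw, direction = direction,
                 degenerate = degenerate)
}

#' Background distance profile for the proximity test
#'
#' Center-to-center distances from each background repeat to its nearest
#' mark, log-transformed as `log10(d + 1)` so a distance of zero maps to
#' zero, with a Gaussian-kernel bandwidth from Silverman's rule
#' `1.06 * sd(x) * n^(-1/5)` floored at `h_floor` (constant distances
#' would otherwise give a zero bandwidth).
#'
#' @param bg Background repeats (matched to the locus of interest).
#' @param map An `epi_map`.
#' @param h_floor Bandwidth floor on the log10 scale (default 1e-3).
#' @return A `distance_profile`: list with `log_distances`, `bandwidth`,
#'   `n`.  Fewer than two defined distances raise an error of class
#'   `"tnr_invalid_profile"`.
#' @export
build_distance_profile <- function(bg, map, h_floor = 1e-3) {
  d <- distance_to_nearest(bg, map)
  d <- d[!is.na(d)]
  if (length(d) < 2L) {
    stop(errorCondition(
      "distance profile needs >= 2 background repeats with defined distances",
      class = c("tnr_invalid_profile", "error", "condition")))
  }
  x <- log10(d + 1)
  h <- max(1.06 * stats::sd(x) * length(x)^(-1 / 5), h_floor)
  structure(list(log_distances = x, bandwidth = h, n = length(x)),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> n = %d, bandwidth = %.4g (log10 bp)\n",
              x$n, x$bandwidth))
  invisible(x)
}

#' Left-tail kernel-density proximity test (M3)
#'
#' Scores how unusually *close* the nearest mark is to one repeat,
#' against the kernel density estimate of background log distances.  With
#' a Gaussian kernel the area of the KDE left of the observed value has
#' the closed form `mean(pnorm((x_obs - x_i) / h))`.  Only proximity is
#' ever scored: small `p_left` means the mark is nearer than expected;
#' the right tail is never reported as significant.
#'
#' @param locus One-row repeat locus tibble.
#' @param profile A [build_distance_profile()] result.
#' @param map The `epi_map` the profile was built against.
#' @return One-row tibble: `assay`, `cell_type`, `distance`,
#'   `log_distance`, `p_left`; zero rows when the observed distance is
#'   absent.
#' @export
m3_test <- function(locus, profile, map) {
  stopifnot(nrow(locus) == 1L, inherits(profile, "distance_profile"))
  d <- distance_to_nearest(locus, map)
  if (is.na(d)) {
    return(tibble::tibble(assay = character(), cell_type = character(),
                          distance = numeric(), log_distance = numeric(),
                          p_left = numeric()))
  }
  x_obs <- log10(d + 1)
  p_left <- mean(stats::pnorm((x_obs - profile$log_distances) /
                                profile$bandwidth))
  tibble::tibble(assay = map$assay,
                 cell_type = as.character(map$cell_type),
                 distance = d, log_distance = x_obs, p_left = p_left)
}
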