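#' Load epigenetic maps listed in a manifest
#'
#' The manifest is a TSV with columns `assay`, `cell_type`, `category`
#' (optional; resolved from metadata when empty), and `path` (relative
#' paths resolved against the manifest's directory).
#'
#' @param path Manifest TSV path.
#' @param metadata Assay metadata table.
#' @return List of `epi_map` objects.
#' @export
read_map_manifest <- function(path, metadata = assay_metadata()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("assay", "cell_type", "path") %in% names(x)))
  base <- dirname(path)
  lapply(seq_len(nrow(x)), function(i) {
    p <- x$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop("map file not found: ", x$path[i])
    category <- if ("category" %in% names(x) && nzchar(x$category[i]) &&
                    !is.na(x$category[i])) x$category[i] else NULL
    load_map(p, x$assay[i], x$cell_type[i], category, metadata)
  })
}

.maps_by_assay <- function(maps) {
  split(maps, vapply(maps, `[[`, character(1), "assay"))
}

# per-cell-type unions of the maps within one mark group
.group_union_maps <- function(maps, group, label) {
  gm <- Filter(function(m) identical(m$mark_group, group), maps)
  if (length(gm) < 1L) return(list())
  by_ct <- split(gm, vapply(gm, function(m) as.character(m$cell_type),
                            character(1)))
  lapply(by_ct, function(ms) mark_group_union(ms, assay = label))
}

#' Grouped enrichment across cell types (M1) over all strata
#'
#' Runs the per-cell-type Fisher test for every assay and every stratum,
#' and additionally for the per-cell-type union of active and of
#' repressive histone marks (rows labelled `Any active` / `Any
#' repressive`).  Strata with an empty foreground or background are
#' skipped with a message.
#'
#' @param da Annotated foreground repeats.
#' @param bg Annotated background repeats.
#' @param maps List of `epi_map` objects (all assays, all cell types).
#' @param strata Tibble of strata (`unit_class`, `region`); defaults to
#'   [applicable_strata()] of the foreground.
#' @param alpha Significance threshold for summaries.
#' @param ... Matching options passed to [m1_run()].
#' @return List with `results` (per stratum/assay/cell type) and
#'   `summary` (per stratum/assay percentages, Table-style).
#' @export
run_m1_analysis <- function(da, bg, maps, strata = NULL, alpha = 0.05,
                            ...) {
  if (is.null(strata)) strata <- applicable_strata(da)
  assay_maps <- .maps_by_assay(maps)
  union_sets <- list(
    `Any active` = .group_union_maps(maps, "active", "Any active"),
    `Any repressive` = .group_union_maps(maps, "repressive",
                                         "Any repressive"))
  union_sets <- Filter(function(x) length(x) > 0, union_sets)
  all_sets <- c(assay_maps, union_sets)
  res <- list(); summ <- list()
  for (i in seq_len(nrow(strata))) {
    u <- strata$unit_class[i]; r <- strata$region[i]
    label <- paste0(u, "/", if (r == "ANY") "Any" else r)
    da_s <- stratify(da, u, r); bg_s <- stratify(bg, u, r)
    if (nrow(da_s) == 0L || nrow(bg_s) == 0L) {
      message("stratum ", label, " skipped (empty foreground or background)")
      next
    }
    for (set_name in names(all_sets)) {
      m <- m1_run(da_s, bg_s, all_sets[[set_name]], ...)
      m$assay <- set_name
      m <- tibble::add_column(m, stratum = label, n_da = nrow(da_s),
                              n_bg = nrow(bg_s), .before = 1)
      res[[length(res) + 1L]] <- m
      s <- m1_summary(m, alpha)
      s <- tibble::add_column(s, stratum = label, n_da = nrow(da_s),
                              n_bg = nrow(bg_s), .before = 1)
      summ[[length(summ) + 1L]] <- s
    }
  }
  list(results = do.call(rbind, res), summary = do.call(rbind, summ))
}

#' Per-locus binomial enrichment (M2) over a foreground set
#'
#' Runs the pooled binomial test for every (locus, assay) pair, matching
#' each locus to the background repeats with the same unit class and an
#' identical genic label set.  P-values are Bonferroni-corrected across
#' all tests run in the call, and a significance tier is attached:
#' `"strong"` (corrected p <= alpha), `"nominal"` (raw p <= alpha),
#' `"ns"` otherwise.
#'
#' @param da Annotated foreground repeats.
#' @param bg Annotated background repeats.
#' @param maps List of `epi_map` objects (all assays, all cell types).
#' @param alpha Significance threshold for tiers.
#' @param ... Options passed to [m2_run()] (e.g. `uniform_window`).
#' @return Tibble, one row per (locus, assay) tested, with `p_corrected`
#'   and `tier`; loci without matched background are skipped with a
#'   message.
#' @export
run_m2_analysis <- function(da, bg, maps, alpha = 0.05, ...) {
  assay_maps <- .maps_by_assay(maps)
  rows <- list()
  for (i in seq_len(nrow(da))) {
    locus <- da[i, ]
    mb <- matched_background(locus, bg)
    id <- if ("gene" %in% names(locus) && !is.na(locus$gene))
      locus$gene else paste0(locus$chrom, ":", locus$start)
    if (nrow(mb) == 0L) {
      message("locus ", id, " skipped (no matched background)")
      next
    }
    loc_chrom <- locus$chrom; loc_start <- locus$start
    loc_uc <- locus$unit_class
    for (assay in names(assay_maps)) {
      m <- m2_run(locus, mb, assay_maps[[assay]], ...)
      m <- tibble::add_column(m, locus = id, chrom = loc_chrom,
                              start = loc_start, unit_class = loc_uc,
                              n_matched_bg = nrow(mb), .before = 1)
      rows[[length(rows) + 1L]] <- m
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_corrected <- pmin(1, out$p_raw * nrow(out))
  out$tier <- ifelse(out$p_corrected <= alpha, "strong",
                     ifelse(out$p_raw <= alpha, "nominal", "ns"))
  out
}

#' Per-locus proximity enrichment (M3) over a foreground set
#'
#' For every (locus, map) pair, builds the kernel-density profile of
#' background log nearest-mark distances from the background repeats
#' with the same unit class and identical genic label set, and scores
#' the left-tail area at the locus's observed distance.  A result is
#' flagged significant only when proximity is enriched
#' (`p_left <= alpha`).
#'
#' @param da Annotated foreground repeats.
#' @param bg Annotated background repeats.
#' @param maps List of `epi_map` objects.
#' @param alpha Significance threshold.
#' @param h_floor Bandwidth floor, see [build_distance_profile()].
#' @return Tibble, one row per (locus, map) scored; pairs with an
#'   invalid profile or absent observed distance are skipped.
#' @export
run_m3_analysis <- function(da, bg, maps, alpha = 0.05, h_floor = 1e-3) {
  rows <- list()
  for (i in seq_len(nrow(da))) {
    locus <- da[i, ]
    mb <- matched_background(locus, bg)
    id <- if ("gene" %in% names(locus) && !is.na(locus$gene))
      locus$gene else paste0(locus$chrom, ":", locus$start)
    loc_chrom <- locus$chrom; loc_start <- locus$start
    loc_uc <- locus$unit_class
    for (map in maps) {
      prof <- tryCatch(build_distance_profile(mb, map, h_floor),
                       tnr_invalid_profile = function(e) NULL)
      if (is.null(prof)) next
      m <- m3_test(locus, prof, map)
      if (nrow(m) == 0L) next
      m <- tibble::add_column(m, locus = id, chrom = loc_chrom,
                              start = loc_start, unit_class = loc_uc,
                              n_matched_bg = prof$n, .before = 1)
      rows[[length(rows) + 1L]] <- m
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$significant <- out$p_left <= alpha
  out
}

#' Write enrichment result tables as TSV
#'
#' @param dir Output directory (created if needed).
#' @param m1 Result of [run_m1_analysis()] (optional).
#' @param m2 Result of [run_m2_analysis()] (optional).
#' @param m3 Result of [run_m3_analysis()] (optional).
#' @return Invisibly, the paths written.
#' @export
write_enrichment_tables <- function(dir, m1 = NULL, m2 = NULL,
                                    m3 = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(m1)) {
    paths <- c(paths, w(m1$results, "m1_results.tsv"),
               w(m1$summary, "m1_summary.tsv"))
  }
  if (!is.null(m2)) paths <- c(paths, w(m2, "m2_results.tsv"))
  if (!is.null(m3)) paths <- c(paths, w(m3, "m3_results.tsv"))
  invisible(paths)
}
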