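#' Assay metadata
#'
#' The packaged metadata table lists the nine genome-wide assays used in
#' the analysis, the number of cell types each was profiled in (758 maps
#' in total), the mark group used for report sections and unions (active,
#' repressive, dnam, accessibility), and the matching-rule category:
#' `histone_broad` (a repeat matches when its start or end point falls
#' inside a broad peak), `dnam_cpg` (an endpoint within 200 bp of a
#' methylated CpG), or `accessibility_narrow` (any overlap with a narrow
#' peak).
#'
#' @param path Optional path to an alternative metadata TSV.
#' @return Tibble with columns `assay`, `description`, `n_cell_types`,
#'   `mark_group`, `category`.
#' @examples
#' assay_metadata()
#' @export
assay_metadata <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "assay_metadata.tsv",
                        package = "tnrenrich", mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

.MAP_CATEGORIES <- c("histone_broad", "dnam_cpg", "accessibility_narrow")

.merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    tibble::tibble(chrom = d$chrom[1],
                   start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Construct an epigenetic map
#'
#' One map holds the called intervals for one (assay, cell type) pair.
#' Overlapping input intervals are merged, so the stored intervals are
#' sorted and disjoint per chromosome.  The matching-rule category is
#' resolved from the assay metadata unless given explicitly.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).  CpG sites are width-1 or width-2 intervals.
#' @param assay Assay name (e.g. `"H3K4me3"`).
#' @param cell_type Cell type label.
#' @param category One of `"histone_broad"`, `"dnam_cpg"`,
#'   `"accessibility_narrow"`; looked up from `metadata` when `NULL`.
#' @param metadata Metadata table, see [assay_metadata()].
#' @return An object of class `epi_map`.
#' @export
epi_map <- function(intervals, assay, cell_type = NA_character_,
                    category = NULL, metadata = assay_metadata()) {
  mark_group <- NA_character_
  if (is.null(category)) {
    row <- metadata[metadata$assay == assay, ]
    if (nrow(row) == 0L) {
      stop("unknown assay '", assay, "'; supply category explicitly")
    }
    category <- row$category[1]
    mark_group <- row$mark_group[1]
  } else if (assay %in% metadata$assay) {
    mark_group <- metadata$mark_group[metadata$assay == assay][1]
  }
  category <- match.arg(category, .MAP_CATEGORIES)
  intervals <- tibble::tibble(chrom = as.character(intervals$chrom),
                              start = as.integer(intervals$start),
                              end = as.integer(intervals$end))
  stopifnot(all(intervals$end > intervals$start))
  structure(list(assay = assay, cell_type = cell_type,
                 category = category, mark_group = mark_group,
                 intervals = .merge_intervals(intervals)),
            class = "epi_map")
}

#' @export
print.epi_map <- function(x, ...) {
  cat(sprintf("<epi_map> %s / %s [%s]: %d interval(s) on %d chromosome(s)\n",
              x$assay, x$cell_type, x$category, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Load an epigenetic map from a BED-style file
#'
#' Accepts BED3 and ENCODE broadPeak/narrowPeak (columns beyond the
#' coordinates are ignored); `track`/`browser`/comment lines are skipped.
#' An empty file yields a valid map with zero intervals.
#'
#' @inheritParams epi_map
#' @param path File path.
#' @return An `epi_map`.
#' @export
load_map <- function(path, assay, cell_type = NA_character_,
                     category = NULL, metadata = assay_metadata()) {
  lines <- .strip_bed_comments(readLines(path))
  if (length(lines) == 0L) {
    iv <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    iv <- tibble::tibble(
      chrom = vapply(fields, `[`, character(1), 1L),
      start = as.integer(vapply(fields, `[`, character(1), 2L)),
      end = as.integer(vapply(fields, `[`, character(1), 3L)))
  }
  epi_map(iv, assay, cell_type, category, metadata)
}

# per-chromosome interval vectors for fast point queries
.map_chrom <- function(map, chrom) {
  iv <- map$intervals
  iv[iv$chrom == chrom, ]
}

# distance (bases between) from 0-based point p to sorted disjoint
# intervals; 0 when inside; Inf when none
.point_gap <- function(p, st, en) {
  n <- length(st)
  if (n == 0L) return(rep(Inf, length(p)))
  idx <- findInterval(p, st)
  inside <- idx > 0L & p < en[pmax(idx, 1L)]
  left <- ifelse(idx > 0L, p - en[pmax(idx, 1L)], Inf)
  right <- ifelse(idx < n, st[pmin(idx + 1L, n)] - p - 1, Inf)
  out <- pmin(pmax(left, 0), pmax(right, 0))
  out[inside] <- 0
  out
}

.any_overlap <- function(s, e, st, en) {
  n <- length(st)
  if (n == 0L) return(rep(FALSE, length(s)))
  j <- findInterval(s, en) + 1L  # first interval ending after s
  j <= n & st[pmin(j, n)] < e
}

#' Category-specific repeat/mark matching
#'
#' Applies the matching rule of the map's category to each locus:
#' * `histone_broad` — the repeat's start point or end point (its last
#'   base) lies inside a peak.  Taken literally, a peak strictly inside a
#'   long repeat does *not* match; set `strict_intersection = TRUE` for a
#'   plain overlap rule instead.
#' * `dnam_cpg` — the start or end point is within `dnam_window` bases of
#'   a methylated CpG (gap counted as bases between point and site).
#' * `accessibility_narrow` — any interval intersects the repeat.
#'
#' @param loci Repeat locus tibble.
#' @param map An `epi_map`.
#' @param dnam_window Window in bp for the CpG rule (default 200).
#' @param strict_intersection Replace the endpoint rule for broad peaks
#'   with plain intersection (default `FALSE`).
#' @return Logical vector, one element per locus.
#' @export
matches_m1 <- function(loci, map, dnam_window = 200,
                       strict_intersection = FALSE) {
  out <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    iv <- .map_chrom(map, ch)
    st <- iv$start; en <- iv$end
    s <- loci$start[sel]; e <- loci$end[sel]
    out[sel] <- switch(
      map$category,
      histone_broad = if (strict_intersection) {
        .any_overlap(s, e, st, en)
      } else {
        .point_gap(s, st, en) == 0 | .point_gap(e - 1L, st, en) == 0
      },
      dnam_cpg = pmin(.point_gap(s, st, en),
                      .point_gap(e - 1L, st, en)) <= dnam_window,
      accessibility_narrow = .any_overlap(s, e, st, en))
  }
  out
}

#' Uniform within-window matching
#'
#' The alternative matching rule in which, for every assay category, a
#' repeat matches when its start or end point is within `window` bases of
#' an interval (used by the optional uniform-window mode of the per-locus
#' binomial test).
#'
#' @inheritParams matches_m1
#' @param window Window in bp.
#' @return Logical vector, one element per locus.
#' @export
matches_within_window <- function(loci, map, window = 200) {
  out <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    iv <- .map_chrom(map, ch)
    out[sel] <- pmin(.point_gap(loci$start[sel], iv$start, iv$end),
                     .point_gap(loci$end[sel] - 1L, iv$start, iv$end)) <=
      window
  }
  out
}

#' Center-to-center distance to the nearest mark
#'
#' Distance from the center of each repeat to the center of the closest
#' interval on the same chromosome, with centers defined as
#' `floor((start + end) / 2)`.  `NA` (absent) when the chromosome carries
#' no intervals.
#'
#' @inheritParams matches_m1
#' @return Numeric vector of distances in bp; `NA` where absent.
#' @export
distance_to_nearest <- function(loci, map) {
  out <- rep(NA_real_, nrow(loci))
  for (ch in unique(loci$chrom)) {
    sel <- loci$chrom == ch
    iv <- .map_chrom(map, ch)
    if (nrow(iv) == 0L) next
    ctr <- (iv$start + iv$end) %/% 2L  # sorted: intervals are disjoint
    p <- (loci$start[sel] + loci$end[sel]) %/% 2L
    idx <- findInterval(p, ctr)
    n <- length(ctr)
    left <- ifelse(idx > 0L, p - ctr[pmax(idx, 1L)], Inf)
    right <- ifelse(idx < n, ctr[pmin(idx + 1L, n)] - p, Inf)
    out[sel] <- pmin(left, right)
  }
  out
}

#' Union of several maps for one cell type
#'
#' Builds the virtual map whose intervals are the union of the input
#' maps' intervals — used to score a whole mark group (e.g. all active
#' histone marks) at once.  All maps must come from the same cell type
#' and share a category; mixing CpG-site maps with peak maps is rejected.
#'
#' @param maps List of `epi_map` objects.
#' @param assay Label for the combined map (default joins the input
#'   assay names).
#' @return An `epi_map`.
#' @export
mark_group_union <- function(maps, assay = NULL) {
  stopifnot(length(maps) >= 1L)
  ct <- unique(vapply(maps, function(m) as.character(m$cell_type),
                      character(1)))
  if (length(ct) != 1L) stop("maps must share one cell type")
  cats <- unique(vapply(maps, `[[`, character(1), "category"))
  if (length(cats) != 1L) {
    stop("cannot union maps of different categories (",
         paste(cats, collapse = ", "), ")")
  }
  if (is.null(assay)) {
    assay <- paste(unique(vapply(maps, `[[`, character(1), "assay")),
                   collapse = "+")
  }
  groups <- unique(vapply(maps, `[[`, character(1), "mark_group"))
  iv <- do.call(rbind, lapply(maps, `[[`, "intervals"))
  out <- epi_map(iv, assay, ct, category = cats)
  out$mark_group <- if (length(groups) == 1L) groups else NA_character_
  out
}
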