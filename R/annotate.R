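#' Gene models
#'
#' A gene model is a tibble of transcripts with 0-based half-open
#' coordinates: `name`, `chrom`, `strand` (`"+"`/`"-"`), `tx_start`,
#' `tx_end`, `cds_start`, `cds_end`, and list-columns `exon_starts` /
#' `exon_ends` holding the sorted, disjoint exon blocks.  Genic regions
#' are derived from it as: coding exon = exon sequence inside the CDS;
#' 5'/3' UTR = exon sequence outside the CDS on the strand-appropriate
#' side; intron = gaps between exon blocks.
#'
#' @name gene-model
NULL

.validate_gene_model <- function(gm) {
  need <- c("name", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_starts", "exon_ends")
  stopifnot(all(need %in% names(gm)))
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es) ||
        is.unsorted(es, strictly = TRUE) ||
        any(es[-1] < ee[-length(ee)]) ||
        es[1] < gm$tx_start[i] || ee[length(ee)] > gm$tx_end[i]) {
      stop("invalid exon blocks in transcript ", gm$name[i])
    }
    if (gm$cds_start[i] > gm$cds_end[i] ||
        gm$cds_start[i] < gm$tx_start[i] || gm$cds_end[i] > gm$tx_end[i]) {
      stop("invalid CDS bounds in transcript ", gm$name[i])
    }
  }
  gm
}

#' Read a gene model from the tabular dialect
#'
#' Columns: `name chrom strand tx_start tx_end cds_start cds_end
#' exon_starts exon_ends`, exon blocks comma-separated, all coordinates
#' 0-based half-open.
#'
#' @param path TSV path.
#' @return A gene-model tibble (see [gene-model]).
#' @export
read_gene_model <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  gm <- tibble::tibble(
    name = as.character(x$name), chrom = x$chrom, strand = x$strand,
    tx_start = as.integer(x$tx_start), tx_end = as.integer(x$tx_end),
    cds_start = as.integer(x$cds_start), cds_end = as.integer(x$cds_end),
    exon_starts = lapply(strsplit(as.character(x$exon_starts), ","),
                         as.integer),
    exon_ends = lapply(strsplit(as.character(x$exon_ends), ","),
                       as.integer))
  .validate_gene_model(gm)
}

#' Write a gene model in the tabular dialect
#'
#' @param gm Gene-model tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_model <- function(gm, path) {
  df <- data.frame(
    name = gm$name, chrom = gm$chrom, strand = gm$strand,
    tx_start = gm$tx_start, tx_end = gm$tx_end,
    cds_start = gm$cds_start, cds_end = gm$cds_end,
    exon_starts = vapply(gm$exon_starts, paste, character(1),
                         collapse = ","),
    exon_ends = vapply(gm$exon_ends, paste, character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene model from BED12
#'
#' Uses `rtracklayer` to parse BED12; `thickStart`/`thickEnd` are taken
#' as the CDS.
#'
#' @param path BED12 path.
#' @return A gene-model tibble (see [gene-model]).
#' @export
read_gene_model_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks)) stop("not a BED12 file (no block definitions)")
  tx_start <- GenomicRanges::start(gr) - 1L
  tx_end <- GenomicRanges::end(gr)
  thick <- gr$thick
  gm <- tibble::tibble(
    name = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    tx_start = tx_start,
    tx_end = tx_end,
    cds_start = IRanges::start(thick) - 1L,
    cds_end = IRanges::end(thick),
    # blocks are relative to the transcript start (1-based)
    exon_starts = lapply(seq_along(gr), function(i)
      tx_start[i] + IRanges::start(gr$blocks[[i]]) - 1L),
    exon_ends = lapply(seq_along(gr), function(i)
      tx_start[i] + IRanges::end(gr$blocks[[i]])))
  gm$strand[!gm$strand %in% c("+", "-")] <- "+"
  # BED12 encodes "no CDS" as thickStart == thickEnd (width-0 thick)
  .validate_gene_model(gm)
}

# region intervals (0-based half-open) for one transcript row
.transcript_regions <- function(tx) {
  es <- tx$exon_starts[[1]]; ee <- tx$exon_ends[[1]]
  cs <- tx$cds_start; ce <- tx$cds_end
  clip <- function(lo, hi) {
    s <- pmax(es, lo); e <- pmin(ee, hi)
    keep <- e > s
    cbind(s[keep], e[keep])
  }
  n <- length(es)
  introns <- if (n > 1L) cbind(ee[-n], es[-1]) else
    matrix(numeric(), ncol = 2)
  introns <- introns[introns[, 2] > introns[, 1], , drop = FALSE]
  if (ce > cs) {
    coding <- clip(cs, ce)
    left <- clip(tx$tx_start, cs)
    right <- clip(ce, tx$tx_end)
  } else {
    # non-coding transcript: no coding exon or UTR labels
    coding <- matrix(numeric(), ncol = 2)
    left <- right <- matrix(numeric(), ncol = 2)
  }
  if (identical(tx$strand, "-")) {
    list(exon = coding, utr5 = right, utr3 = left, intron = introns)
  } else {
    list(exon = coding, utr5 = left, utr3 = right, intron = introns)
  }
}

.overlaps_set <- function(s, e, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(s)))
  vapply(seq_along(s), function(i)
    any(iv[, 1] < e[i] & iv[, 2] > s[i]), logical(1))
}

#' Annotate repeat loci with genic regions
#'
#' Labels each locus with the genic regions it overlaps: `exon` (coding
#' exon sequence), `utr5`/`utr3` (exonic sequence outside the CDS,
#' strand-aware), and `intron` (gaps between exon blocks).  Labels
#' accumulate over all overlapping transcripts, so a locus can carry
#' several labels (e.g. spanning an exon/intron junction, or annotated
#' differently by two transcripts).  Loci on chromosomes absent from the
#' model get an empty label set (reported via `message()`).  Non-coding
#' transcripts (zero-width CDS) contribute intron labels only.
#'
#' @param loci Repeat locus tibble.
#' @param model Gene-model tibble (see [gene-model]).
#' @return `loci` with logical columns `exon`, `intron`, `utr5`, `utr3`.
#' @export
annotate_loci <- function(loci, model) {
  n <- nrow(loci)
  lab <- matrix(FALSE, n, 4,
                dimnames = list(NULL, c("exon", "intron", "utr5", "utr3")))
  off_model <- !loci$chrom %in% model$chrom
  if (any(off_model)) {
    message(sum(off_model),
            " locus/loci on chromosome(s) absent from the gene model")
  }
  for (i in seq_len(nrow(model))) {
    tx <- model[i, ]
    sel <- which(loci$chrom == tx$chrom & loci$start < tx$tx_end &
                   loci$end > tx$tx_start)
    if (length(sel) == 0L) next
    reg <- .transcript_regions(tx)
    for (r in names(reg)) {
      hit <- .overlaps_set(loci$start[sel], loci$end[sel], reg[[r]])
      lab[sel[hit], r] <- TRUE
    }
  }
  loci$exon <- lab[, "exon"]; loci$intron <- lab[, "intron"]
  loci$utr5 <- lab[, "utr5"]; loci$utr3 <- lab[, "utr3"]
  loci
}

.REGIONS <- c("exon", "intron", "utr5", "utr3")

#' Select the repeats in one stratum
#'
#' A stratum fixes the repeat-unit class, the genic region, or both
#' (`"ANY"` matches everything on that axis; at least one axis must be
#' constrained).  Membership is by label, not partition: a multi-labelled
#' locus belongs to every applicable stratum.
#'
#' @param loci Annotated repeat locus tibble.
#' @param unit_class Canonical class label or `"ANY"`.
#' @param region One of `"exon"`, `"intron"`, `"utr5"`, `"utr3"`, or
#'   `"ANY"`.
#' @return The matching subset of `loci`.
#' @examples
#' stratify(load_catalog(), unit_class = "CAG")
#' @export
stratify <- function(loci, unit_class = "ANY", region = "ANY") {
  if (identical(unit_class, "ANY") && identical(region, "ANY")) {
    stop(errorCondition("a stratum must constrain at least one axis",
                        class = c("tnr_invalid_stratum", "error",
                                  "condition")))
  }
  keep <- rep(TRUE, nrow(loci))
  if (!identical(unit_class, "ANY")) {
    keep <- keep & loci$unit_class %in% unit_class
  }
  if (!identical(region, "ANY")) {
    region <- match.arg(region, .REGIONS)
    keep <- keep & loci[[region]] %in% TRUE
  }
  loci[keep, ]
}

#' Strata applicable to a foreground set
#'
#' Enumerates the single-axis strata (each region with any class, each
#' class with any region) and the class-by-region combinations populated
#' by at least one foreground locus.
#'
#' @param da Annotated repeat locus tibble (foreground).
#' @return Tibble with columns `unit_class`, `region`, `n_da`.
#' @export
applicable_strata <- function(da) {
  rows <- list()
  for (r in .REGIONS) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(unit_class = "ANY", region = r,
                     n_da = sum(da[[r]] %in% TRUE))
  }
  for (u in sort(unique(da$unit_class))) {
    rows[[length(rows) + 1L]] <-
      tibble::tibble(unit_class = u, region = "ANY",
                     n_da = sum(da$unit_class == u))
    for (r in .REGIONS) {
      n <- sum(da$unit_class == u & da[[r]] %in% TRUE)
      if (n > 0) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(unit_class = u, region = r, n_da = n)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[out$n_da > 0, ]
}

#' Background repeats matched to one locus
#'
#' Returns the background repeats with the same unit class and an
#' *identical* genic label set as the query locus — the matching used by
#' the per-locus tests (M2 and the distance profiles of M3).
#'
#' @param locus One-row repeat locus tibble (annotated).
#' @param bg Annotated background repeat tibble.
#' @return The matching subset of `bg`.
#' @export
matched_background <- function(locus, bg) {
  stopifnot(nrow(locus) == 1L)
  keep <- bg$unit_class == locus$unit_class
  for (r in .REGIONS) keep <- keep & (bg[[r]] %in% TRUE) ==
      (locus[[r]] %in% TRUE)
  bg[keep, ]
}
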