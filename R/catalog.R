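#' Repeat locus tables
#'
#' Repeat loci are kept in plain tibbles with 0-based half-open coordinates
#' and one row per tract: `chrom`, `start`, `end`, `unit_class` (canonical
#' class label, see [canonical_unit()]), `unit_count`, `source`
#' (`"disease"` or `"background"`), and optionally `gene`, `disease`,
#' `disease_id` plus the genic-region flags `exon`, `intron`, `utr5`,
#' `utr3` filled by [annotate_loci()] or loaded with the packaged catalog.
#'
#' @name tnr-loci
NULL

.loci_core_cols <- c("chrom", "start", "end", "unit_class", "unit_count",
                     "source")

.empty_loci <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 unit_class = character(), unit_count = integer(),
                 source = character())
}

#' Build a repeat locus table
#'
#' Convenience constructor used in examples and simulations.
#'
#' @param chrom,start,end Coordinates (0-based half-open).
#' @param unit Repeat unit as written in the sequence; canonicalized.
#' @param source `"disease"` or `"background"`.
#' @return A repeat locus tibble (see [tnr-loci]).
#' @export
tnr_loci <- function(chrom, start, end, unit, source = "background") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(all(end > start))
  tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                 unit_class = canonical_unit(unit),
                 unit_count = (end - start) %/% 3L,
                 source = source)
}

#' Load the disease-associated repeat catalog
#'
#' Reads the packaged catalog of 32 disease-associated tri-nucleotide
#' repeat loci (hg19).  The shipped table records 1-based start positions
#' and repeat-unit counts; coordinates are converted to the internal
#' 0-based half-open convention with `end = start + 3 * unit_count`.
#' Genic-region flags (`exon`, `intron`, `utr5`, `utr3`) are part of the
#' curated record.
#'
#' @param path Path to a catalog TSV; defaults to the packaged file.
#' @return A repeat locus tibble with `source = "disease"`, 32 rows for
#'   the packaged catalog.
#' @examples
#' cat32 <- load_catalog()
#' table(cat32$unit_class)
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "da_tnr_catalog.tsv",
                        package = "tnrenrich", mustWork = TRUE)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("disease", "disease_id", "gene", "chrom", "pos_1based", "unit",
            "unit_count", "exon", "intron", "utr5", "utr3")
  if (!all(need %in% names(x))) {
    stop("malformed catalog file: missing column(s) ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  if (any(!is.finite(x$pos_1based)) || any(x$pos_1based < 1) ||
      any(!is.finite(x$unit_count)) || any(x$unit_count < 1)) {
    stop("malformed catalog file: bad coordinates or unit counts")
  }
  start <- as.integer(x$pos_1based) - 1L
  tibble::tibble(
    chrom = x$chrom,
    start = start,
    end = start + 3L * as.integer(x$unit_count),
    unit_class = canonical_unit(x$unit),
    unit_count = as.integer(x$unit_count),
    source = "disease",
    gene = x$gene,
    disease = x$disease,
    disease_id = x$disease_id,
    exon = x$exon == 1,
    intron = x$intron == 1,
    utr5 = x$utr5 == 1,
    utr3 = x$utr3 == 1)
}

.strip_bed_comments <- function(lines) {
  lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
}

#' Read repeat loci from a BED file
#'
#' Accepts BED3+; a fourth (name) column, when present, is interpreted as
#' the repeat unit and canonicalized.  Extra columns are ignored.  Records
#' with non-numeric coordinates or `start >= end` are hard errors reported
#' with their line numbers.
#'
#' @param path BED file path.
#' @param source Value for the `source` column (default `"background"`).
#' @return A repeat locus tibble.
#' @export
read_tnr_bed <- function(path, source = "background") {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(.empty_loci())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- ncol < 3L
  start <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))))
  end <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 3) f[3] else NA_character_, character(1))))
  bad <- bad | is.na(start) | is.na(end) | start >= end | start < 0
  if (any(bad)) {
    stop("invalid BED record(s) at line(s) ",
         paste(lineno[bad], collapse = ", "),
         " (need >=3 columns, numeric coordinates, start < end)")
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  name <- vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, character(1))
  unit_class <- rep(NA_character_, length(name))
  has_name <- !is.na(name)
  if (any(has_name)) unit_class[has_name] <- canonical_unit(name[has_name])
  out <- tibble::tibble(chrom = chrom, start = start, end = end,
                        unit_class = unit_class,
                        unit_count = (end - start) %/% 3L,
                        source = source)
  out[order(out$chrom, out$start), ]
}

#' Write repeat loci as BED4
#'
#' The name field carries the canonical unit-class label, so a write/read
#' round trip is the identity on `(chrom, start, end, unit_class)`.
#'
#' @param loci Repeat locus tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tnr_bed <- function(loci, path) {
  stopifnot(all(c("chrom", "start", "end", "unit_class") %in% names(loci)))
  df <- data.frame(loci$chrom, loci$start, loci$end, loci$unit_class)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
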