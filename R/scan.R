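#' Scanner configuration
#'
#' The background repeat set is built by scanning genome sequence for
#' maximal perfect tri-nucleotide tandem tracts.  The default threshold of
#' 6 repeat units matches the convention for genome-wide triplet repeat
#' surveys; the `"zipseq"` preset lowers it to 3 units, the sensitivity of
#' experimentally determined CAG-repeat databases.
#'
#' @param min_units Minimum number of full repeat units (>= 2).
#' @param allow_interruptions Must be `FALSE`; only perfect tracts are
#'   modelled (externally produced repeat calls with interruptions can be
#'   brought in via [import_background()]).
#' @param preset Optional preset name, `"zipseq"` sets `min_units = 3`.
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_units = 6L, allow_interruptions = FALSE,
                        preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "zipseq")
    min_units <- 3L
  }
  min_units <- as.integer(min_units)
  if (is.na(min_units) || min_units < 2L) stop("min_units must be >= 2")
  if (isTRUE(allow_interruptions)) {
    stop("interrupted tracts are not modelled; import external calls ",
         "with import_background()")
  }
  structure(list(min_units = min_units, allow_interruptions = FALSE),
            class = "scan_config")
}

#' Scan a sequence for perfect tri-nucleotide tandem tracts
#'
#' Finds every maximal run of `>= min_units` consecutive copies of one
#' triplet.  A tract is anchored at its leftmost full unit and trailing
#' partial units are excluded, so `end - start == 3 * unit_count` exactly.
#' Homopolymer runs are excluded (they are mononucleotide repeats), and
#' `N` bases terminate tracts.
#'
#' @param seq DNA sequence as a single string (or anything coercible via
#'   `as.character`, e.g. a `DNAString`).
#' @param chrom Chromosome name to record.
#' @param cfg A [scan_config()].
#' @return A repeat locus tibble with `source = "background"`, sorted by
#'   position.
#' @examples
#' scan_sequence("ACAGCAGCAGCAGCAGCAGT", "chr1")
#' @export
scan_sequence <- function(seq, chrom = "chr1", cfg = scan_config()) {
  s <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  L <- length(s)
  if (L < 3L * cfg$min_units) return(.empty_loci())
  ok <- s %in% .DNA_BASES
  # period-3 self-match; a run of TRUEs of length r spans a tract of
  # r + 3 bases
  m <- s[1:(L - 3L)] == s[4:L] & ok[1:(L - 3L)] & ok[4:L]
  r <- rle(m)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  want <- r$values & r$lengths >= 3L * cfg$min_units - 3L
  if (!any(want)) return(.empty_loci())
  a <- run_start[want]
  len <- r$lengths[want] + 3L
  units <- len %/% 3L
  unit <- paste0(s[a], s[a + 1L], s[a + 2L])
  keep <- !.is_homopolymer(unit)
  if (!any(keep)) return(.empty_loci())
  a <- a[keep]; units <- units[keep]; unit <- unit[keep]
  tibble::tibble(chrom = chrom,
                 start = a - 1L,
                 end = a - 1L + 3L * units,
                 unit_class = canonical_unit(unit),
                 unit_count = units,
                 source = "background")
}

#' Scan a multi-record FASTA file
#'
#' @param path FASTA path.
#' @param cfg A [scan_config()].
#' @return A repeat locus tibble covering all records; record names are
#'   truncated at the first whitespace.
#' @export
scan_fasta <- function(path, cfg = scan_config()) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs), function(i) {
    scan_sequence(as.character(seqs[[i]]), names(seqs)[i], cfg)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), ]
}

#' Import externally produced background repeats from BED
#'
#' For repeat calls made by external tools (e.g. Tandem Repeats Finder or
#' experimentally determined repeat databases) exported as BED with the
#' repeat unit in the name column.  Units are canonicalized; records whose
#' unit count (tract width / 3) falls below `cfg$min_units` are dropped,
#' and records with a missing or invalid unit name are skipped; both
#' counts are reported via `message()`.
#'
#' @param path BED file path.
#' @param cfg A [scan_config()].
#' @return A repeat locus tibble with `source = "background"`.
#' @export
import_background <- function(path, cfg = scan_config()) {
  lines <- .strip_bed_comments(readLines(path))
  if (length(lines) == 0L) {
    warning("empty background BED: ", path)
    return(.empty_loci())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 2) f[2] else NA_character_, character(1))))
  end <- suppressWarnings(as.integer(vapply(fields, function(f)
    if (length(f) >= 3) f[3] else NA_character_, character(1))))
  name <- toupper(vapply(fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, character(1)))
  valid_coord <- !is.na(start) & !is.na(end) & start < end & start >= 0
  valid_name <- !is.na(name) & grepl("^[ACGT]{3}$", name) &
    !.is_homopolymer(ifelse(is.na(name), "NNN", name))
  skipped <- sum(!(valid_coord & valid_name))
  if (skipped > 0) {
    message(skipped, " record(s) skipped (invalid coordinates or unit name)")
  }
  keep <- valid_coord & valid_name
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  name <- name[keep]
  units <- (end - start) %/% 3L
  short <- units < cfg$min_units
  if (any(short)) {
    message(sum(short), " record(s) dropped below min_units = ",
            cfg$min_units)
  }
  out <- tibble::tibble(chrom = chrom[!short], start = start[!short],
                        end = end[!short],
                        unit_class = if (any(!short))
                          canonical_unit(name[!short]) else character(),
                        unit_count = units[!short],
                        source = "background")
  out[order(out$chrom, out$start), ]
}
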