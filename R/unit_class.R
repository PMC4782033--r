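#' Canonical tri-nucleotide repeat unit classes
#'
#' A tandem repeat of period three can be written six ways: three cyclic
#' rotations of the unit on the given strand, and three rotations of its
#' reverse complement.  All six describe the same genomic tract, so repeat
#' units are classified into equivalence classes under rotation and reverse
#' complement.  Homopolymer triplets (AAA, CCC, GGG, TTT) describe
#' mononucleotide runs and are excluded; the remaining 60 triplets fall into
#' exactly 10 classes of 6 members each.
#'
#' Four of the ten classes cover all known disease-associated loci and carry
#' their conventional labels (CAG, GCG, GAA, GAC); the other six are labelled
#' by the lexicographically smallest member.
#'
#' @name unit-classes
NULL

.DNA_BASES <- c("A", "C", "G", "T")

# conventional labels for the four disease classes, keyed by canonical
# (lexicographically minimal) member
.PAPER_LABELS <- c(AGC = "CAG", CCG = "GCG", AAG = "GAA", ACG = "GAC")

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.rotations <- function(t) {
  c(t,
    paste0(substr(t, 2, 3), substr(t, 1, 1)),
    paste0(substr(t, 3, 3), substr(t, 1, 2)))
}

.is_homopolymer <- function(t) {
  substr(t, 1, 1) == substr(t, 2, 2) & substr(t, 2, 2) == substr(t, 3, 3)
}

.validate_triplet <- function(triplet) {
  bad <- nchar(triplet) != 3 |
    !grepl("^[ACGT]{3}$", triplet)
  if (any(bad)) {
    stop(errorCondition(
      sprintf("not a DNA triplet over {A,C,G,T}: %s",
              paste(unique(triplet[bad]), collapse = ", ")),
      class = c("tnr_invalid_triplet", "error", "condition")))
  }
  homo <- .is_homopolymer(triplet)
  if (any(homo)) {
    stop(errorCondition(
      sprintf("homopolymer triplet has no repeat-unit class: %s",
              paste(unique(triplet[homo]), collapse = ", ")),
      class = c("tnr_homopolymer", "error", "condition")))
  }
  invisible(triplet)
}

#' Members of the unit class containing a triplet
#'
#' @param triplet A single DNA triplet (e.g. `"CTG"`).
#' @return Character vector of the 6 equivalent triplets, sorted.
#' @examples
#' unit_class_members("CAG")
#' @export
unit_class_members <- function(triplet) {
  triplet <- toupper(triplet)
  stopifnot(length(triplet) == 1L)
  .validate_triplet(triplet)
  sort(unique(c(.rotations(triplet), .rotations(.revcomp(triplet)))))
}

#' Canonical class of a repeat unit
#'
#' Maps a triplet to the label of its equivalence class under cyclic
#' rotation and reverse complement.  The four disease classes are reported
#' under their conventional names (CAG, GCG, GAA, GAC); other classes are
#' labelled by their lexicographically smallest member.
#'
#' @param triplet Character vector of DNA triplets.
#' @return Character vector of class labels, same length as `triplet`.
#'   Homopolymer or non-DNA input raises an error of class
#'   `"tnr_homopolymer"` or `"tnr_invalid_triplet"` respectively.
#' @examples
#' canonical_unit(c("CAG", "CTG", "AGC"))  # all "CAG"
#' @export
canonical_unit <- function(triplet) {
  triplet <- toupper(as.character(triplet))
  .validate_triplet(triplet)
  vapply(triplet, function(t) {
    key <- min(c(.rotations(t), .rotations(.revcomp(t))))
    if (key %in% names(.PAPER_LABELS)) .PAPER_LABELS[[key]] else key
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate all canonical repeat-unit classes
#'
#' @return A tibble with one row per class: `canonical_key` (smallest
#'   member), `label` (conventional name where one exists), and `members`
#'   (comma-separated sorted members).  Ten rows.
#' @examples
#' unit_classes()
#' @export
unit_classes <- function() {
  triplets <- apply(expand.grid(.DNA_BASES, .DNA_BASES, .DNA_BASES,
                                stringsAsFactors = FALSE),
                    1, paste, collapse = "")
  triplets <- triplets[!.is_homopolymer(triplets)]
  keys <- vapply(triplets, function(t) {
    min(c(.rotations(t), .rotations(.revcomp(t))))
  }, character(1), USE.NAMES = FALSE)
  out <- lapply(sort(unique(keys)), function(k) {
    tibble::tibble(
      canonical_key = k,
      label = if (k %in% names(.PAPER_LABELS)) .PAPER_LABELS[[k]] else k,
      members = paste(sort(triplets[keys == k]), collapse = ","))
  })
  do.call(rbind, out)
}
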