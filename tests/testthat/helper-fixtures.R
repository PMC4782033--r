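# shared fixtures and independent oracles, all built in code

# an epi_map with explicit category (assay name free-form)
map_of <- function(starts, ends, category, chrom = "chr1",
                   assay = "markX", cell_type = "CT1") {
  epi_map(data.frame(chrom = rep_len(chrom, length(starts)),
                     start = starts, end = ends),
          assay, cell_type, category = category)
}

locus_of <- function(start, end, unit = "CAG", chrom = "chr1",
                     source = "background") {
  tnr_loci(chrom, start, end, unit, source)
}

# exhaustive hypergeometric enumeration: independent two-sided Fisher
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  as <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(as, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# linear-scan nearest center-to-center distance
nearest_linear <- function(locus_start, locus_end, starts, ends) {
  if (length(starts) == 0L) return(NA_real_)
  p <- (locus_start + locus_end) %/% 2L
  min(abs(p - (starts + ends) %/% 2L))
}

# per-base genic labels for a single transcript (brute force)
base_labels <- function(tx) {
  lab <- rep("", tx$tx_end - tx$tx_start)  # indexed by pos - tx_start
  pos <- seq(tx$tx_start, tx$tx_end - 1L)
  es <- tx$exon_starts[[1]]; ee <- tx$exon_ends[[1]]
  in_exon <- vapply(pos, function(p) any(p >= es & p < ee), logical(1))
  lab[!in_exon] <- "intron"
  cs <- tx$cds_start; ce <- tx$cds_end
  coding <- in_exon & pos >= cs & pos < ce
  lab[coding] <- "exon"
  left <- in_exon & pos < cs
  right <- in_exon & pos >= ce
  if (tx$strand == "+") {
    lab[left] <- "utr5"; lab[right] <- "utr3"
  } else {
    lab[left] <- "utr3"; lab[right] <- "utr5"
  }
  data.frame(pos = pos, label = lab)
}

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
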