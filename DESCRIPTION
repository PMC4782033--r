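Package: tnrenrich
Title: Stratified Enrichment of Epigenetic Marks Around Tri-Nucleotide
    Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether epigenetic marks (histone
    modifications, DNA methylation, chromatin accessibility) are
    enriched around disease-associated tri-nucleotide repeats relative
    to a background of comparable repeats stratified by repeat-unit
    class and genic region.  Ships a curated catalog of 32
    disease-associated repeat loci (hg19), a perfect-tract repeat
    scanner, genic annotation against simple gene models, the three
    complementary statistics (per-cell-type Fisher tests on grouped
    repeats, per-locus binomial tests pooled across cell types, and a
    left-tail kernel-density test on log nearest-mark distances), and a
    synthetic-data generator with ground-truth manifests so every stage
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
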