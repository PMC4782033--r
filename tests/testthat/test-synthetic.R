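small_cfg <- function(...) {
  args <- list(seed = 5, n_da_repeats = 4, n_bg_repeats = 30,
               n_cell_types = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

test_that("scenario generation is deterministic given the seed", {
  s1 <- generate_scenario(small_cfg())
  s2 <- generate_scenario(small_cfg())
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(lapply(s1$maps, `[[`, "intervals"),
                   lapply(s2$maps, `[[`, "intervals"))
  s3 <- generate_scenario(small_cfg(seed = 6))
  expect_false(identical(s1$genome, s3$genome))
  # and file outputs are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_scenario(small_cfg(), dir = d1)
  generate_scenario(small_cfg(), dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("forced match probabilities pin the contingency tables", {
  sc <- generate_scenario(small_cfg(match_prob_da = 1, match_prob_bg = 0))
  da <- sc$loci[sc$loci$source == "disease", ]
  bg <- sc$loci[sc$loci$source == "background", ]
  for (assay in sc$cfg$assays) {
    maps <- Filter(function(m) m$assay == assay, sc$maps)
    r <- m1_run(da, bg, maps)
    expect_true(all(r$b == 0L))
    expect_true(all(r$c == 0L))
    expect_true(all(r$a == nrow(da)))
  }
})

test_that("the scanner recovers exactly the planted tracts", {
  sc <- generate_scenario(small_cfg(n_bg_repeats = 60))
  found <- do.call(rbind, lapply(names(sc$genome), function(ch)
    scan_sequence(sc$genome[[ch]], ch, scan_config(sc$cfg$min_units))))
  planted <- sc$loci[order(sc$loci$chrom, sc$loci$start), ]
  expect_identical(paste(found$chrom, found$start, found$end,
                         found$unit_class, found$unit_count),
                   paste(planted$chrom, planted$start, planted$end,
                         planted$unit_class, planted$unit_count))
})

test_that("emitted files re-parsed by the pipeline reproduce the manifest", {
  d <- withr::local_tempdir()
  sc <- generate_scenario(small_cfg(match_prob_da = 0.8,
                                    match_prob_bg = 0.3), dir = d)
  # repeat BEDs round-trip the loci
  da <- read_tnr_bed(file.path(d, "da_tnr.bed"), source = "disease")
  bg <- read_tnr_bed(file.path(d, "bg_tnr.bed"))
  loci <- rbind(da, bg)
  want <- sc$manifest$loci
  expect_identical(sort(paste(loci$chrom, loci$start, loci$end,
                              loci$unit_class)),
                   sort(paste(want$chrom, want$start, want$end,
                              want$unit_class)))
  # genic labels recomputed from the written gene model match the intent
  gm <- read_gene_model(file.path(d, "gene_model.tsv"))
  ann <- annotate_loci(loci, gm)
  key <- paste(want$chrom, want$start)
  ord <- match(paste(ann$chrom, ann$start), key)
  for (r in c("exon", "intron", "utr5", "utr3")) {
    expect_identical(ann[[r]], want[[r]][ord], info = r)
  }
  # match indicators recomputed from the written maps match the intent
  maps <- read_map_manifest(file.path(d, "map_manifest.tsv"))
  mm <- sc$manifest$matches
  for (m in maps) {
    got <- matches_m1(want, m)
    expect_identical(got, mm$match[mm$assay == m$assay &
                                     mm$cell_type == m$cell_type],
                     info = paste(m$assay, m$cell_type))
  }
  # intended distances hold where recorded (non-matching loci)
  for (m in maps) {
    sel <- mm$assay == m$assay & mm$cell_type == m$cell_type & !mm$match
    idx <- match(mm$locus_id[sel], want$locus_id)
    expect_equal(distance_to_nearest(want[idx, ], m),
                 mm$distance[sel], info = paste(m$assay, m$cell_type))
  }
  # scanning the written genome recovers the planted repeats
  found <- scan_fasta(file.path(d, "genome.fa"),
                      scan_config(sc$cfg$min_units))
  expect_identical(nrow(found), nrow(want))
})

test_that("configurations are validated", {
  expect_error(scenario_config(match_prob_da = 1.2), "match_prob")
  expect_error(scenario_config(unit_count_range = c(4, 10),
                               min_units = 6))
  expect_error(scenario_config(assays = "FAIREish"), "unknown assay")
})

test_that("spike reports summarize recovery against ground truth", {
  sc <- generate_scenario(small_cfg(match_prob_da = 1, match_prob_bg = 0))
  da <- sc$loci[sc$loci$source == "disease", ]
  bg <- sc$loci[sc$loci$source == "background", ]
  m1 <- do.call(rbind, lapply(sc$cfg$assays, function(a)
    m1_run(da, bg, Filter(function(m) m$assay == a, sc$maps))))
  rep <- spike_report(sc, m1 = m1)
  expect_identical(unique(rep$m1$expected_effect), "over")
  expect_true(all(rep$m1$rate_over == 1))
  bad <- m1; bad$assay <- "H3K9me3"
  expect_error(spike_report(sc, m1 = bad), "absent")
})
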