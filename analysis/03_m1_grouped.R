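#!/usr/bin/env Rscript
# Grouped enrichment (M1): per-cell-type Fisher tests on every stratum,
# reading the simulated study back from disk exactly as a real analysis
# would read repeat BEDs, a gene model and peak files.

suppressMessages(library(tnrenrich))
dir.create("results", showWarnings = FALSE)
src <- "scratch/scenario_spike"
if (!dir.exists(src)) stop("run analysis/02_simulate.R first")

da <- read_tnr_bed(file.path(src, "da_tnr.bed"), source = "disease")
bg <- read_tnr_bed(file.path(src, "bg_tnr.bed"))
gm <- read_gene_model(file.path(src, "gene_model.tsv"))
da <- annotate_loci(da, gm)
bg <- annotate_loci(bg, gm)
maps <- read_map_manifest(file.path(src, "map_manifest.tsv"))
cat("Re-read", nrow(da), "foreground and", nrow(bg),
    "background repeats;", length(maps), "epigenetic maps.\n")

out <- run_m1_analysis(da, bg, maps)
write_enrichment_tables("results", m1 = out)
cat("Per-stratum summary (percent of cell types at p <= 0.05):\n")
print(as.data.frame(out$summary[out$summary$n_da >= 5,
                                c("stratum", "assay", "n_da", "n_bg",
                                  "pct_over", "pct_under")]),
      row.names = FALSE)
cat("Full tables in results/m1_results.tsv and results/m1_summary.tsv.\n")
cat("With the planted effect (0.85 vs 0.25), well-populated strata are\n")
cat("flagged over-enriched in most cell types; single-locus strata are\n")
cat("underpowered, mirroring how grouped tests behave on small classes.\n")
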