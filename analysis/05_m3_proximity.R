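#!/usr/bin/env Rscript
# Proximity enrichment (M3): left-tail kernel-density test on log
# nearest-mark distances, on a scenario with a planted proximity effect
# (foreground marks placed 0.3x as far as background marks).

suppressMessages(library(tnrenrich))
dir.create("results", showWarnings = FALSE)

cfg <- scenario_config(seed = 20260903, n_da_repeats = 12,
                       n_bg_repeats = 300, n_cell_types = 1,
                       assays = "H3K4me3", match_prob_da = 0,
                       match_prob_bg = 0, proximity_shift = 0.3,
                       decoys_per_map = 0)
sc <- generate_scenario(cfg)
da <- sc$loci[sc$loci$source == "disease", ]
bg <- sc$loci[sc$loci$source == "background", ]
set.seed(20260904)
hold <- sample(nrow(bg), 50)

m3_da <- run_m3_analysis(da, bg[-hold, ], sc$maps)
m3_bg <- run_m3_analysis(bg[hold, ], bg[-hold, ], sc$maps)
write_enrichment_tables("results", m3 = m3_da)
rep <- spike_report(sc, m3_da = m3_da, m3_bg = m3_bg)
cat("Planted proximity shift 0.3x; held-out background as control:\n")
print(as.data.frame(rep$m3), row.names = FALSE)
write.table(rep$m3, "results/m3_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Foreground loci sit far in the left tail of the background\n")
cat("distance density; held-out background centers near 0.5, as an\n")
cat("unshifted draw from its own density should.\n")
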