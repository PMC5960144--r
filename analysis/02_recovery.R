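#!/usr/bin/env Rscript
# Stage 2: taxa recovery and relative-abundance capture, on un-rarefied
# counts, for both study comparisons:
#   S1 vs S2      - how reproducible are two straw aliquots of one donor?
#   S2 vs mouse   - how much of the gavage inoculum engrafts in mice?
# A taxon enters a comparison only if it reaches 0.1% relative abundance in
# at least one of the compared samples; recovery = detection (count > 0) of
# reference taxa in the query group.

library(engraftr)

study <- read_study("results/synthetic_study")
outdir <- "results/recovery"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

for (cmp in c("S1_vs_S2", "S2_vs_mouse")) {
  for (pool in c("any_mouse", "per_mouse_mean")) {
    tab <- recovery_table(study$counts, study$tax, study$manifest,
                          comparison = cmp, pooling = pool)
    smry <- summarize_recovery(tab)
    base <- file.path(outdir, sprintf("%s_%s", tolower(cmp), pool))
    write.table(tab, paste0(base, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(smry, paste0(base, "_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (pool == "any_mouse") {
      cat(sprintf("\n%s (pooling: %s) - mean +/- SE over %d subjects\n",
                  cmp, pool, smry$n_subjects[1]))
      for (i in seq_len(nrow(smry))) {
        cat(sprintf("  %-7s recovery %6.2f%% +/- %.2f | abundance captured %6.2f%% +/- %.2f\n",
                    smry$rank[i], smry$mean_recovery_pct[i],
                    smry$se_recovery_pct[i],
                    smry$mean_abundance_captured_pct[i],
                    smry$se_abundance_captured_pct[i]))
      }
    }
  }
}
cat("\nTables written under", outdir, "\n")
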