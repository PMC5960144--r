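#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic engraftment study and write the
# file bundle (counts, taxonomy, tree, manifest, serum metabolites) that the
# downstream stages consume.
#
# The default configuration mirrors the study design: 8 donor subjects, two
# straw aliquots (S1 for extraction, S2 for gavage) and 3 recipient germ-free
# mice per subject, 800 OTUs, 60,000 reads per sample, and an engraftment
# stage retaining included OTUs at a baseline probability of 0.785.

library(engraftr)

cfg <- synthetic_config(rng_seed = 1)
study <- generate_study(cfg)
outdir <- "results/synthetic_study"
write_study(study, outdir)

cat("Synthetic study bundle written to", outdir, "\n")
cat(sprintf("  %d OTUs x %d samples (%d subjects x [S1, S2, %d mice])\n",
            nrow(study$counts), ncol(study$counts), cfg$n_subjects,
            cfg$n_mice_per_subject))
cat(sprintf("  reads per sample: %d; retention baseline: %.3f\n",
            cfg$reads_per_sample, cfg$retention_p))
cat(sprintf("  TMA-producer OTUs: %d; per-subject producer abundance range: %.3f-%.3f\n",
            length(study$producers),
            min(colSums(study$donors[study$producers, ])),
            max(colSums(study$donors[study$producers, ]))))
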