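#!/usr/bin/env Rscript
# Stage 1: generate the demo study.
#
# A seeded synthetic genome (4 x 25 Mb), 2000 genes with 200 planted
# up-targets and 200 down-targets, a focal (BRD9-like) and a partner
# (SMARCA4-like) cistrome with half the focal peaks co-occupied, paired
# wild-type/knockout signal tracks, and a DESeq2-shaped expression table.
# Every artifact is written in its standard on-disk format under
# results/demo/inputs/ so the later stages consume files, not R objects.

suppressPackageStartupMessages(library(bindexpr))

cfg <- simulation_config(seed = 1)
dir.create("results/demo", recursive = TRUE, showWarnings = FALSE)
study <- simulate_study(cfg, out_dir = "results/demo/inputs")

tt <- table(study$truth_genes$label)
cat("Synthetic study written to results/demo/inputs/\n")
cat(sprintf("  genes: %d (%d planted up, %d planted down, %d static)\n",
            nrow(study$genes), tt["planted_up"], tt["planted_down"],
            tt["static"]))
cat(sprintf("  focal peaks: %d (%d target-linked), partner peaks: %d\n",
            nrow(study$focal),
            sum(study$truth_peaks$label == "target-linked"),
            nrow(study$partner)))
cat(sprintf("  signal steps: wt %d, ko %d\n",
            nrow(study$signal_wt), nrow(study$signal_ko)))
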