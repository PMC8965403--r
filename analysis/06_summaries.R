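#!/usr/bin/env Rscript
# Stage 6 — the cross-feature summary layer: signal-rate correlation
# (Kendall's tau, with and without zero-rate-floored features), D and rate
# bin proportions, per-category medians, reconstructability bands and
# pairwise family overlaps.

source(file.path("analysis", "00_config.R"))
cfg <- pipe_config()

stage_summaries(cfg)

tau <- read.table(file.path(run_dir, "kendall_tau.csv"), header = TRUE,
                  sep = ",", comment.char = "#")
cat("Kendall tau, median D vs median log10 rate:\n")
print(tau, row.names = FALSE)

dbin <- read.table(file.path(run_dir, "d_bin_proportions.csv"),
                   header = TRUE, sep = ",", comment.char = "#")
cat("\nD bins (overclumped / signal / random / overdispersed):\n")
print(dbin, row.names = FALSE)

ovl <- read.table(file.path(run_dir, "family_overlap_percent.csv"),
                  header = TRUE, sep = ",", comment.char = "#")
cat("\npairwise family overlap in >=0.95 reconstructable features (%):\n")
print(ovl, row.names = FALSE)

cat("\nrun artefacts under", run_dir, "— see manifest.json\n")
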