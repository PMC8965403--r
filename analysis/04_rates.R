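#!/usr/bin/env Rscript
# Stage 4 — hidden-rates model fits (8 transition rates, 2 rate classes)
# per feature per tree; per-feature summary gain/loss rates are the
# conditional-occupancy-weighted class averages, summarized by the median
# log10 rate across trees. Fitted rates are compared with the generating
# rates for the CTMC-regime features.

source(file.path("analysis", "00_config.R"))
cfg <- pipe_config()

stage_rates(cfg)

rsum <- read.table(file.path(run_dir, "rate_summary.csv"), header = TRUE,
                   sep = ",", comment.char = "#")
truth <- read.table(file.path(synth_dir, "truth.csv"), header = TRUE,
                    sep = ",")
m <- merge(rsum, truth, by = "feature")
ct <- m[m$regime == "ctmc" & !is.na(m$gain), ]
if (nrow(ct) > 0) {
  cat(sprintf("CTMC features (n=%d): median |log10(est) - log10(true)|:\n",
              nrow(ct)))
  cat(sprintf("  gain %.2f  loss %.2f (decades)\n",
              median(abs(ct$median_log_gain - log10(ct$gain))),
              median(abs(ct$median_log_loss - log10(ct$loss)))))
}
cat("rate bins (slow < -0.5 < medium < 0.5 < fast), all features:\n")
print(table(gain = bin_rate(m$median_log_gain)))
print(table(loss = bin_rate(m$median_log_loss)))
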