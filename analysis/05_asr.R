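#!/usr/bin/env Rscript
# Stage 5 — marginal ancestral state reconstruction at each family root
# under the fitted hidden-rates models; per-feature family-root presence
# probability is the median across trees.

source(file.path("analysis", "00_config.R"))
cfg <- pipe_config()

stage_asr(cfg)

probs <- read.table(file.path(run_dir, "asr_root_probs.csv"), header = TRUE,
                    sep = ",", comment.char = "#")
cat("per-family reconstructability (proportion of features):\n")
for (fam in sort(unique(probs$family))) {
  p <- probs$p_present[probs$family == fam]
  cat(sprintf("  %-8s present>=0.95: %.2f  present>=0.75: %.2f  uncertain(0.25,0.75): %.2f\n",
              fam, mean(p >= 0.95), mean(p >= 0.75),
              mean(p > 0.25 & p < 0.75)))
}
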