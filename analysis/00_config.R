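# Shared configuration for the analysis drivers. The study emulates the
# 5-family / 60-language design; the driver runs are scaled to 40 features,
# 10 posterior trees, 100 null simulations and 3 optimizer starts so the
# whole workflow completes in minutes on one core (the package defaults are
# the full-size settings).

library(lingstab)

ANALYSIS_SEED <- 20260927L

synth_dir <- file.path("results", "synthetic")
run_dir <- file.path("results", "run")

sim_config <- simulation_config(n_features = 40, seed = ANALYSIS_SEED)

pipe_config <- function() {
  pipeline_config(
    matrix_path = file.path(synth_dir, "matrix.csv"),
    catalog_path = file.path(synth_dir, "catalog.csv"),
    taxonomy_path = file.path(synth_dir, "taxonomy.nwk"),
    out_dir = run_dir,
    n_trees = 10, n_sim = 100, n_starts = 3,
    seed = ANALYSIS_SEED, scaled_down = TRUE)
}
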