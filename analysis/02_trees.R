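#!/usr/bin/env Rscript
# Stage 2 — filter the matrix (drop never-present features) and draw the
# data-free tree pseudo-posterior honouring the family constraints. Checks
# the two topological contracts: constrained clades appear with frequency
# 1, unresolved groupings with uniform low support.

source(file.path("analysis", "00_config.R"))
cfg <- pipe_config()

stage_filter(cfg)
stage_trees(cfg)

post <- read_trees(file.path(run_dir, "trees.nwk"))
taxo <- read_taxonomy(cfg$taxonomy_path)
fams <- taxonomy_families(taxo$tip.label)
cat(sprintf("sampled %d trees over %d tips\n", post$n,
            length(taxo$tip.label)))
for (f in unique(fams)) {
  tips <- names(fams)[fams == f]
  if (length(tips) >= 2)
    cat(sprintf("  family %s (%d tips): clade frequency %.2f\n",
                f, length(tips), clade_frequency(post, tips)))
}
# an unresolved pair inside the largest family, the Kazakh-Nogai analogue
big <- names(which.max(table(fams)))
pair <- names(fams)[fams == big][1:2]
cat(sprintf("  unresolved pair {%s, %s}: frequency %.2f (low = agnostic)\n",
            pair[1], pair[2], clade_frequency(post, pair)))
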