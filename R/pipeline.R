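#' Pipeline configuration
#'
#' Bundles paths, stage sizes and the master seed for [run_pipeline()].
#' `scaled_down = TRUE` presets the reduced settings (100 trees, 100 null
#' simulations, 3 restarts) instead of the full-size defaults (1000 trees,
#' 1000 null simulations, 5 restarts).
#'
#' @param matrix_path,catalog_path,taxonomy_path Input files (delimited
#'   matrix, delimited catalogue, Newick taxonomy).
#' @param out_dir Output directory (created if needed).
#' @param n_trees,n_sim,n_starts Stage sizes; `NULL` means the preset for
#'   the chosen scale.
#' @param thresholds Reconstructability certainty thresholds.
#' @param seed Master seed.
#' @param branch_model Passed to [sample_trees()].
#' @param scaled_down Use the reduced presets.
#' @return List of class `pipeline_config` (including `hash`, an md5 of the
#'   configuration used to stamp outputs).
#' @export
pipeline_config <- function(matrix_path, catalog_path, taxonomy_path,
                            out_dir, n_trees = NULL, n_sim = NULL,
                            n_starts = NULL, thresholds = c(0.95, 0.75),
                            seed = 1, branch_model = "yule",
                            scaled_down = FALSE) {
  preset <- if (scaled_down) c(100, 100, 3) else c(1000, 1000, 5)
  cfg <- list(matrix_path = matrix_path, catalog_path = catalog_path,
              taxonomy_path = taxonomy_path, out_dir = out_dir,
              n_trees = if (is.null(n_trees)) preset[1] else n_trees,
              n_sim = if (is.null(n_sim)) preset[2] else n_sim,
              n_starts = if (is.null(n_starts)) preset[3] else n_starts,
              thresholds = thresholds, seed = as.integer(seed),
              branch_model = branch_model, scaled_down = scaled_down)
  stopifnot(cfg$n_trees >= 1, cfg$n_sim >= 1, cfg$n_starts >= 1,
            all(cfg$thresholds > 0), all(cfg$thresholds < 1))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[sort(setdiff(names(cfg), "hash"))]), f)
  unname(tools::md5sum(f))
}

stamp_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", cfg$hash, cfg$seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  path
}

read_stage_csv <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Run the full stability analysis pipeline
#'
#' Executes the stages in order — filter, trees, D statistic, hidden-rates
#' fits, ancestral reconstruction, summaries — writing every stage's output
#' as delimited text under `config$out_dir`, stamped with the configuration
#' hash and seed, plus a JSON manifest. Stages communicate only through the
#' serialized artefacts, so each can be re-run independently via the
#' `stage_*` functions. Re-running with the same configuration reproduces
#' the outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (list of artefact paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$matrix_path, config$catalog_path,
              config$taxonomy_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_filter(config)
  stage_trees(config)
  stage_dstat(config)
  stage_rates(config)
  stage_asr(config)
  stage_summaries(config)
  arts <- union(list.files(config$out_dir, full.names = FALSE),
                "manifest.json")
  manifest <- list(config = unclass(config)[setdiff(names(config), "hash")],
                   config_hash = config$hash, seed = config$seed,
                   artefacts = sort(arts))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @export
stage_filter <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fm <- read_feature_matrix(config$matrix_path)
  flt <- drop_never_present(fm)
  read_feature_catalog(config$catalog_path,
                       features = flt$matrix$features)  # validates coverage
  cov <- coverage_stats(flt$matrix)
  write_feature_matrix(flt$matrix,
                       file.path(config$out_dir, "filtered_matrix.csv"))
  stamp_csv(data.frame(feature = flt$removed),
            file.path(config$out_dir, "removed_features.csv"), config)
  stamp_csv(data.frame(feature = names(cov$per_feature),
                       n_coded = as.integer(cov$per_feature)),
            file.path(config$out_dir, "coverage_per_feature.csv"), config)
  stamp_csv(data.frame(taxon = names(cov$per_taxon),
                       n_coded = as.integer(cov$per_taxon)),
            file.path(config$out_dir, "coverage_per_taxon.csv"), config)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_trees <- function(config) {
  fm <- read_feature_matrix(file.path(config$out_dir,
                                      "filtered_matrix.csv"))
  taxo <- read_taxonomy(config$taxonomy_path)
  extra_m <- setdiff(fm$taxa, taxo$tip.label)
  extra_t <- setdiff(taxo$tip.label, fm$taxa)
  if (length(extra_m) + length(extra_t) > 0)
    stop("taxa mismatch between matrix and taxonomy; only in matrix: [",
         paste(extra_m, collapse = ", "), "]; only in taxonomy: [",
         paste(extra_t, collapse = ", "), "]")
  post <- sample_trees(taxo, config$n_trees, config$seed,
                       config$branch_model)
  write_trees(post, file.path(config$out_dir, "trees.nwk"), "newick")
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_dstat <- function(config) {
  fm <- read_feature_matrix(file.path(config$out_dir,
                                      "filtered_matrix.csv"))
  post <- read_trees(file.path(config$out_dir, "trees.nwk"))
  per <- vector("list", length(fm$features))
  summ <- vector("list", length(fm$features))
  for (j in seq_along(fm$features)) {
    f <- fm$features[j]
    md <- median_D(post, feature_values(fm, f), n_sim = config$n_sim,
                   seed = config$seed + j * 10000L)
    per[[j]] <- cbind(feature = f, md$per_tree)
    summ[[j]] <- data.frame(feature = f, median_D = md$median_D,
                            n_ok = md$n_ok, n_not_ok = md$n_not_ok)
  }
  stamp_csv(do.call(rbind, per),
            file.path(config$out_dir, "d_per_tree.csv"), config)
  stamp_csv(do.call(rbind, summ),
            file.path(config$out_dir, "d_summary.csv"), config)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_rates <- function(config) {
  fm <- read_feature_matrix(file.path(config$out_dir,
                                      "filtered_matrix.csv"))
  post <- read_trees(file.path(config$out_dir, "trees.nwk"))
  rows <- list()
  for (j in seq_along(fm$features)) {
    f <- fm$features[j]
    trait <- feature_values(fm, f)
    for (i in seq_along(post$trees)) {
      fit <- fit_hidden_rates(post$trees[[i]], trait,
                              seed = config$seed + j * 10000L + i,
                              n_starts = config$n_starts)
      rows[[length(rows) + 1]] <-
        data.frame(feature = f, tree = i, t(fit$rates),
                   logL = fit$log_likelihood, converged = fit$converged,
                   summary_gain = fit$summary_gain,
                   summary_loss = fit$summary_loss,
                   occupancy = fit$occupancy,
                   occupancy_gain = fit$occupancy_gain,
                   occupancy_loss = fit$occupancy_loss)
    }
  }
  fits <- do.call(rbind, rows)
  stamp_csv(fits, file.path(config$out_dir, "rate_fits.csv"), config)
  agg <- do.call(rbind, lapply(split(fits, fits$feature), function(g)
    data.frame(feature = g$feature[1],
               median_log_gain = stats::median(log10_rate(g$summary_gain)),
               median_log_loss = stats::median(log10_rate(g$summary_loss)))))
  agg <- agg[match(fm$features, agg$feature), ]
  stamp_csv(agg, file.path(config$out_dir, "rate_summary.csv"), config)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_asr <- function(config) {
  fm <- read_feature_matrix(file.path(config$out_dir,
                                      "filtered_matrix.csv"))
  post <- read_trees(file.path(config$out_dir, "trees.nwk"))
  fits <- read_stage_csv(file.path(config$out_dir, "rate_fits.csv"))
  fams <- sort(unique(fm$families))
  fams <- fams[vapply(fams, function(x) sum(fm$families == x) >= 2, TRUE)]
  rows <- list()
  for (r in seq_len(nrow(fits))) {
    f <- fits$feature[r]; i <- fits$tree[r]
    Q <- hidden_rate_matrix(unlist(fits[r, RATE_NAMES]))
    asr <- marginal_asr(post$trees[[i]], feature_values(fm, f), Q)
    for (fam in fams)
      rows[[length(rows) + 1]] <-
        data.frame(feature = f, tree = i, family = fam,
                   p_present = family_root_presence(asr, fam, fm$families))
  }
  per <- do.call(rbind, rows)
  stamp_csv(per, file.path(config$out_dir, "asr_per_tree.csv"), config)
  agg <- do.call(rbind, lapply(split(per, list(per$feature, per$family)),
    function(g) data.frame(feature = g$feature[1], family = g$family[1],
                           p_present = stats::median(g$p_present))))
  agg <- agg[order(agg$feature, agg$family), ]
  stamp_csv(agg, file.path(config$out_dir, "asr_root_probs.csv"), config)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @export
stage_summaries <- function(config) {
  out <- config$out_dir
  dsum <- read_stage_csv(file.path(out, "d_summary.csv"))
  rsum <- read_stage_csv(file.path(out, "rate_summary.csv"))
  fm <- read_feature_matrix(file.path(out, "filtered_matrix.csv"))
  catalog <- read_feature_catalog(config$catalog_path,
                                  features = fm$features)
  stab <- feature_stability(dsum$feature, dsum$median_D,
                            rsum$median_log_gain[match(dsum$feature,
                                                       rsum$feature)],
                            rsum$median_log_loss[match(dsum$feature,
                                                       rsum$feature)])
  stamp_csv(stab, file.path(out, "stability.csv"), config)
  ov <- overall_summary(stab)
  stamp_csv(cbind(metric = rownames(ov$metrics), ov$metrics),
            file.path(out, "overall_summary.csv"), config)
  stamp_csv(data.frame(category = c("slow", "medium", "fast"),
                       gain = as.numeric(ov$gain_bin_proportions),
                       loss = as.numeric(ov$loss_bin_proportions)),
            file.path(out, "rate_bin_proportions.csv"), config)
  stamp_csv(data.frame(bin = names(ov$D_bin_proportions),
                       proportion = as.numeric(ov$D_bin_proportions)),
            file.path(out, "d_bin_proportions.csv"), config)
  tau <- rbind(cbind(direction = "gain",
                     signal_rate_correlation(stab, "gain")),
               cbind(direction = "loss",
                     signal_rate_correlation(stab, "loss")))
  stamp_csv(tau, file.path(out, "kendall_tau.csv"), config)
  for (axis in c("functional_category", "domain", "part_of_speech"))
    stamp_csv(category_medians(stab, catalog, axis),
              file.path(out, paste0("category_medians_", axis, ".csv")),
              config)
  probs <- read_stage_csv(file.path(out, "asr_root_probs.csv"))
  root_probs <- do.call(cbind, lapply(split(probs, probs$family),
                                      function(g) g$p_present[match(
                                        dsum$feature, g$feature)]))
  rownames(root_probs) <- dsum$feature
  rec <- reconstructability_summary(root_probs, config$thresholds)
  stamp_csv(rec$per_family, file.path(out, "reconstructability.csv"),
            config)
  stamp_csv(category_normalized_reconstruction(root_probs, catalog,
                                               "functional_category",
                                               max(config$thresholds)),
            file.path(out, "reconstruction_by_category.csv"), config)
  ovl <- pairwise_family_overlap(root_probs, max(config$thresholds))
  stamp_csv(cbind(family = rownames(ovl$percent),
                  as.data.frame(ovl$percent)),
            file.path(out, "family_overlap_percent.csv"), config)
  pcd <- do.call(rbind, lapply(colnames(root_probs), function(fam)
    cbind(family = fam,
          proto_child_distance(stats::setNames(root_probs[, fam],
                                               rownames(root_probs)),
                               fm, fam, max(config$thresholds)))))
  stamp_csv(pcd, file.path(out, "proto_child_distance.csv"), config)
  jsonlite::write_json(
    list(config_hash = config$hash, seed = config$seed,
         stability = stab, overall = ov, kendall = tau),
    file.path(out, "stability.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out)
}
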