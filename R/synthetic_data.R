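#' Configuration for the synthetic study generator
#'
#' Defaults emulate the real study design: five family clades of sizes 12,
#' 2, 14, 11 and 21 (60 taxa) under an unconstrained root, 171 binary
#' features, and missing values injected at a 15% rate. Features are
#' assigned generating regimes: `ctmc` (binary gain/loss process with rates
#' drawn log-uniformly from `rate_range`), `clumped` (a single gain on one
#' internal branch), `shuffled` (random arrangement) and
#' `brownian_threshold` (thresholded Brownian motion).
#'
#' @param n_families Number of family clades.
#' @param tips_per_family Integer vector of family sizes (each >= 2).
#' @param polytomy_fraction Probability that an internal grouping inside a
#'   family is collapsed into a polytomy.
#' @param n_features Number of features to simulate.
#' @param regime_weights Named sampling weights over the four regimes.
#' @param rate_range Range for log-uniform ctmc gain/loss rates.
#' @param missing_rate Probability a cell is blanked to `missing`.
#' @param missing_mode `"random"` (completely at random) or
#'   `"family_blocked"` (whole families uncodable for a feature, mimicking
#'   per-language coverage gaps).
#' @param seed Integer seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 5,
                              tips_per_family = c(12, 2, 14, 11, 21),
                              polytomy_fraction = 0.5,
                              n_features = 171,
                              regime_weights = c(ctmc = 0.4, clumped = 0.2,
                                                 shuffled = 0.2,
                                                 brownian_threshold = 0.2),
                              rate_range = c(0.1, 5),
                              missing_rate = 0.15,
                              missing_mode = c("random", "family_blocked"),
                              seed = 1) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(length(tips_per_family) == n_families,
            all(tips_per_family >= 2),
            polytomy_fraction >= 0, polytomy_fraction <= 1,
            n_features >= 1,
            all(rate_range >= RATE_LOWER), all(rate_range <= RATE_UPPER),
            missing_rate >= 0, missing_rate <= 1)
  regimes <- c("ctmc", "clumped", "shuffled", "brownian_threshold")
  if (!all(names(regime_weights) %in% regimes) || sum(regime_weights) <= 0)
    stop("regime_weights must be named over: ",
         paste(regimes, collapse = ", "))
  structure(list(n_families = n_families,
                 tips_per_family = tips_per_family,
                 polytomy_fraction = polytomy_fraction,
                 n_features = n_features,
                 regime_weights = regime_weights,
                 rate_range = rate_range,
                 missing_rate = missing_rate,
                 missing_mode = missing_mode,
                 seed = seed),
            class = "simulation_config")
}

#' Generate a constrained taxonomy
#'
#' Builds `n_families` constrained family clades under an unconstrained
#' root. Inside each family, subgroupings are nested at random and each
#' internal grouping is collapsed into a polytomy with probability
#' `polytomy_fraction`, emulating a classification with partly unresolved
#' subgroups.
#'
#' @param config A [simulation_config()].
#' @return A `phylo` taxonomy (tips `Fi_tj`, families recoverable with
#'   [taxonomy_families()]).
#' @export
make_taxonomy <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  fam_clade <- function(f, m) {
    labs <- sprintf("F%d_t%02d", f, seq_len(m))
    if (m == 2) return(sprintf("(%s,%s)", labs[1], labs[2]))
    groups <- as.list(labs)
    while (length(groups) > 1) {
      pair <- sample.int(length(groups), 2)
      joined <- if (length(groups) > 2 &&
                    stats::runif(1) < config$polytomy_fraction)
        paste(groups[[pair[1]]], groups[[pair[2]]], sep = ",")
      else sprintf("(%s,%s)", groups[[pair[1]]], groups[[pair[2]]])
      groups <- c(groups[-pair], list(joined))
    }
    sprintf("(%s)", groups[[1]])
  }
  clades <- mapply(fam_clade, seq_len(config$n_families),
                   config$tips_per_family)
  read_taxonomy(text = paste0("(", paste(clades, collapse = ","), ");"))
}

#' Family labels of synthetic taxa
#'
#' @param taxa Tip labels produced by [make_taxonomy()].
#' @return Named character vector taxon -> `Family<i>`.
#' @export
taxonomy_families <- function(taxa) {
  stats::setNames(sub("^F(\\d+)_.*$", "Family\\1", taxa), taxa)
}

#' Simulate a binary trait by an exact CTMC along a tree
#'
#' States evolve with exponential waiting times along each branch (event
#' times simulated exactly, not endpoint-sampled), so true ancestral states
#' and event counts are retained for recovery diagnostics. Works for any
#' generator whose state names begin with `0` or `1` (e.g. the 2-state
#' gain/loss matrix or the 4-state hidden-rates matrix); the observed value
#' of a state is that leading digit.
#'
#' @param tree A `phylo` tree.
#' @param Q Generator matrix with named states.
#' @param root Root state name, or a prior vector over states to draw from.
#' @param seed Integer seed.
#' @return List with `tip_values` (named 0/1 vector), `node_states` (state
#'   name per ape node id), `n_events`.
#' @export
simulate_trait <- function(tree, Q, root = NULL, seed = 1) {
  k <- nrow(Q)
  states <- rownames(Q)
  if (is.null(states)) stop("Q must have state names")
  set.seed(seed)
  root_state <- if (is.null(root)) sample(states, 1)
    else if (is.character(root)) match.arg(root, states)
    else sample(states, 1, prob = root)
  cl <- stats::reorder(tree, "cladewise")
  ntot <- length(tree$tip.label) + tree$Nnode
  node_states <- character(ntot)
  node_states[cl$edge[1, 1]] <- root_state
  n_events <- 0L
  for (e in seq_len(nrow(cl$edge))) {
    s <- node_states[cl$edge[e, 1]]
    t_left <- cl$edge.length[e]
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      wait <- stats::rexp(1, out_rate)
      if (wait > t_left) break
      t_left <- t_left - wait
      others <- setdiff(states, s)
      s <- if (length(others) == 1) others
           else sample(others, 1, prob = Q[s, others])
      n_events <- n_events + 1L
    }
    node_states[cl$edge[e, 2]] <- s
  }
  ntip <- length(tree$tip.label)
  tips <- as.numeric(substr(node_states[seq_len(ntip)], 1, 1))
  list(tip_values = stats::setNames(tips, tree$tip.label),
       node_states = node_states, n_events = n_events)
}

#' Two-state gain/loss generator
#'
#' @param gain,loss Rates 0 -> 1 and 1 -> 0.
#' @return 2x2 generator with states `"0"`, `"1"`.
#' @export
two_state_matrix <- function(gain, loss) {
  matrix(c(-gain, loss, gain, -loss), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Simulate a full feature matrix with known ground truth
#'
#' Applies a per-feature generating regime on the designated tree of the
#' posterior (by default its first tree) and injects missing values at the
#' configured rate.
#'
#' @param config A [simulation_config()].
#' @param posterior A `tree_posterior` over the taxa of the config's
#'   taxonomy.
#' @param tree_index Which posterior tree generates the data (default 1).
#' @return List with `matrix` (a [feature_matrix()]) and `truth` (per
#'   feature: regime, rates where applicable, true complete tip values and
#'   node states).
#' @export
simulate_matrix <- function(config, posterior, tree_index = 1) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- if (inherits(posterior, "tree_posterior"))
    posterior$trees[[tree_index]] else posterior[[tree_index]]
  ntip <- length(tree$tip.label)
  set.seed(config$seed + 1000L)
  feats <- sprintf("SF%03d", seq_len(config$n_features))
  w <- config$regime_weights
  regimes <- sample(names(w), config$n_features, replace = TRUE, prob = w)
  feature_seeds <- sample.int(2^30, config$n_features)
  vals <- matrix("absent", ntip, config$n_features,
                 dimnames = list(tree$tip.label, feats))
  truth <- vector("list", config$n_features)
  names(truth) <- feats
  internal_edges <- which(tree$edge[, 2] > ntip)
  for (j in seq_len(config$n_features)) {
    set.seed(feature_seeds[j])
    reg <- regimes[j]
    rec <- list(regime = reg)
    if (reg == "ctmc") {
      r <- exp(stats::runif(2, log(config$rate_range[1]),
                            log(config$rate_range[2])))
      Q <- two_state_matrix(r[1], r[2])
      sim <- simulate_trait(tree, Q, seed = feature_seeds[j])
      v <- sim$tip_values
      rec$gain <- r[1]; rec$loss <- r[2]
      rec$node_states <- sim$node_states
    } else if (reg == "clumped") {
      e <- sample(internal_edges, 1)
      clade_tips <- ape::extract.clade(tree, tree$edge[e, 2])$tip.label
      v <- stats::setNames(as.numeric(tree$tip.label %in% clade_tips),
                           tree$tip.label)
      rec$gain_edge_node <- tree$edge[e, 2]
    } else if (reg == "shuffled") {
      kpos <- sample.int(ntip - 1, 1)
      v <- stats::setNames(sample(c(rep(1, kpos), rep(0, ntip - kpos))),
                           tree$tip.label)
      rec$prevalence <- kpos
    } else {                                  # brownian_threshold
      cl <- stats::reorder(tree, "cladewise")
      x <- numeric(ntip + tree$Nnode)
      for (e in seq_len(nrow(cl$edge)))
        x[cl$edge[e, 2]] <- x[cl$edge[e, 1]] +
          sqrt(cl$edge.length[e]) * stats::rnorm(1)
      kpos <- sample.int(ntip - 1, 1)
      v <- stats::setNames(as.numeric(rank(x[seq_len(ntip)]) > ntip - kpos),
                           tree$tip.label)
      rec$prevalence <- kpos
    }
    rec$true_tip_values <- v
    truth[[j]] <- rec
    vals[, j] <- ifelse(v[tree$tip.label] == 1, "present", "absent")
  }
  set.seed(config$seed + 2000L)
  if (config$missing_rate > 0) {
    fams <- taxonomy_families(tree$tip.label)
    if (config$missing_mode == "random") {
      mask <- matrix(stats::runif(length(vals)) < config$missing_rate,
                     nrow(vals))
      vals[mask] <- "missing"
    } else {
      for (j in seq_len(config$n_features)) {
        blocked <- unique(fams)[stats::runif(length(unique(fams))) <
                                  config$missing_rate]
        vals[fams %in% blocked, j] <- "missing"
      }
    }
  }
  fm <- feature_matrix(vals, taxonomy_families(tree$tip.label))
  list(matrix = fm,
       truth = list(config = unclass(config), tree_index = tree_index,
                    regimes = stats::setNames(regimes, feats),
                    features = truth))
}
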