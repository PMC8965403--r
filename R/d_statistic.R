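postorder_edge <- function(tree) {
  po <- stats::reorder(tree, "postorder")
  list(edge = po$edge, len = po$edge.length)
}

# Accept a trait as numeric 0/1/NA or character present/absent/missing,
# named by tip; return numeric vector aligned to tree tip order.
as_binary_trait <- function(trait, tree, allow_missing = TRUE) {
  if (is.character(trait))
    trait <- stats::setNames(
      ifelse(trait == "present", 1, ifelse(trait == "absent", 0, NA_real_)),
      names(trait))
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss) > 0)
      stop("no trait value for tip(s): ", paste(miss, collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stop("trait length does not match number of tips")
  }
  if (!allow_missing && anyNA(trait))
    stop("trait has missing values for tip(s): ",
         paste(tree$tip.label[is.na(trait)], collapse = ", "))
  bad <- !is.na(trait) & !trait %in% c(0, 1)
  if (any(bad)) stop("trait values must be 0, 1 or missing")
  unname(trait)
}

#' Sum of sister-clade differences for a binary trait
#'
#' Nodal values are computed bottom-up as the unweighted mean of the two
#' daughter values; the statistic is the sum over internal nodes of the
#' absolute difference between the two daughters. Branch lengths play no
#' role here (they enter only the Brownian null).
#'
#' @param tree A binary `phylo` tree.
#' @param trait Tip values: numeric 0/1 (or character present/absent), named
#'   by tip label or ordered as `tree$tip.label`. No missing values here;
#'   pruning happens in [compute_D()].
#' @return The observed sum of sister differences (nonnegative scalar).
#' @export
sister_diff_sum <- function(tree, trait) {
  if (!ape::is.binary(tree)) stop("tree must be strictly binary")
  v <- as_binary_trait(trait, tree, allow_missing = FALSE)
  pe <- postorder_edge(tree)
  as.numeric(cpp_sister_diff_sum(pe$edge, matrix(v, ncol = 1), tree$Nnode))
}

#' Permutation (shuffle) null for the D statistic
#'
#' Each replicate permutes the tip values uniformly at random, preserving
#' the number of 1s, and records the sister-difference sum.
#'
#' @inheritParams sister_diff_sum
#' @param n_sim Number of replicates.
#' @param seed Integer seed (replicates are reproducible).
#' @return Numeric vector of `n_sim` d values.
#' @export
shuffle_null <- function(tree, trait, n_sim, seed) {
  stopifnot(n_sim >= 1)
  v <- as_binary_trait(trait, tree, allow_missing = FALSE)
  set.seed(seed)
  perm <- replicate(n_sim, sample(v))
  pe <- postorder_edge(tree)
  as.numeric(cpp_sister_diff_sum(pe$edge, perm, tree$Nnode))
}

#' Brownian-threshold null for the D statistic
#'
#' Each replicate simulates unit-rate Brownian motion along the branches,
#' thresholds the tip values at the rank that reproduces the observed number
#' of 1s, and records the sister-difference sum. Rank ties (possible with
#' zero-length branches) are broken by a deterministic jitter drawn from the
#' replicate seed.
#'
#' @inheritParams shuffle_null
#' @return Numeric vector of `n_sim` d values.
#' @export
brownian_threshold_null <- function(tree, trait, n_sim, seed) {
  stopifnot(n_sim >= 1)
  v <- as_binary_trait(trait, tree, allow_missing = FALSE)
  if (all(tree$edge.length == 0)) stop("all branch lengths are zero")
  k <- sum(v == 1)
  ntip <- length(tree$tip.label)
  set.seed(seed)
  cl <- stats::reorder(tree, "cladewise")
  x <- matrix(0, ntip + tree$Nnode, n_sim)
  for (e in seq_len(nrow(cl$edge))) {     # root-first: parents before children
    p <- cl$edge[e, 1]; ch <- cl$edge[e, 2]
    x[ch, ] <- x[p, ] + sqrt(cl$edge.length[e]) * stats::rnorm(n_sim)
  }
  tips <- x[seq_len(ntip), , drop = FALSE] +
    matrix(stats::runif(ntip * n_sim), ntip) * 1e-12
  bin <- apply(tips, 2, function(col) as.numeric(rank(col) > ntip - k))
  pe <- postorder_edge(tree)
  as.numeric(cpp_sister_diff_sum(pe$edge, bin, tree$Nnode))
}

#' The D phylogenetic-signal statistic for a binary trait
#'
#' Prunes tips with missing trait values, computes the observed
#' sister-difference sum and the means of the shuffle and Brownian-threshold
#' nulls, and returns the scaled statistic
#' `D = (d_obs - mean_brownian) / (mean_shuffle - mean_brownian)`,
#' so that D is calibrated at 1 under random shuffling and at 0 under the
#' thresholded Brownian model; D < 0 indicates overclumping and D > 1
#' overdispersion.
#'
#' @param tree A binary ultrametric `phylo` tree.
#' @param trait Tip values with possible missing entries (numeric 0/1/NA or
#'   character present/absent/missing), named by tip label.
#' @param n_sim Replicates per null (default 1000).
#' @param seed Integer seed.
#' @return Object of class `d_result`: list with `d_obs`, `d_random_mean`,
#'   `d_brownian_mean`, `D`, `n_sim`, `status` (one of `ok`,
#'   `undefined_constant`, `undefined_degenerate`) and `n_tips_used`.
#'   `D` is `NA` whenever `status != "ok"`.
#' @export
compute_D <- function(tree, trait, n_sim = 1000, seed = 1) {
  v <- as_binary_trait(trait, tree, allow_missing = TRUE)
  names(v) <- tree$tip.label
  keep <- names(v)[!is.na(v)]
  res <- structure(list(d_obs = NA_real_, d_random_mean = NA_real_,
                        d_brownian_mean = NA_real_, D = NA_real_,
                        n_sim = n_sim, status = "ok",
                        n_tips_used = length(keep)),
                   class = "d_result")
  if (length(keep) < 4) { res$status <- "undefined_degenerate"; return(res) }
  sub <- if (length(keep) == length(v)) tree else ape::keep.tip(tree, keep)
  vv <- v[sub$tip.label]
  if (length(unique(vv)) < 2) { res$status <- "undefined_constant"; return(res) }
  res$d_obs <- sister_diff_sum(sub, vv)
  res$d_random_mean <- mean(shuffle_null(sub, vv, n_sim, seed))
  res$d_brownian_mean <- mean(brownian_threshold_null(sub, vv, n_sim,
                                                      seed + 1L))
  denom <- res$d_random_mean - res$d_brownian_mean
  if (abs(denom) < 1e-12) { res$status <- "undefined_degenerate"; return(res) }
  res$D <- (res$d_obs - res$d_brownian_mean) / denom
  res
}

#' @export
print.d_result <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("D = %.4f (d_obs %.3f, shuffle mean %.3f, Brownian mean %.3f, %d sims, %d tips)\n",
                x$D, x$d_obs, x$d_random_mean, x$d_brownian_mean, x$n_sim,
                x$n_tips_used))
  else cat(sprintf("D undefined (%s, %d tips)\n", x$status, x$n_tips_used))
  invisible(x)
}

#' Median D over a tree posterior
#'
#' Computes D per tree and summarizes by the median over trees with a
#' defined value.
#'
#' @param posterior A `tree_posterior` or `multiPhylo`.
#' @inheritParams compute_D
#' @return List with `median_D` (NA if no tree yields a defined value, with
#'   `reason`), `per_tree` (data.frame: tree, D, status), `n_ok`, `n_not_ok`.
#' @export
median_D <- function(posterior, trait, n_sim = 1000, seed = 1) {
  trees <- if (inherits(posterior, "tree_posterior")) posterior$trees
           else posterior
  per <- lapply(seq_along(trees), function(i)
    compute_D(trees[[i]], trait, n_sim = n_sim, seed = seed + 2L * (i - 1L)))
  df <- data.frame(tree = seq_along(trees),
                   D = vapply(per, function(r) r$D, 0),
                   status = vapply(per, function(r) r$status, ""))
  ok <- df$status == "ok"
  out <- list(median_D = NA_real_, per_tree = df,
              n_ok = sum(ok), n_not_ok = sum(!ok), reason = NULL)
  if (!any(ok)) {
    out$reason <- if (all(df$status == "undefined_constant"))
      "trait constant on every tree after pruning" else
      "no tree yielded a defined D"
  } else out$median_D <- stats::median(df$D[ok])
  out
}
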