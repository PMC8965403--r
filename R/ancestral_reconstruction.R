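#' Marginal ancestral state reconstruction under the hidden-rates model
#'
#' For every node (tips included) the marginal probability of each hidden
#' state, integrating over the states at all other nodes: the normalized
#' product of the down-pass (subtree) partial and the up-pass (rest-of-tree)
#' partial, with the root handled by the conditional-likelihood weighting of
#' [root_weighting()]. The probability of `present` at a node is
#' `P(1S) + P(1F)` (collapsed over rate classes).
#'
#' @inheritParams pruning_loglik
#' @return Object of class `ancestral_reconstruction`: list with `probs`
#'   (matrix, rows = nodes in `1..(ntip+Nnode)` ape numbering, columns =
#'   hidden states), `p_present`, `loglik`, `log_joint` (per-node
#'   log of the marginal identity, equal to `loglik` for every node),
#'   and `tree`.
#' @export
marginal_asr <- function(tree, trait, Q) {
  if (!ape::is.binary(tree)) stop("tree must be strictly binary")
  pe <- postorder_edge(tree)
  tp <- tip_partials_hidden(tree, trait)
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  dn <- cpp_down_partials(pe$edge, pe$len, tp, Q, tree$Nnode)
  d <- dn$partials                 # 4 x ntot, scaled; true = d * exp(Fv)
  Fv <- as.numeric(dn$log_scale)
  root <- pe$edge[nrow(pe$edge), 1]
  rw <- root_weighting(d[, root])
  loglik <- log(rw$likelihood) + Fv[root]
  # up pass, root-first over edges; S_c = t(P_c) %*% (S_u * W_sib)
  cl <- stats::reorder(tree, "cladewise")
  s <- matrix(0, 4, ntot)
  Gv <- numeric(ntot)
  s[, root] <- rw$prior
  child_of <- split(seq_len(nrow(cl$edge)), cl$edge[, 1])
  for (e in seq_len(nrow(cl$edge))) {
    u <- cl$edge[e, 1]; ch <- cl$edge[e, 2]
    sibs <- setdiff(cl$edge[child_of[[as.character(u)]], 2], ch)
    sib_e <- child_of[[as.character(u)]][cl$edge[child_of[[as.character(u)]], 2] == sibs]
    W <- cpp_expm(Q, cl$edge.length[sib_e]) %*% d[, sibs]
    raw <- t(cpp_expm(Q, cl$edge.length[e])) %*% (s[, u] * W)
    m <- max(raw)
    s[, ch] <- raw / m
    Gv[ch] <- Gv[u] + Fv[sibs] + log(m)
  }
  joint <- d * s                    # 4 x ntot
  tot <- colSums(joint)
  probs <- t(joint) / tot
  colnames(probs) <- HIDDEN_STATES
  structure(list(probs = probs,
                 p_present = unname(probs[, "1S"] + probs[, "1F"]),
                 loglik = loglik,
                 log_joint = log(tot) + Fv + Gv,
                 tree = tree),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("marginal reconstruction: %d nodes, logL %.4f, root P(present) %.3f\n",
              nrow(x$probs), x$loglik,
              x$p_present[length(x$tree$tip.label) + 1]))
  invisible(x)
}

#' Probability of presence at a family's most recent common ancestor
#'
#' @param asr An [marginal_asr()] result.
#' @param family Family label.
#' @param families Named character vector mapping taxa to families.
#' @return `p_present` at the MRCA node of the family's tips.
#' @export
family_root_presence <- function(asr, family, families) {
  tree <- asr$tree
  tips <- intersect(tree$tip.label, names(families)[families == family])
  if (length(tips) < 2)
    stop("family '", family, "' has fewer than 2 tips in the tree")
  node <- ape::getMRCA(tree, tips)
  asr$p_present[node]
}

#' Band summary of proto-language reconstructability
#'
#' Classifies per-feature family-root presence probabilities into the nested
#' certainty thresholds (reconstructable as present at >= 0.95 / >= 0.75, as
#' absent at <= 0.05 / <= 0.25) and into five exclusive bands that partition
#' the features.
#'
#' @param root_probs Numeric matrix, features x families, of `p_present` at
#'   each family root.
#' @param thresholds Upper certainty thresholds (default `c(0.95, 0.75)`).
#' @return List with `per_family` (data.frame of nested proportions:
#'   `present_95`, `present_75`, `absent_05`, `absent_25`, `uncertain`, and
#'   matching counts) and `bands` (features x families factor matrix over
#'   the five exclusive bands).
#' @export
reconstructability_summary <- function(root_probs,
                                       thresholds = c(0.95, 0.75)) {
  stopifnot(is.matrix(root_probs) || is.data.frame(root_probs))
  root_probs <- as.matrix(root_probs)
  if (any(root_probs < 0 | root_probs > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  hi <- max(thresholds); lo <- min(thresholds)
  band_of <- function(p)
    ifelse(p >= hi, "present_95",
      ifelse(p >= lo, "present_75",
        ifelse(p <= 1 - hi, "absent_05",
          ifelse(p <= 1 - lo, "absent_25", "uncertain"))))
  bands <- apply(root_probs, 2, band_of)
  rownames(bands) <- rownames(root_probs)
  per <- data.frame(family = colnames(root_probs), row.names = NULL)
  n <- nrow(root_probs)
  per$n_features <- n
  per$present_95 <- colMeans(root_probs >= hi)
  per$present_75 <- colMeans(root_probs >= lo)
  per$absent_05 <- colMeans(root_probs <= 1 - hi)
  per$absent_25 <- colMeans(root_probs <= 1 - lo)
  per$uncertain <- colMeans(root_probs > 1 - lo & root_probs < lo)
  per$n_present_95 <- colSums(root_probs >= hi)
  per$n_present_75 <- colSums(root_probs >= lo)
  per$n_absent_05 <- colSums(root_probs <= 1 - hi)
  per$n_absent_25 <- colSums(root_probs <= 1 - lo)
  per$n_uncertain <- colSums(root_probs > 1 - lo & root_probs < lo)
  list(per_family = per, bands = bands)
}

#' Category-normalized reconstructable-feature proportions
#'
#' Proportion of a category's features reconstructable as present
#' (`p >= threshold`) at each family root, normalized by category size so
#' large categories do not dominate.
#'
#' @inheritParams reconstructability_summary
#' @param catalog Feature catalogue (see [read_feature_catalog()]) covering
#'   every feature in `root_probs`.
#' @param axis One of `"functional_category"`, `"domain"`,
#'   `"part_of_speech"`.
#' @param threshold Certainty threshold (default 0.95).
#' @return data.frame: family, category, `n_category` (category size),
#'   `n_reconstructed`, `proportion`. Empty categories are absent by
#'   construction (every feature is categorized).
#' @export
category_normalized_reconstruction <- function(root_probs, catalog,
                                               axis = c("functional_category",
                                                        "domain",
                                                        "part_of_speech"),
                                               threshold = 0.95) {
  axis <- match.arg(axis)
  root_probs <- as.matrix(root_probs)
  feats <- rownames(root_probs)
  miss <- setdiff(feats, catalog$feature)
  if (length(miss) > 0)
    stop("features without catalogue entry: ", paste(miss, collapse = ", "))
  cat_of <- catalog[[axis]][match(feats, catalog$feature)]
  out <- expand.grid(family = colnames(root_probs),
                     category = unique(cat_of),
                     stringsAsFactors = FALSE)
  out$n_category <- as.integer(table(cat_of)[out$category])
  out$n_reconstructed <- mapply(function(fam, cc)
    sum(root_probs[cat_of == cc, fam] >= threshold), out$family, out$category)
  out$proportion <- out$n_reconstructed / out$n_category
  out[order(out$family, out$category), ]
}

#' Pairwise family overlap in reconstructable features
#'
#' Percentage of all features reconstructable as present (`p >= threshold`)
#' at the roots of both families of a pair.
#'
#' @inheritParams category_normalized_reconstruction
#' @return List with `percent` (symmetric family x family matrix, diagonal
#'   `NA`, values `100 * shared / total features`) and `counts` (raw shared
#'   feature counts).
#' @export
pairwise_family_overlap <- function(root_probs, threshold = 0.95) {
  root_probs <- as.matrix(root_probs)
  if (ncol(root_probs) < 2) stop("need at least two families")
  rec <- root_probs >= threshold
  counts <- t(rec) %*% rec
  pct <- 100 * counts / nrow(root_probs)
  diag(pct) <- NA
  diag(counts) <- NA
  list(percent = pct, counts = counts)
}

#' Distance between a proto-language and its child languages
#'
#' Restricts to features reconstructable as present at the family root
#' (`p >= threshold`) and counts, for each tip in the family, the features
#' whose observed value differs from `present`. Missing values are excluded
#' from the difference count and reported separately.
#'
#' @param root_probs Named numeric vector: per-feature `p_present` at the
#'   family's root.
#' @param matrix A [feature_matrix()] holding the observed tip values.
#' @param family Family label.
#' @param threshold Certainty threshold (default 0.95).
#' @return data.frame: taxon, `n_reconstructed` (features compared),
#'   `n_differ`, `n_missing`.
#' @export
proto_child_distance <- function(root_probs, matrix, family,
                                 threshold = 0.95) {
  stopifnot(inherits(matrix, "feature_matrix"))
  feats <- names(root_probs)[root_probs >= threshold]
  feats <- intersect(feats, matrix$features)
  taxa <- matrix$taxa[matrix$families == family]
  if (length(taxa) == 0) stop("no taxa in family '", family, "'")
  vals <- matrix$values[taxa, feats, drop = FALSE]
  data.frame(taxon = taxa,
             n_reconstructed = length(feats),
             n_differ = rowSums(vals == "absent"),
             n_missing = rowSums(vals == "missing"),
             row.names = NULL)
}
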