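# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: series expansions, exhaustive
# enumeration, O(n^2) pair counting.

# Truncated Taylor-series matrix exponential.
series_expm <- function(Q, t, terms = 80) {
  A <- Q * t
  P <- diag(nrow(Q))
  term <- diag(nrow(Q))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    P <- P + term
  }
  P
}

# Tip partial sets for the 4-state hidden model (state order 0S,0F,1S,1F).
allowed_states <- function(value) {
  if (is.na(value)) 1:4 else if (value == 1) 3:4 else 1:2
}

# Exhaustive-enumeration likelihood: sums over every assignment of hidden
# states to internal nodes, collapsing each tip analytically over its
# allowed set. Root treated with conditional-likelihood weights.
enum_root_conditionals <- function(tree, trait, Q, k = 4) {
  trait <- trait[tree$tip.label]
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  root <- ntip + 1
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) series_expm(Q, tree$edge.length[e]))
  L <- numeric(k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + tree$Nnode)
    st[nodes] <- grid[g, ]
    p <- 1
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      p <- p * if (ch <= ntip)
        sum(P[[e]][st[par], allowed_states(trait[ch])])
      else P[[e]][st[par], st[ch]]
    }
    L[st[root]] <- L[st[root]] + p
  }
  L
}

enum_loglik <- function(tree, trait, Q, k = 4) {
  L <- enum_root_conditionals(tree, trait, Q, k)
  log(sum(L^2) / sum(L))
}

# Exhaustive marginal probabilities at one internal node.
enum_marginal <- function(tree, trait, Q, node, k = 4) {
  trait <- trait[tree$tip.label]
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  root <- ntip + 1
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) series_expm(Q, tree$edge.length[e]))
  prior <- enum_root_conditionals(tree, trait, Q, k)
  prior <- prior / sum(prior)
  marg <- numeric(k)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tree$Nnode)))
  for (g in seq_len(nrow(grid))) {
    st <- integer(ntip + tree$Nnode)
    st[nodes] <- grid[g, ]
    p <- prior[st[root]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      p <- p * if (ch <= ntip)
        sum(P[[e]][st[par], allowed_states(trait[ch])])
      else P[[e]][st[par], st[ch]]
    }
    marg[st[node]] <- marg[st[node]] + p
  }
  marg / sum(marg)
}

# Plain 2-state ARD pruning likelihood (states 0, 1), FitzJohn root.
two_state_loglik <- function(tree, trait, gain, loss) {
  trait <- trait[tree$tip.label]
  Q <- matrix(c(-gain, loss, gain, -loss), 2, 2)
  ntip <- length(tree$tip.label)
  po <- reorder(tree, "postorder")
  part <- matrix(1, 2, ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    if (!is.na(trait[i])) part[, i] <- if (trait[i] == 1) c(0, 1) else c(1, 0)
  }
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    part[, par] <- part[, par] * (series_expm(Q, po$edge.length[e]) %*% part[, ch])
  }
  L <- part[, po$edge[nrow(po$edge), 1]]
  log(sum(L^2) / sum(L))
}

# O(n^2) tie-corrected Kendall tau-b by direct pair counting.
brute_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) next
    else if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# Exact probability, under uniform labeled histories (uniform sequential
# pair joining), that a given tip set appears as a clade. Recursive
# enumeration over all join choices.
lh_clade_prob <- function(lineages, target) {
  k <- length(lineages)
  if (k == 1) return(0)
  npair <- k * (k - 1) / 2
  total <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    merged <- sort(c(lineages[[i]], lineages[[j]]))
    hit <- identical(merged, sort(target))
    rest <- c(lineages[-c(i, j)], list(merged))
    total <- total + (if (hit) 1 else lh_clade_prob(rest, target)) / npair
  }
  total
}

# Small fixture trees.
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
tree5 <- function()
  ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1.5,E:1.5):1.5);")
tree6 <- function()
  ape::read.tree(
    text = "(((A:0.4,B:0.4):0.9,(C:0.7,D:0.7):0.6):0.7,(E:1.1,F:1.1):0.9);")

rate_vec <- function(gain_S, loss_S, gain_F, loss_F,
                     class_up_0, class_down_0, class_up_1, class_down_1) {
  c(gain_S = gain_S, loss_S = loss_S, gain_F = gain_F, loss_F = loss_F,
    class_up_0 = class_up_0, class_down_0 = class_down_0,
    class_up_1 = class_up_1, class_down_1 = class_down_1)
}

random_rates <- function(seed) {
  set.seed(seed)
  r <- exp(runif(8, log(0.05), log(5)))
  rate_vec(r[1], r[2], r[3], r[4], r[5], r[6], r[7], r[8])
}

write_toy_matrix <- function(path, body) {
  writeLines(body, path)
  path
}
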