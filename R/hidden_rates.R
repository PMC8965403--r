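RATE_LOWER <- 1e-10
RATE_UPPER <- 100

HIDDEN_STATES <- c("0S", "0F", "1S", "1F")

RATE_NAMES <- c("gain_S", "loss_S", "gain_F", "loss_F",
                "class_up_0", "class_down_0", "class_up_1", "class_down_1")

#' Build the 4x4 hidden-rates generator from the eight named rates
#'
#' States are ordered `0S, 0F, 1S, 1F` (observed value x rate class, S =
#' slow, F = fast). Gains and losses act within a class, class switches
#' within an observed value; entries that would change value and class
#' simultaneously (dual transitions) are structurally zero. The diagonal is
#' minus the row sum.
#'
#' @param rates Named numeric vector with elements `gain_S` (0S->1S),
#'   `loss_S` (1S->0S), `gain_F` (0F->1F), `loss_F` (1F->0F), `class_up_0`
#'   (0S->0F), `class_down_0` (0F->0S), `class_up_1` (1S->1F),
#'   `class_down_1` (1F->1S). All must lie in `[1e-10, 100]`.
#' @return 4x4 generator matrix with dimnames `HIDDEN_STATES`.
#' @export
hidden_rate_matrix <- function(rates) {
  if (is.null(names(rates)) || !all(RATE_NAMES %in% names(rates)))
    stop("'rates' must be named: ", paste(RATE_NAMES, collapse = ", "))
  r <- rates[RATE_NAMES]
  if (any(r < RATE_LOWER - 1e-15 | r > RATE_UPPER))
    stop(sprintf("rates must lie in [%g, %g]", RATE_LOWER, RATE_UPPER))
  Q <- matrix(0, 4, 4, dimnames = list(HIDDEN_STATES, HIDDEN_STATES))
  Q["0S", "1S"] <- r[["gain_S"]]
  Q["1S", "0S"] <- r[["loss_S"]]
  Q["0F", "1F"] <- r[["gain_F"]]
  Q["1F", "0F"] <- r[["loss_F"]]
  Q["0S", "0F"] <- r[["class_up_0"]]
  Q["0F", "0S"] <- r[["class_down_0"]]
  Q["1S", "1F"] <- r[["class_up_1"]]
  Q["1F", "1S"] <- r[["class_down_1"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix over a branch
#'
#' `exp(Q t)` for a generator `Q` and nonnegative branch length `t`.
#'
#' @param Q Square generator matrix (rows sum to 0).
#' @param t Branch length (>= 0).
#' @return Row-stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("negative branch length")
  P <- cpp_expm(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}

# Tip partial likelihoods, 4 x ntip, in tree tip order.
# present -> (0,0,1,1); absent -> (1,1,0,0); missing -> all ones (the model
# treats '?' tips as ambiguous 0/1, never by deletion).
tip_partials_hidden <- function(tree, trait) {
  v <- as_binary_trait(trait, tree, allow_missing = TRUE)
  tp <- matrix(1, 4, length(v))
  tp[3:4, which(!is.na(v) & v == 0)] <- 0
  tp[1:2, which(!is.na(v) & v == 1)] <- 0
  tp
}

#' Pruning log-likelihood of a binary trait under the hidden-rates model
#'
#' Felsenstein's post-order pruning over the four hidden states, with the
#' root handled by [root_weighting()] (conditional-likelihood weights).
#' Missing tips enter as ambiguous (all-ones partials).
#'
#' @param tree Binary `phylo` tree with finite branch lengths.
#' @param trait Tip values (0/1/NA numeric or present/absent/missing
#'   character), named by tip label.
#' @param Q 4x4 generator from [hidden_rate_matrix()].
#' @return Log-likelihood (finite, <= 0 for any data with at least one
#'   observed tip).
#' @export
pruning_loglik <- function(tree, trait, Q) {
  if (!ape::is.binary(tree)) stop("tree must be strictly binary")
  if (any(!is.finite(tree$edge.length))) stop("non-finite branch length")
  pe <- postorder_edge(tree)
  res <- cpp_pruning(pe$edge, pe$len, tip_partials_hidden(tree, trait), Q,
                     tree$Nnode)
  res$loglik
}

#' Conditional-likelihood root treatment
#'
#' Root prior weights proportional to the root's conditional likelihoods
#' (`prior_i = L_i / sum_j L_j`), combined likelihood
#' `sum_i prior_i * L_i`.
#'
#' @param root_partials Nonnegative vector of root conditional likelihoods,
#'   not all zero.
#' @return List with `prior` (normalized weights) and `likelihood`.
#' @export
root_weighting <- function(root_partials) {
  if (any(root_partials < 0) || all(root_partials == 0))
    stop("root partials must be nonnegative and not all zero")
  prior <- root_partials / sum(root_partials)
  list(prior = prior, likelihood = sum(prior * root_partials))
}

#' Maximum-likelihood fit of the hidden-rates model
#'
#' Maximizes [pruning_loglik()] over the eight transition rates in log-rate
#' space with bound constraints `[1e-10, 100]`, using L-BFGS-B with
#' `n_starts` random restarts (start points log-uniform over the bounds,
#' derived deterministically from `seed`). The per-feature summary gain and
#' loss rates are the class-occupancy-weighted averages of the slow and fast
#' class rates ([summarize_rates()]), with occupancy taken from the marginal
#' reconstruction under the fitted model.
#'
#' @inheritParams pruning_loglik
#' @param seed Integer seed.
#' @param n_starts Number of random restarts (default 5).
#' @return Object of class `hidden_rate_fit`: list with `rates` (named
#'   8-vector), `Q`, `log_likelihood`, `n_starts`, `converged`,
#'   `summary_gain`, `summary_loss`, `occupancy`.
#' @export
fit_hidden_rates <- function(tree, trait, seed = 1, n_starts = 5) {
  v <- as_binary_trait(trait, tree, allow_missing = TRUE)
  if (all(is.na(v))) stop("trait needs at least one non-missing tip")
  pe <- postorder_edge(tree)
  tp <- tip_partials_hidden(tree, trait)
  lb <- log(RATE_LOWER); ub <- log(RATE_UPPER)
  negll <- function(logr) {
    # clamp: finite-difference gradient steps may poke just past the bounds
    r <- pmin(pmax(exp(logr), RATE_LOWER), RATE_UPPER)
    Q <- hidden_rate_matrix(stats::setNames(r, RATE_NAMES))
    -cpp_pruning(pe$edge, pe$len, tp, Q, tree$Nnode)$loglik
  }
  # informed start: maximum-likelihood 2-state fit; the 8-parameter search
  # begins at tied classes with slow class switching, a point where the
  # hidden-rates likelihood equals the 2-state one, and can only improve
  tp2 <- matrix(1, 2, length(v))
  tp2[2, which(!is.na(v) & v == 0)] <- 0
  tp2[1, which(!is.na(v) & v == 1)] <- 0
  negll2 <- function(logr) {
    r <- pmin(pmax(exp(logr), RATE_LOWER), RATE_UPPER)
    Q2 <- matrix(c(-r[1], r[2], r[1], -r[2]), 2, 2)
    -cpp_pruning(pe$edge, pe$len, tp2, Q2, tree$Nnode)$loglik
  }
  opt2 <- tryCatch(
    stats::optim(c(log(0.5), log(0.5)), negll2, method = "L-BFGS-B",
                 lower = lb, upper = ub, control = list(maxit = 500)),
    error = function(e) list(par = c(log(0.5), log(0.5))))
  tied <- pmin(pmax(exp(opt2$par), RATE_LOWER), RATE_UPPER)
  best <- NULL
  converged <- FALSE
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    start <- if (s == 1)
      log(c(tied[1], tied[2], tied[1], tied[2], rep(0.05, 4)))
    else stats::runif(8, lb, ub)
    opt <- tryCatch(
      stats::optim(start, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) converged <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed in every start")
  rates <- stats::setNames(pmin(exp(best$par), RATE_UPPER), RATE_NAMES)
  # rates numerically indistinguishable from zero on a height-1 tree are
  # reported at the floor (the likelihood is flat below this scale)
  rates[rates < 1e-8] <- RATE_LOWER
  Q <- hidden_rate_matrix(rates)
  asr <- marginal_asr(tree, trait, Q)
  p <- colMeans(asr$probs)
  occ <- unname(p["0F"] + p["1F"])
  # per-direction class occupancy, conditional on the observed state the
  # transition leaves from: the summary gain rate is the average gain rate
  # experienced while absent, and likewise for loss (falls back to the
  # overall fast-class occupancy when a state is never visited)
  occ_gain <- if (p["0S"] + p["0F"] > 1e-12)
    unname(p["0F"] / (p["0S"] + p["0F"])) else occ
  occ_loss <- if (p["1S"] + p["1F"] > 1e-12)
    unname(p["1F"] / (p["1S"] + p["1F"])) else occ
  s <- summarize_rates(rates, c(gain = occ_gain, loss = occ_loss))
  s[s < 1e-8] <- RATE_LOWER   # same reporting floor as the raw rates
  structure(list(rates = rates, Q = Q, log_likelihood = -best$value,
                 n_starts = n_starts, converged = converged,
                 summary_gain = s[["summary_gain"]],
                 summary_loss = s[["summary_loss"]],
                 occupancy = occ, occupancy_gain = occ_gain,
                 occupancy_loss = occ_loss),
            class = "hidden_rate_fit")
}

#' @export
print.hidden_rate_fit <- function(x, ...) {
  cat(sprintf("hidden-rates fit: logL %.4f (%d starts, converged: %s)\n",
              x$log_likelihood, x$n_starts, x$converged))
  cat(sprintf("  summary gain %.4g, summary loss %.4g, fast-class occupancy %.3f\n",
              x$summary_gain, x$summary_loss, x$occupancy))
  print(round(x$rates, 6))
  invisible(x)
}

#' Collapse the eight fitted rates to one gain and one loss rate
#'
#' The per-feature summary rate is the average of the slow- and fast-class
#' rates weighted by the fast-class occupancy. [fit_hidden_rates()] supplies
#' per-direction occupancies conditional on the observed state the
#' transition leaves from (marginal class probability while absent for the
#' gain rate, while present for the loss rate), computed over all tips and
#' internal nodes of the reconstruction; a single scalar occupancy applies
#' the same weight to both directions.
#'
#' @param rates Named 8-vector as in [hidden_rate_matrix()].
#' @param occupancy Probability of the fast class, in `[0, 1]`: either a
#'   scalar or a vector `c(gain = , loss = )` of per-direction occupancies.
#' @return Named vector `c(summary_gain, summary_loss)`.
#' @export
summarize_rates <- function(rates, occupancy) {
  stopifnot(all(occupancy >= 0), all(occupancy <= 1))
  if (length(occupancy) == 1) occupancy <- c(gain = unname(occupancy),
                                             loss = unname(occupancy))
  c(summary_gain = unname((1 - occupancy[["gain"]]) * rates[["gain_S"]] +
                            occupancy[["gain"]] * rates[["gain_F"]]),
    summary_loss = unname((1 - occupancy[["loss"]]) * rates[["loss_S"]] +
                            occupancy[["loss"]] * rates[["loss_F"]]))
}

#' Log10 transform of a rate with the reporting floor
#'
#' Rates at (or reported as) zero map to -10, the lower rate bound on the
#' log10 scale.
#'
#' @param rate Nonnegative rate.
#' @return `log10(max(rate, 1e-10))`.
#' @export
log10_rate <- function(rate) {
  if (any(rate < 0)) stop("negative rate")
  log10(pmax(rate, RATE_LOWER))
}
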