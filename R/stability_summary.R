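#' Kendall rank correlation (tau-b) with tie correction
#'
#' Wrapper around [stats::cor.test()] with `method = "kendall"`:
#' tie-corrected tau-b and the normal-approximation p-value. Pairs with an
#' undefined entry in either vector are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 defined pairs).
#' @return List with `tau` and `p_value`; errors if either vector is
#'   constant over the defined pairs (tau undefined).
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 defined pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("tau undefined: all values tied")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Bin a median D value into the four signal categories
#'
#' `D < 0` overclumped; `0 <= D <= 0.5` phylogenetic signal; `0.5 < D <= 1`
#' random; `D > 1` overdispersed. The signal interval is closed at both
#' ends so the four verbal ranges are exhaustive.
#'
#' @param D Numeric vector of median D values (NA allowed).
#' @return Character vector over
#'   `{overclumped, signal, random, overdispersed}`; NA where D is NA.
#' @export
bin_D <- function(D) {
  ifelse(is.na(D), NA_character_,
    ifelse(D < 0, "overclumped",
      ifelse(D <= 0.5, "signal",
        ifelse(D <= 1, "random", "overdispersed"))))
}

#' Bin a log10 rate into slow / medium / fast
#'
#' Cutoffs at -0.5 and 0.5; the boundaries belong to `medium` (closed
#' interval).
#'
#' @param r Numeric vector of log10-transformed rates.
#' @return Character vector over `{slow, medium, fast}`.
#' @export
bin_rate <- function(r) {
  ifelse(is.na(r), NA_character_,
    ifelse(r < -0.5, "slow", ifelse(r <= 0.5, "medium", "fast")))
}

#' Assemble the per-feature stability table
#'
#' @param feature Character vector of feature ids.
#' @param median_D Per-feature median D over the tree posterior (NA where
#'   undefined).
#' @param median_log_gain,median_log_loss Per-feature median log10 summary
#'   rates.
#' @return data.frame with the inputs plus `D_bin`, `gain_bin`, `loss_bin`.
#' @export
feature_stability <- function(feature, median_D, median_log_gain,
                              median_log_loss) {
  data.frame(feature = feature, median_D = median_D,
             median_log_gain = median_log_gain,
             median_log_loss = median_log_loss,
             D_bin = bin_D(median_D),
             gain_bin = bin_rate(median_log_gain),
             loss_bin = bin_rate(median_log_loss),
             stringsAsFactors = FALSE)
}

#' Per-category medians of signal and rate
#'
#' @param stability A [feature_stability()] data.frame.
#' @param catalog Feature catalogue covering every feature.
#' @param axis One of `"functional_category"`, `"domain"`,
#'   `"part_of_speech"`.
#' @return data.frame: category, `n`, `n_undefined_D`, `median_D`,
#'   `median_log_gain`, `median_log_loss` (medians over defined values).
#' @export
category_medians <- function(stability, catalog,
                             axis = c("functional_category", "domain",
                                      "part_of_speech")) {
  axis <- match.arg(axis)
  miss <- setdiff(stability$feature, catalog$feature)
  if (length(miss) > 0)
    stop("features without catalogue entry: ", paste(miss, collapse = ", "))
  cat_of <- catalog[[axis]][match(stability$feature, catalog$feature)]
  med <- function(v) if (all(is.na(v))) NA_real_ else
    stats::median(v, na.rm = TRUE)
  out <- do.call(rbind, lapply(split(stability, cat_of), function(g)
    data.frame(category = cat_of[match(g$feature[1], stability$feature)],
               n = nrow(g),
               n_undefined_D = sum(is.na(g$median_D)),
               median_D = med(g$median_D),
               median_log_gain = med(g$median_log_gain),
               median_log_loss = med(g$median_log_loss),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$category), ]
}

#' Cross-feature summary of signal and rate distributions
#'
#' Order statistics (min, median, max, sample s.d.) per metric, the bin
#' proportions of [bin_D()] and [bin_rate()], and the coarse splits used in
#' prose summaries: D below/above 0.5 and log10 rate below/above 0.
#'
#' @param stability A [feature_stability()] data.frame.
#' @return List with `metrics` (data.frame of order statistics),
#'   `D_bin_proportions`, `gain_bin_proportions`, `loss_bin_proportions`,
#'   and `coarse_splits`.
#' @export
overall_summary <- function(stability) {
  stats_of <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(c(min = NA, median = NA, max = NA, sd = NA, n = 0))
    c(min = min(v), median = stats::median(v), max = max(v),
      sd = stats::sd(v), n = length(v))
  }
  metrics <- rbind(D = stats_of(stability$median_D),
                   log_gain = stats_of(stability$median_log_gain),
                   log_loss = stats_of(stability$median_log_loss))
  prop <- function(bins, levels) {
    b <- bins[!is.na(bins)]
    if (length(b) == 0) return(stats::setNames(rep(NA_real_, length(levels)),
                                               levels))
    tb <- table(factor(b, levels = levels)) / length(b)
    stats::setNames(as.numeric(tb), names(tb))
  }
  D_ok <- stability$median_D[!is.na(stability$median_D)]
  gain_ok <- stability$median_log_gain[!is.na(stability$median_log_gain)]
  loss_ok <- stability$median_log_loss[!is.na(stability$median_log_loss)]
  list(metrics = as.data.frame(metrics),
       D_bin_proportions = prop(stability$D_bin,
                                c("overclumped", "signal", "random",
                                  "overdispersed")),
       gain_bin_proportions = prop(stability$gain_bin,
                                   c("slow", "medium", "fast")),
       loss_bin_proportions = prop(stability$loss_bin,
                                   c("slow", "medium", "fast")),
       coarse_splits = list(
         D_below_0.5 = mean(D_ok <= 0.5),
         D_above_0.5 = mean(D_ok > 0.5),
         gain_below_0 = mean(gain_ok < 0),
         gain_above_0 = mean(gain_ok >= 0),
         loss_below_0 = mean(loss_ok < 0),
         loss_above_0 = mean(loss_ok >= 0)))
}

#' Correlation between phylogenetic signal and evolutionary rate
#'
#' Kendall's tau between per-feature median D and median log10 rate,
#' computed both including and excluding features whose raw rate sits at
#' the zero floor (log10 rate of -10), since those features are either
#' present nearly everywhere or absent nearly everywhere and their rate is
#' not informative.
#'
#' @param stability A [feature_stability()] data.frame.
#' @param direction `"gain"` or `"loss"`.
#' @return data.frame with rows `all` and `excluding_floored`: n, tau,
#'   p_value.
#' @export
signal_rate_correlation <- function(stability,
                                    direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  r <- if (direction == "gain") stability$median_log_gain
       else stability$median_log_loss
  run <- function(keep) {
    x <- stability$median_D[keep]; y <- r[keep]
    kt <- tryCatch(kendall_tau(x, y),
                   error = function(e) list(tau = NA_real_,
                                            p_value = NA_real_))
    data.frame(n = sum(!is.na(x) & !is.na(y)), tau = kt$tau,
               p_value = kt$p_value)
  }
  out <- rbind(run(rep(TRUE, nrow(stability))), run(!is.na(r) & r > -10))
  out <- cbind(variant = c("all", "excluding_floored"), out)
  out
}
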