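#' Westfall-Young maxT thresholds and multiple-testing baselines
#'
#' Per permutation the maximal test statistic over all markers (equivalently
#' the minimal p-value) estimates the family-wise null distribution; the
#' significance threshold is the `alpha`-percentile of the minimal p-values,
#' and adjusted per-marker p-values count how often a permutation maximum
#' reaches each observed statistic.
#'
#' @name significance
NULL

#' Row-wise minimal p-value per permutation
#'
#' @param p_matrix q x m matrix of permutation p-values in `(0, 1]`; markers
#'   with missing values must be excluded beforehand.
#' @return length-q vector.
#' @export
min_p_per_permutation <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  if (ncol(p_matrix) == 0) stop_pl("empty marker set")
  if (anyNA(p_matrix)) stop_pl("missing values in permutation p-values; drop failed markers first")
  apply(p_matrix, 1, min)
}

#' Permutation-based significance threshold
#'
#' The empirical `alpha`-quantile of the per-permutation minimal p-values,
#' with linear interpolation between order statistics at `h = (q - 1) alpha`
#' (the convention of [stats::quantile()] type 7). The convention is recorded
#' in result metadata because the percentile definition matters at small `q`.
#'
#' @param min_p per-permutation minimal p-values.
#' @param alpha significance level in `(0, 1)`.
#' @return scalar threshold.
#' @export
permutation_threshold <- function(min_p, alpha = 0.05) {
  check_probability(alpha, "alpha")
  if (length(min_p) == 0) stop_pl("no permutations")
  unname(quantile(min_p, probs = alpha, type = 7, names = FALSE))
}

#' Adjusted permutation p-values
#'
#' `p_i = #{k : tmax_k >= t_i} / q`, the fraction of permutation maxima at or
#' above each observed statistic. With `plus_one = TRUE` the
#' `(count + 1) / (q + 1)` variant is used instead, which cannot return an
#' adjusted p-value of exactly 0.
#'
#' @param t observed per-marker statistics (length m).
#' @param t_max per-permutation maximal statistics (length q).
#' @param plus_one use the `(count + 1) / (q + 1)` estimator.
#' @return length-m vector in `[0, 1]`, antitone in `t`.
#' @export
adjusted_pvalues <- function(t, t_max, plus_one = FALSE) {
  if (length(t_max) == 0) stop_pl("no permutations")
  q <- length(t_max)
  counts <- vapply(t, function(ti) sum(t_max >= ti), numeric(1))
  if (plus_one) (counts + 1) / (q + 1) else counts / q
}

#' Recommended number of permutations
#'
#' From the binomial standard error of the adjusted p-value estimate: to pin
#' an adjusted p-value near `alpha` down to precision `theta` with confidence
#' `gamma`, at least `q = ceil(z^2 alpha (1 - alpha) / theta^2)` permutations
#' are needed, where `z` is the `(1 + gamma) / 2` standard-normal quantile.
#'
#' @param alpha significance level.
#' @param gamma confidence level of the interval.
#' @param theta desired precision of the adjusted p-value estimate.
#' @return integer permutation count.
#' @export
required_permutations <- function(alpha = 0.05, gamma = 0.95, theta = 0.01) {
  check_probability(alpha, "alpha")
  if (!is_scalar_number(gamma) || gamma < 0 || gamma >= 1) {
    stop_pl("gamma must lie in [0, 1)")
  }
  if (!is_scalar_number(theta) || theta <= 0) stop_pl("theta must be > 0")
  z <- qnorm((1 + gamma) / 2)
  as.integer(ceiling(z^2 * alpha * (1 - alpha) / theta^2))
}

#' Bonferroni per-marker threshold
#'
#' @param alpha family-wise significance level.
#' @param m number of markers tested.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is_scalar_number(m) || m < 1) stop_pl("m must be >= 1")
  alpha / m
}

#' Benjamini-Hochberg step-up procedure
#'
#' Flags the largest k with `p_(k) <= k alpha / m` and everything below that
#' order statistic. When no k qualifies, nothing is flagged and the effective
#' threshold is 0.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param alpha target false discovery rate.
#' @return list with logical `significant` (in input order) and scalar
#'   `threshold` (the largest flagged p-value, or 0).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_pl("p-values outside [0, 1]")
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * alpha / m)
  if (length(k) == 0) {
    return(list(significant = rep(FALSE, m), threshold = 0))
  }
  thr <- ps[max(k)]
  list(significant = !is.na(p) & p <= thr, threshold = thr)
}

#' Permutation summary container
#'
#' @param min_p per-permutation minimal p-values.
#' @param alpha significance level.
#' @param adjusted_p optional per-marker adjusted p-values.
#' @param method permutation strategy (`"x"` or `"y"`).
#' @param seed seed of the plan.
#' @return An object of class `permutation_summary` with the threshold filled
#'   in.
#' @export
permutation_summary <- function(min_p, alpha = 0.05, adjusted_p = NULL,
                                method = "x", seed = NA_integer_) {
  structure(list(q = length(min_p), min_p = min_p,
                 threshold = permutation_threshold(min_p, alpha),
                 alpha = alpha, adjusted_p = adjusted_p, method = method,
                 seed = seed),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("<permutation_summary> q = %d (%s-permutation), alpha = %g, threshold = %.3g\n",
              x$q, x$method, x$alpha, x$threshold))
  invisible(x)
}
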