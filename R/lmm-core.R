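#' Single-model linear-mixed-model machinery
#'
#' The model is `y = X beta + u + eps` with `u ~ N(0, sigma_g^2 K)` and
#' `eps ~ N(0, sigma_e^2 I)`. After rotating every quantity by the kinship
#' eigenvectors (`y_rot = U'y`, `X_rot = U'X`), the covariance becomes the
#' diagonal `sigma_g^2 (D + delta I)` with `delta = sigma_e^2 / sigma_g^2`, so
#' the generalized least squares fit, the residual sum of squares and the
#' profiled log-likelihood are all O(n) per evaluation.
#'
#' @name lmm-core
NULL

# Delta grid used by the profile-likelihood search: 100 log-equidistant
# points spanning [1e-5, 1e5].
delta_grid <- function(n_grid = 100L, lower = 1e-5, upper = 1e5) {
  exp(seq(log(lower), log(upper), length.out = n_grid))
}

#' Generalized least squares effects in the rotated basis
#'
#' Solves `(X' E^-1 X) beta = X' E^-1 y` with `E = diag(e)`; the normal matrix
#' is solved, never inverted, for `beta`. Its inverse is additionally returned
#' because standard errors need it.
#'
#' @param X_rot rotated fixed effects, n x c.
#' @param y_rot rotated phenotype, length n.
#' @param e positive weights (eigenvalues plus delta), length n.
#' @return list with `beta` (length c) and `xhx_inv` (c x c).
#' @export
gls_effects <- function(X_rot, y_rot, e) {
  X_rot <- as.matrix(X_rot)
  if (any(e <= 0)) stop_pl("weights e must be strictly positive")
  if (ncol(X_rot) == 0L) {
    return(list(beta = numeric(0), xhx_inv = matrix(0, 0, 0)))
  }
  Xw <- X_rot / e
  XtX <- crossprod(Xw, X_rot)
  Xty <- crossprod(Xw, y_rot)
  beta <- tryCatch(drop(solve(XtX, Xty)), error = function(err) {
    d <- abs(diag(qr.R(qr(X_rot))))
    bad <- which(d < 1e-10 * max(d))
    stop_pl("singular normal equations; near-collinear column(s): ",
            paste(colnames(X_rot)[bad] %||% bad, collapse = ", "))
  })
  list(beta = beta, xhx_inv = solve(XtX))
}

#' Residual sum of squares in the rotated basis
#'
#' `RSS = sum((y_rot - X_rot beta)^2 / e)`, the generalized residual sum of
#' squares `(y - X beta)' H^-1 (y - X beta)` evaluated diagonally.
#'
#' @inheritParams gls_effects
#' @param beta GLS effects from [gls_effects()] on the same inputs.
#' @return nonnegative scalar.
#' @export
residual_sum_squares <- function(X_rot, y_rot, e, beta) {
  r <- y_rot - drop(as.matrix(X_rot) %*% beta)
  rss <- sum(r^2 / e)
  if (rss < -1e-10) stop_pl("negative residual sum of squares: ", rss)
  max(rss, 0)
}

#' Negative profiled log-likelihood in delta
#'
#' For fixed `delta`, both `beta` and `sigma_g^2` have closed-form maximizers:
#' `beta` is the GLS estimate under weights `e = d + delta` and
#' `sigma_g^2 = RSS / n` (full maximum likelihood). The returned value is
#' `0.5 * (n log(2 pi sigma_g^2) + sum(log e) + n)`.
#'
#' @param delta positive variance ratio `sigma_e^2 / sigma_g^2`.
#' @param y_rot,X_rot rotated phenotype and fixed effects.
#' @param d kinship eigenvalues.
#' @return scalar negative log-likelihood.
#' @export
profile_neg_loglik <- function(delta, y_rot, X_rot, d) {
  if (!is_scalar_number(delta) || delta <= 0) stop_pl("delta must be > 0")
  e <- d + delta
  if (any(e <= 0)) stop_pl("nonpositive weights d + delta")
  n <- length(y_rot)
  fit <- gls_effects(X_rot, y_rot, e)
  rss <- residual_sum_squares(X_rot, y_rot, e, fit$beta)
  sigma_g2 <- rss / n
  0.5 * (n * log(2 * pi * sigma_g2) + sum(log(e)) + n)
}

# Degenerate-direction guard for the profiled ML. A centered kinship matrix
# has an exact zero eigenvalue whose eigenvector is the constant vector; with
# an intercept among the fixed effects that rotated coordinate is fitted
# exactly for every delta, while its log-determinant term contributes
# log(delta), so the full ML diverges as delta -> 0. Whenever the
# zero-eigenvalue coordinates are exactly absorbable by the fixed effects
# (rank of their rotated rows equals their count) they carry no information
# about the variance components and are removed from the likelihood, together
# with fixed-effect columns that become undetermined on the remaining
# coordinates. If they are not absorbable they stay: their residuals then
# penalize small delta and the likelihood is well behaved.
reduce_degenerate_coords <- function(y_rot, X_rot, d) {
  null_idx <- which(d == 0)
  X_rot <- as.matrix(X_rot)
  out <- list(y = y_rot, X = X_rot, d = d)
  if (length(null_idx) == 0) return(out)
  Z0 <- X_rot[null_idx, , drop = FALSE]
  if (qr(Z0)$rank < length(null_idx)) return(out)
  keep <- setdiff(seq_along(d), null_idx)
  if (length(keep) == 0) stop_pl("kinship matrix is identically zero")
  Xk <- X_rot[keep, , drop = FALSE]
  # A column concentrated in the removed coordinates (e.g. the intercept when
  # the zero eigenvector is the constant vector) is numerical noise on the
  # kept coordinates; fitting it would absorb an arbitrary noise direction.
  # Judge each column against its own full-coordinate norm, then remove any
  # remaining rank deficiency by QR pivoting.
  full_norm <- sqrt(colSums(X_rot^2))
  kept_norm <- sqrt(colSums(Xk^2))
  cols <- which(kept_norm > 1e-8 * full_norm)
  Xk <- Xk[, cols, drop = FALSE]
  if (ncol(Xk) > 0L) {
    qrX <- qr(Xk)
    Xk <- Xk[, sort(qrX$pivot[seq_len(qrX$rank)]), drop = FALSE]
  }
  list(y = y_rot[keep], X = Xk, d = d[keep])
}

#' Fit variance components on the null model
#'
#' Evaluates the profiled negative log-likelihood on a grid of 100
#' log-equidistant `delta` values in `[1e-5, 1e5]`, runs Brent minimization
#' (in log delta, tolerance 1e-8) inside every bracket around an interior
#' local minimum, and returns the global optimum. Grid endpoints compete as
#' candidates; an optimum at the global boundary is returned with a warning
#' that the variance ratio is at its bound.
#'
#' @param y_rot rotated phenotype `U'y`.
#' @param Z_rot rotated null-model fixed effects `U'Z` (intercept +
#'   covariates, no marker).
#' @param d kinship eigenvalues.
#' @return An object of class `variance_components`: list with `delta`,
#'   `sigma_g2`, `sigma_e2`, `loglik`.
#' @export
estimate_variance_components <- function(y_rot, Z_rot, d) {
  red <- reduce_degenerate_coords(y_rot, Z_rot, d)
  y_rot <- red$y; Z_rot <- red$X; d <- red$d
  grid <- delta_grid()
  f_log <- function(ld) profile_neg_loglik(exp(ld), y_rot, Z_rot, d)
  lg <- log(grid)
  vals <- vapply(lg, f_log, numeric(1))
  if (any(!is.finite(vals))) stop_pl("non-finite likelihood on the delta grid")
  cand_ld <- lg
  cand_val <- vals
  interior <- which(diff(sign(diff(vals))) > 0) + 1L  # local minima of vals
  for (i in interior) {
    opt <- optimize(f_log, lower = lg[i - 1L], upper = lg[i + 1L], tol = 1e-8)
    cand_ld <- c(cand_ld, opt$minimum)
    cand_val <- c(cand_val, opt$objective)
  }
  best <- which.min(cand_val)
  delta <- exp(cand_ld[best])
  at_bound <- best %in% c(1L, length(grid))
  if (at_bound) {
    rlang::warn(paste0("variance ratio delta at grid bound (", format(delta),
                       "); heritability is effectively ",
                       if (best == 1L) "1" else "0"),
                class = "permlmm_boundary")
  }
  e <- d + delta
  fit <- gls_effects(Z_rot, y_rot, e)
  rss <- residual_sum_squares(Z_rot, y_rot, e, fit$beta)
  n <- length(y_rot)
  sigma_g2 <- rss / n
  structure(list(delta = delta, sigma_g2 = sigma_g2,
                 sigma_e2 = delta * sigma_g2, loglik = -cand_val[best]),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  h2 <- x$sigma_g2 / (x$sigma_g2 + x$sigma_e2)
  cat(sprintf("<variance_components> delta = %.4g, sigma_g2 = %.4g, sigma_e2 = %.4g (pseudo-h2 = %.3f)\n",
              x$delta, x$sigma_g2, x$sigma_e2, h2))
  invisible(x)
}

#' F-test for the one-degree-of-freedom marker term
#'
#' `F = (RSS_null - RSS_alt) / (RSS_alt / (n - c_alt))` compared against
#' `F(1, n - c_alt)`. A tiny negative numerator from floating point is
#' clamped to 0.
#'
#' @param rss_null residual sum of squares of the model without the marker.
#' @param rss_alt residual sum of squares with the marker.
#' @param n sample count.
#' @param c_alt number of fixed effects in the alternative model (intercept +
#'   covariates + marker).
#' @return list with `f_stat` and `p_value`.
#' @export
f_test <- function(rss_null, rss_alt, n, c_alt) {
  if (n <= c_alt) stop_pl("need n > number of fixed effects (", n, " <= ", c_alt, ")")
  if (rss_alt > rss_null + 1e-10 * max(1, rss_null)) {
    stop_pl("rss_alt exceeds rss_null beyond tolerance")
  }
  f <- max(rss_null - rss_alt, 0) / (rss_alt / (n - c_alt))
  list(f_stat = f, p_value = pf(f, 1, n - c_alt, lower.tail = FALSE))
}
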