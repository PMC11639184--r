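#' Permutation plans
#'
#' Draws `q` random permutations of `1..n` under a fixed seed. One plan is
#' shared by every marker batch: the maxT procedure takes the maximum
#' statistic over markers per permutation, which requires the same
#' permutations for all markers.
#'
#' Two strategies are supported. The conventional `"y"` strategy shuffles the
#' phenotype, which breaks the relatedness between individuals encoded in the
#' kinship matrix. The population-aware `"x"` strategy instead permutes the
#' rows of the fixed-effects matrix (covariates and marker) with the inverse
#' permutation, which is equivalent to permuting the phenotype together with
#' the rows and columns of the covariance matrix, so the phenotype-kinship
#' relationship stays intact.
#'
#' @param n sample count.
#' @param q number of permutations.
#' @param seed integer seed for the shuffles.
#' @param method `"x"` (population-aware, permute fixed effects) or `"y"`
#'   (conventional, permute phenotype).
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(n, q, seed = 42L, method = c("x", "y")) {
  method <- match.arg(method)
  if (!is_scalar_number(q) || q < 1) stop_pl("q must be a positive integer")
  q <- as.integer(q)
  perms <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(q), function(k) sample.int(n))
  })
  structure(list(q = q, n = as.integer(n), permutations = perms,
                 seed = as.integer(seed), method = method),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat("<permutation_plan> q = ", x$q, ", n = ", x$n, ", method = ",
      x$method, "-permutation, seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Permute the rows of a matrix (or entries of a vector)
#'
#' Convention: output row `i` is input row `tau[i]`. Applying the inverse
#' permutation (as the population-aware strategy requires for the fixed
#' effects) means calling `permute_rows(X, invert = TRUE)`. Worked 3-row
#' example: with `tau = c(3, 1, 2)`, `permute_rows(X, tau)` returns rows
#' `(x3, x1, x2)`, and `permute_rows(X, tau, invert = TRUE)` returns rows
#' `(x2, x3, x1)`.
#'
#' @param X matrix or vector with n rows/entries.
#' @param tau integer permutation of `1..n`.
#' @param invert apply the inverse permutation instead.
#' @return X with rows reordered.
#' @export
permute_rows <- function(X, tau, invert = FALSE) {
  n <- if (is.matrix(X)) nrow(X) else length(X)
  tau <- check_permutation(tau, n)
  if (invert) tau <- invert_permutation(tau)
  if (is.matrix(X)) X[tau, , drop = FALSE] else X[tau]
}

# Rotate columns of S (n x b, samples in rows) into the kinship eigenbasis.
rotate_columns <- function(U, S) crossprod(U, S)

#' Block-decomposed normal equations for a marker batch
#'
#' For fixed effects `X_i = [Z, s_i]`, the normal matrix
#' `X_i' E^-1 X_i` has a block structure in which `Z' E^-1 Z`, `Z' E^-1 y` and
#' `y' E^-1 y` do not depend on the marker. They are computed once; per batch
#' only the SNP-dependent blocks `Z' E^-1 s_i`, `s_i' E^-1 s_i` and
#' `s_i' E^-1 y` are formed, and each c x c system is assembled and solved.
#' Results are independent of the batch size.
#'
#' A marker whose rotated column is (numerically) in the span of `Z` makes the
#' system singular; its results are set to `NA` and counted in a log message.
#'
#' @param Z_rot rotated covariate matrix `U'Z`, n x (c-1) (intercept first).
#' @param S_rot rotated marker batch `U'S`, n x b (markers in columns).
#' @param y_rot rotated phenotype.
#' @param e positive weights `d + delta`.
#' @return list with `beta` (c x b; covariate effects then the marker effect
#'   in the last row), `rss` (length b), `rss_null` (scalar), `var_beta_snp`
#'   (length b; the marker diagonal of the inverse normal matrix).
#' @export
block_normal_equations <- function(Z_rot, S_rot, y_rot, e) {
  Z_rot <- as.matrix(Z_rot)
  S_rot <- as.matrix(S_rot)
  if (any(e <= 0)) stop_pl("weights e must be strictly positive")
  n <- length(y_rot)
  stopifnot(nrow(Z_rot) == n, nrow(S_rot) == n)
  b <- ncol(S_rot)
  p <- ncol(Z_rot)
  w <- 1 / e
  Zw <- Z_rot * w
  ZtZ <- crossprod(Zw, Z_rot)          # once per (delta, Z)
  Zty <- drop(crossprod(Zw, y_rot))
  yty <- sum(y_rot^2 * w)
  ZtS <- crossprod(Zw, S_rot)          # SNP-dependent blocks, batch-wise
  StS <- colSums(S_rot^2 * w)
  Sty <- drop(crossprod(S_rot, y_rot * w))

  null_fit <- gls_effects(Z_rot, y_rot, e)
  rss_null <- residual_sum_squares(Z_rot, y_rot, e, null_fit$beta)

  beta <- matrix(NA_real_, p + 1L, b)
  rss <- rep(NA_real_, b)
  var_snp <- rep(NA_real_, b)
  scale_ref <- max(StS, 1e-300)
  if (p == 1L) {
    # intercept-only: closed-form 2x2 solve, vectorized over the batch
    zz <- ZtZ[1, 1]
    det <- zz * StS - ZtS[1, ]^2
    ok <- det > 1e-12 * scale_ref * zz
    bs <- (zz * Sty - ZtS[1, ] * Zty) / det
    bz <- (StS * Zty - ZtS[1, ] * Sty) / det
    beta[1, ok] <- bz[ok]
    beta[2, ok] <- bs[ok]
    rss[ok] <- pmax(yty - bz[ok] * Zty - bs[ok] * Sty[ok], 0)
    var_snp[ok] <- zz / det[ok]
  } else {
    for (i in seq_len(b)) {
      M <- rbind(cbind(ZtZ, ZtS[, i]), c(ZtS[, i], StS[i]))
      rhs <- c(Zty, Sty[i])
      Minv <- tryCatch(solve(M), error = function(err) NULL)
      if (is.null(Minv) || !all(is.finite(Minv))) next
      bi <- drop(Minv %*% rhs)
      beta[, i] <- bi
      rss[i] <- max(yty - sum(bi * rhs), 0)
      var_snp[i] <- Minv[p + 1L, p + 1L]
    }
  }
  n_bad <- sum(is.na(rss))
  if (n_bad > 0) pl_log(n_bad, " marker(s) collinear with the covariates; ",
                        "results set to NA")
  list(beta = beta, rss = rss, rss_null = rss_null, var_beta_snp = var_snp)
}

#' Refit variance components per permutation
#'
#' Under population-aware (`"x"`) permutations the null fixed effects are the
#' permuted `Z` with the original phenotype; under conventional (`"y"`)
#' permutations the phenotype is shuffled and `Z` stays. The variance ratio
#' `delta` (and hence the diagonal `E = D + delta I`) must be refit for each
#' permutation — except in the `"x"` case with an intercept-only `Z`, where
#' permuting a constant column is the identity and the unpermuted fit is
#' provably reused.
#'
#' @param y phenotype in original coordinates (length n).
#' @param Z fixed effects in original coordinates (intercept first).
#' @param plan a [permutation_plan].
#' @param kinship a [kinship_model].
#' @return list of `q` [estimate_variance_components()] results.
#' @export
permutation_variance_components <- function(y, Z, plan, kinship) {
  stopifnot(inherits(plan, "permutation_plan"), inherits(kinship, "kinship_model"))
  U <- kinship$U; d <- kinship$d
  y_rot <- drop(crossprod(U, y))
  Z <- as.matrix(Z)
  intercept_only <- ncol(Z) == 1L && all(Z == Z[1, 1])
  if (plan$method == "x" && intercept_only) {
    vc <- estimate_variance_components(y_rot, rotate_columns(U, Z), d)
    return(rep(list(vc), plan$q))
  }
  lapply(plan$permutations, function(tau) {
    if (plan$method == "x") {
      Zp <- permute_rows(Z, tau, invert = TRUE)
      estimate_variance_components(y_rot, rotate_columns(U, Zp), d)
    } else {
      yp_rot <- drop(crossprod(U, permute_rows(y, tau)))
      estimate_variance_components(yp_rot, rotate_columns(U, Z), d)
    }
  })
}

#' Permutation-wise association statistics
#'
#' Computes the F statistic (or its p-value) of every marker under every
#' permutation of the plan, with the per-permutation variance ratio from
#' [permutation_variance_components()] and the block decomposition of
#' [block_normal_equations()], in which the covariate block is formed once per
#' permutation and only SNP-dependent blocks are formed per marker batch.
#'
#' @param S dosage matrix in original coordinates (n x m, markers in columns).
#' @param Z fixed effects in original coordinates (intercept first).
#' @param y phenotype (length n).
#' @param plan a [permutation_plan].
#' @param kinship a [kinship_model].
#' @param statistic return raw F statistics or their p-values.
#' @param batch_size markers per batch (memory knob; results do not depend on
#'   it).
#' @param vc optional precomputed list from
#'   [permutation_variance_components()].
#' @return q x m matrix.
#' @export
permuted_association_stats <- function(S, Z, y, plan, kinship,
                                       statistic = c("f", "p"),
                                       batch_size = 2048L, vc = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(plan, "permutation_plan"), inherits(kinship, "kinship_model"))
  S <- as.matrix(S)
  Z <- as.matrix(Z)
  U <- kinship$U; d <- kinship$d
  n <- nrow(S); m <- ncol(S)
  c_alt <- ncol(Z) + 1L
  if (is.null(vc)) vc <- permutation_variance_components(y, Z, plan, kinship)
  y_rot <- drop(crossprod(U, y))
  Z_rot <- rotate_columns(U, Z)
  out <- matrix(NA_real_, plan$q, m)
  chunks <- split(seq_len(m), ceiling(seq_len(m) / batch_size))
  for (k in seq_len(plan$q)) {
    tau <- plan$permutations[[k]]
    e_k <- d + vc[[k]]$delta
    if (plan$method == "x") {
      inv <- invert_permutation(tau)
      Zk_rot <- rotate_columns(U, Z[inv, , drop = FALSE])
      yk_rot <- y_rot
      for (idx in chunks) {
        Sk_rot <- crossprod(U, S[inv, idx, drop = FALSE])
        blk <- block_normal_equations(Zk_rot, Sk_rot, yk_rot, e_k)
        out[k, idx] <- f_from_block(blk, n, c_alt)
      }
    } else {
      yk_rot <- drop(crossprod(U, y[tau]))
      for (idx in chunks) {
        Sk_rot <- crossprod(U, S[, idx, drop = FALSE])
        blk <- block_normal_equations(Z_rot, Sk_rot, yk_rot, e_k)
        out[k, idx] <- f_from_block(blk, n, c_alt)
      }
    }
  }
  if (statistic == "p") out <- pf(out, 1, n - c_alt, lower.tail = FALSE)
  out
}

# F statistics from a block_normal_equations() result.
f_from_block <- function(blk, n, c_alt) {
  pmax(blk$rss_null - blk$rss, 0) / (blk$rss / (n - c_alt))
}
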