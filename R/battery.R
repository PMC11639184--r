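#' Scan many phenotypes over one genotype panel with a shared permutation plan
#'
#' Simulation batteries test hundreds of phenotypes against the same markers
#' and kinship. This scan shares everything that does not depend on the
#' phenotype across traits: the rotated markers, and — because one
#' permutation plan is reused — each permutation's rotated, row-permuted
#' marker matrix, which is by far the dominant cost. Results are identical to
#' running [lmm_scan()] plus [permuted_association_stats()] per phenotype
#' with that plan (this is asserted in the test suite).
#'
#' Restricted to the intercept-only model under population-aware (`"x"`)
#' permutations: permuting a constant column is the identity, so the
#' per-permutation variance-ratio refit provably equals the null fit and the
#' phenotype-side quantities stay fixed while only the markers move.
#'
#' @param design a [gwas_design] with no covariates; markers must be
#'   polymorphic (drop monomorphic ones with `maf_filter(g, 0)`).
#' @param Y n x P phenotype matrix (one column per trait).
#' @param plan a [permutation_plan] with `method = "x"`.
#' @param alpha significance level for the per-phenotype thresholds.
#' @return list with `raw_p` (m x P), `min_p` (q x P per-permutation minimal
#'   p-values), `threshold` (length P), `delta` (length P), `pseudo_h2`
#'   (length P), `n`, `m`.
#' @export
battery_scan <- function(design, Y, plan, alpha = 0.05) {
  stopifnot(inherits(design, "gwas_design"), inherits(plan, "permutation_plan"))
  if (ncol(design$Z) != 1L) stop_pl("battery_scan supports the intercept-only model")
  if (plan$method != "x") stop_pl("battery_scan supports x-permutations")
  Y <- as.matrix(Y)
  if (nrow(Y) != design$n) stop_pl("phenotype rows != sample count")
  S <- design$genotypes$dosages
  if (any(apply(S, 2, var) == 0)) {
    stop_pl("monomorphic markers present; apply maf_filter(g, 0) first")
  }
  U <- design$U; d <- design$d
  n <- design$n; m <- design$m; P <- ncol(Y)
  z_rot <- design$Z_rot[, 1]
  Y_rot <- crossprod(U, Y)

  # per-phenotype null fits (delta differs per trait)
  vc <- lapply(seq_len(P), function(p) {
    suppressWarnings(
      estimate_variance_components(Y_rot[, p], design$Z_rot, d))
  })
  delta <- vapply(vc, `[[`, numeric(1), "delta")
  h2 <- vapply(vc, function(v) v$sigma_g2 / (v$sigma_g2 + v$sigma_e2), numeric(1))
  W <- 1 / (outer(d, delta, "+"))          # n x P weights
  A <- W * Y_rot                            # E^-1 y~ per trait
  B <- W * z_rot                            # E^-1 z~ per trait
  zz <- colSums(z_rot * B)
  zy <- colSums(z_rot * A)
  yy <- colSums(Y_rot * A)
  rss_null <- yy - zy^2 / zz

  f_stats <- function(S_rot) {
    SS <- crossprod(S_rot^2, W)             # m x P: s~' E^-1 s~
    SY <- crossprod(S_rot, A)               # s~' E^-1 y~
    SZ <- crossprod(S_rot, B)               # s~' E^-1 z~
    det <- sweep(SS, 2, zz, "*") - SZ^2
    bs <- (sweep(SY, 2, zz, "*") - sweep(SZ, 2, zy, "*")) / det
    bz <- (sweep(SS, 2, zy, "*") - SZ * SY) / det
    rss <- sweep(-sweep(bz, 2, zy, "*") - bs * SY, 2, yy, "+")
    num <- pmax(sweep(-rss, 2, rss_null, "+"), 0)
    list(f = num / rss * (n - 2), bs = bs, rss = rss)
  }

  raw <- f_stats(design$S_rot)
  raw_p <- pf(raw$f, 1, n - 2, lower.tail = FALSE)
  dimnames(raw_p) <- list(design$genotypes$marker_ids, colnames(Y))

  max_f <- matrix(NA_real_, plan$q, P)
  for (k in seq_len(plan$q)) {
    inv <- invert_permutation(plan$permutations[[k]])
    Sk_rot <- crossprod(U, S[inv, , drop = FALSE])
    max_f[k, ] <- apply(f_stats(Sk_rot)$f, 2, max)
  }
  min_p <- pf(max_f, 1, n - 2, lower.tail = FALSE)
  threshold <- apply(min_p, 2, quantile, probs = alpha, type = 7, names = FALSE)
  list(raw_p = raw_p, min_p = min_p, threshold = threshold,
       delta = delta, pseudo_h2 = h2, n = n, m = m)
}
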