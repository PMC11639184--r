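#' Precompute the reusable parts of a mixed-model scan
#'
#' Bundles the imputed genotypes, the kinship eigendecomposition, the
#' fixed-effects matrix and the rotated copies of everything that does not
#' depend on the phenotype, so repeated scans (many traits, simulation
#' batteries) pay the rotation cost once.
#'
#' @param g a [genotype_data] object (missing dosages are mean-imputed).
#' @param kinship optional [kinship_model]; computed via [compute_grm()] when
#'   absent.
#' @param covariates optional numeric matrix (no intercept column), rows
#'   aligned with `g`.
#' @return An object of class `gwas_design`.
#' @export
gwas_design <- function(g, kinship = NULL, covariates = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  g <- impute_genotypes(g)
  if (is.null(kinship)) kinship <- compute_grm(g)
  stopifnot(inherits(kinship, "kinship_model"))
  if (!identical(kinship$sample_ids, g$sample_ids)) {
    kinship <- subset_kinship(kinship, g$sample_ids)
  }
  n <- nrow(g$dosages)
  Z <- fixed_effects_matrix(n, covariates, g$sample_ids)
  structure(list(
    genotypes = g, kinship = kinship, Z = Z,
    U = kinship$U, d = kinship$d,
    Z_rot = rotate_columns(kinship$U, Z),
    S_rot = rotate_columns(kinship$U, g$dosages),
    n = n, m = ncol(g$dosages)
  ), class = "gwas_design")
}

#' @export
print.gwas_design <- function(x, ...) {
  cat("<gwas_design> ", x$n, " samples x ", x$m, " markers, ",
      ncol(x$Z), " fixed effect(s)\n", sep = "")
  invisible(x)
}

#' Mixed-model association scan
#'
#' Fits the variance components once on the null model (no marker), then
#' tests every marker with a one-degree-of-freedom F-test using the block
#' decomposition. With `refit_delta = TRUE` the variance ratio is instead
#' re-estimated per marker on the alternative model (exact but much slower);
#' the default reuses the null-model estimate.
#'
#' @param design a [gwas_design].
#' @param y phenotype vector aligned with the design samples (named vectors
#'   are checked against the sample ids).
#' @param refit_delta re-estimate `delta` per marker.
#' @param batch_size markers per block-solve batch.
#' @return tibble with columns `marker_id`, `chromosome`, `position`, `maf`,
#'   `beta`, `se_beta`, `f_stat`, `p_value`; the fitted
#'   `variance_components` in attribute `"vc"`.
#' @export
lmm_scan <- function(design, y, refit_delta = FALSE, batch_size = 4096L) {
  stopifnot(inherits(design, "gwas_design"))
  y <- check_aligned_y(design, y)
  y_rot <- drop(crossprod(design$U, y))
  vc <- estimate_variance_components(y_rot, design$Z_rot, design$d)
  n <- design$n
  c_alt <- ncol(design$Z) + 1L
  m <- design$m
  beta <- se <- fst <- rep(NA_real_, m)
  if (!refit_delta) {
    e <- design$d + vc$delta
    chunks <- split(seq_len(m), ceiling(seq_len(m) / batch_size))
    for (idx in chunks) {
      blk <- block_normal_equations(design$Z_rot,
                                    design$S_rot[, idx, drop = FALSE],
                                    y_rot, e)
      fst[idx] <- f_from_block(blk, n, c_alt)
      beta[idx] <- blk$beta[nrow(blk$beta), ]
      se[idx] <- sqrt(blk$rss / n * blk$var_beta_snp)
    }
  } else {
    for (i in seq_len(m)) {
      X_rot <- cbind(design$Z_rot, design$S_rot[, i])
      vci <- tryCatch(
        suppressWarnings(estimate_variance_components(y_rot, X_rot, design$d)),
        error = function(err) NULL)
      if (is.null(vci)) next
      e_i <- design$d + vci$delta
      fit <- gls_effects(X_rot, y_rot, e_i)
      rss_alt <- residual_sum_squares(X_rot, y_rot, e_i, fit$beta)
      null_fit <- gls_effects(design$Z_rot, y_rot, e_i)
      rss_null <- residual_sum_squares(design$Z_rot, y_rot, e_i, null_fit$beta)
      fst[i] <- f_test(rss_null, rss_alt, n, c_alt)$f_stat
      beta[i] <- fit$beta[c_alt]
      se[i] <- sqrt(rss_alt / n * fit$xhx_inv[c_alt, c_alt])
    }
  }
  out <- marker_info(design$genotypes)
  out$beta <- beta
  out$se_beta <- se
  out$f_stat <- fst
  out$p_value <- pf(fst, 1, n - c_alt, lower.tail = FALSE)
  attr(out, "vc") <- vc
  out
}

check_aligned_y <- function(design, y) {
  if (inherits(y, "data.frame")) {
    y <- setNames(y$value, y$sample_id)
  }
  if (!is.null(names(y))) {
    if (!setequal(names(y), design$genotypes$sample_ids)) {
      stop_pl("phenotype sample ids do not match the design; run align_samples() first")
    }
    y <- y[design$genotypes$sample_ids]
  }
  if (length(y) != design$n) stop_pl("phenotype length != sample count")
  unname(as.numeric(y))
}

#' Full GWAS pipeline with permutation-based thresholds
#'
#' read -> align -> MAF filter -> kinship -> null variance components ->
#' batched association scan -> optional maxT permutations -> thresholds.
#' Inputs may be objects or file paths.
#'
#' @param genotypes [genotype_data] or a path accepted by [read_genotypes()].
#' @param phenotype tibble (`sample_id`, `value`) or a path for
#'   [read_phenotypes()].
#' @param covariates optional matrix or path for [read_covariates()].
#' @param kinship optional [kinship_model] or path for [load_kinship()].
#' @param maf MAF filter threshold (markers with MAF > `maf` are kept).
#' @param q number of permutations (0 disables permutations).
#' @param alpha significance level.
#' @param method permutation strategy, `"x"` (population-aware) or `"y"`.
#' @param seed seed for the permutation plan.
#' @param batch_size,perm_batch marker/permutation batching knobs (memory
#'   only; results are independent of both).
#' @param trait,genotype_format passed to the readers.
#' @return An object of class `permlmm_gwas`: list with `assoc` (tibble),
#'   `perm` (`permutation_summary` or `NULL`), `vc`, `thresholds`, `meta`.
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL, kinship = NULL,
                     maf = 0.05, q = 500L, alpha = 0.05,
                     method = c("x", "y"), seed = 42L,
                     batch_size = 4096L, perm_batch = NULL,
                     trait = NULL, genotype_format = "auto") {
  method <- match.arg(method)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes, genotype_format)
  if (is.character(phenotype)) phenotype <- read_phenotypes(phenotype, trait)
  if (is.character(covariates)) covariates <- read_covariates(covariates)
  if (is.character(kinship)) kinship <- load_kinship(kinship)
  al <- align_samples(genotypes, phenotype, covariates, kinship)
  g <- impute_genotypes(al$genotypes)
  g <- maf_filter(g, maf)
  design <- gwas_design(g, kinship = al$kinship, covariates = al$covariates)
  assoc <- lmm_scan(design, al$y, batch_size = batch_size)
  vc <- attr(assoc, "vc")
  m_tested <- sum(!is.na(assoc$p_value))
  thresholds <- list(bonferroni = bonferroni_threshold(alpha, m_tested),
                     bh = benjamini_hochberg(assoc$p_value[!is.na(assoc$p_value)],
                                             alpha)$threshold)
  perm <- NULL
  if (q > 0) {
    plan <- permutation_plan(design$n, q, seed = seed, method = method)
    ok <- !is.na(assoc$p_value)
    stats <- permuted_association_stats(design$genotypes$dosages[, ok, drop = FALSE],
                                        design$Z, al$y, plan, design$kinship,
                                        statistic = "p",
                                        batch_size = batch_size)
    min_p <- min_p_per_permutation(stats)
    t_max <- apply(-stats, 1, max)  # max statistic on the -p scale
    adj <- rep(NA_real_, nrow(assoc))
    adj[ok] <- adjusted_pvalues(-assoc$p_value[ok], t_max)
    perm <- permutation_summary(min_p, alpha = alpha, adjusted_p = adj,
                                method = method, seed = as.integer(seed))
  }
  structure(list(assoc = assoc, perm = perm, vc = vc, thresholds = thresholds,
                 meta = list(n = design$n, m = design$m, maf = maf, q = q,
                             alpha = alpha, method = method,
                             seed = as.integer(seed),
                             trait = attr(phenotype, "trait") %||% "trait",
                             version = as.character(utils::packageVersion("permlmm")))),
            class = "permlmm_gwas")
}

#' @export
print.permlmm_gwas <- function(x, ...) {
  cat("<permlmm_gwas> trait '", x$meta$trait, "': ", x$meta$n, " samples, ",
      x$meta$m, " markers\n", sep = "")
  print(x$vc)
  cat("  Bonferroni threshold: ", format(x$thresholds$bonferroni, digits = 3),
      "\n", sep = "")
  if (!is.null(x$perm)) {
    cat(sprintf("  %s-permutation threshold (q = %d, alpha = %g): %.3g\n",
                x$perm$method, x$perm$q, x$perm$alpha, x$perm$threshold))
    cat("  markers below permutation threshold: ",
        sum(x$assoc$p_value <= x$perm$threshold, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy an association scan
#'
#' @param x a `permlmm_gwas` object.
#' @param ... unused.
#' @return The per-marker association tibble, with a logical `significant`
#'   column when permutations were run.
#' @importFrom generics tidy
#' @export
tidy.permlmm_gwas <- function(x, ...) {
  out <- x$assoc
  attr(out, "vc") <- NULL
  if (!is.null(x$perm)) {
    out$adjusted_p <- x$perm$adjusted_p
    out$significant <- !is.na(out$p_value) & out$p_value <= x$perm$threshold
  }
  out
}

#' One-row model summary
#'
#' @param x a `permlmm_gwas` object.
#' @param ... unused.
#' @return tibble with sample/marker counts, variance components, pseudo
#'   heritability and every threshold.
#' @importFrom generics glance
#' @export
glance.permlmm_gwas <- function(x, ...) {
  tibble::tibble(
    n = x$meta$n, m = x$meta$m,
    delta = x$vc$delta, sigma_g2 = x$vc$sigma_g2, sigma_e2 = x$vc$sigma_e2,
    pseudo_h2 = x$vc$sigma_g2 / (x$vc$sigma_g2 + x$vc$sigma_e2),
    q = x$meta$q, alpha = x$meta$alpha, method = x$meta$method,
    perm_threshold = if (is.null(x$perm)) NA_real_ else x$perm$threshold,
    bonferroni = x$thresholds$bonferroni, bh_threshold = x$thresholds$bh)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Manhattan plot of a scan
#'
#' @param object a `permlmm_gwas` object.
#' @param ... unused.
#' @return A ggplot object with `-log10(p)` against genome position, the
#'   Bonferroni threshold dashed and (when available) the permutation
#'   threshold solid.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.permlmm_gwas <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$p_value), ]
  df$chromosome <- factor(df$chromosome, levels = unique(df$chromosome))
  offs <- c(0, cumsum(as.numeric(tapply(df$position, df$chromosome, max))))
  df$x <- df$position + offs[as.integer(df$chromosome)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -log10(.data$p_value),
                                        colour = .data$chromosome)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(object$thresholds$bonferroni),
                        linetype = "dashed") +
    ggplot2::labs(x = "genome position", y = expression(-log[10](p)),
                  title = object$meta$trait)
  if (!is.null(object$perm)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(object$perm$threshold))
  }
  p
}

#' @export
ggplot2::autoplot

#' Quantile-quantile plot of scan p-values
#'
#' @param x a `permlmm_gwas` object or a vector of p-values.
#' @return A ggplot object of observed against expected `-log10(p)`.
#' @export
plot_qq <- function(x) {
  p <- if (inherits(x, "permlmm_gwas")) x$assoc$p_value else x
  p <- sort(p[!is.na(p)])
  df <- tibble::tibble(expected = -log10(stats::ppoints(length(p))),
                       observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = expression(Expected~-log[10](p)),
                  y = expression(Observed~-log[10](p)))
}

#' @importFrom rlang .data
NULL
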