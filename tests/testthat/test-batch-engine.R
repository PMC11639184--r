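test_that("permutation plans are valid, reproducible and seed-sensitive", {
  plan <- permutation_plan(8, 5, seed = 1, method = "x")
  expect_s3_class(plan, "permutation_plan")
  expect_length(plan$permutations, 5L)
  for (tau in plan$permutations) expect_setequal(tau, 1:8)

  plan2 <- permutation_plan(8, 5, seed = 1, method = "x")
  expect_identical(plan$permutations, plan2$permutations)
  plan3 <- permutation_plan(8, 5, seed = 2, method = "x")
  expect_false(identical(plan$permutations, plan3$permutations))

  expect_error(permutation_plan(8, 0), "positive")
})

test_that("permute_rows follows the documented convention", {
  X <- matrix(1:6, 3, 2)  # rows x1, x2, x3
  tau <- c(3L, 1L, 2L)
  expect_identical(permute_rows(X, tau), X[c(3, 1, 2), ])
  expect_identical(permute_rows(X, tau, invert = TRUE), X[c(2, 3, 1), ])
  # applying tau then its inverse restores the input
  expect_identical(permute_rows(permute_rows(X, tau), tau, invert = TRUE), X)
  expect_identical(permute_rows(X, 1:3), X)
  # vectors follow the same rule
  expect_identical(permute_rows(c(10, 20, 30), tau), c(30, 10, 20))
  expect_error(permute_rows(X, c(1L, 1L, 2L)), "permutation")
})

test_that("block normal equations reduce to the single-marker GLS fit", {
  withr::with_seed(40, {
    n <- 18
    K <- random_kinship(n, seed = 41)
    dec <- spectral_decompose(K)
    delta <- 0.8
    e <- dec$d + delta
    y_rot <- drop(crossprod(dec$U, rnorm(n)))
    S_rot <- crossprod(dec$U, matrix(rbinom(n * 6, 2, 0.4), n, 6))
  })

  # intercept-only branch (vectorized 2x2) against gls_effects per marker
  Z1 <- crossprod(dec$U, matrix(1, n, 1))
  blk <- block_normal_equations(Z1, S_rot, y_rot, e)
  expect_equal(blk$rss_null,
               residual_sum_squares(Z1, y_rot, e,
                                    gls_effects(Z1, y_rot, e)$beta),
               tolerance = 1e-12)
  for (i in 1:6) {
    X <- cbind(Z1, S_rot[, i])
    fit <- gls_effects(X, y_rot, e)
    expect_equal(unname(blk$beta[, i]), unname(fit$beta), tolerance = 1e-10)
    expect_equal(blk$rss[i],
                 residual_sum_squares(X, y_rot, e, fit$beta),
                 tolerance = 1e-10)
    expect_equal(blk$var_beta_snp[i], fit$xhx_inv[2, 2], tolerance = 1e-10)
  }

  # general branch (intercept + covariate) against gls_effects per marker
  Z2 <- crossprod(dec$U, cbind(1, rnorm(n)))
  blk2 <- block_normal_equations(Z2, S_rot, y_rot, e)
  for (i in 1:6) {
    X <- cbind(Z2, S_rot[, i])
    fit <- gls_effects(X, y_rot, e)
    expect_equal(unname(blk2$beta[, i]), unname(fit$beta), tolerance = 1e-10)
    expect_equal(blk2$var_beta_snp[i], fit$xhx_inv[3, 3], tolerance = 1e-10)
  }

  # a marker collinear with the covariates yields NA, others are unaffected
  S_bad <- cbind(S_rot[, 1], Z2[, 2])
  blk3 <- block_normal_equations(Z2, S_bad, y_rot, e)
  expect_false(anyNA(blk3$rss[1]))
  expect_true(is.na(blk3$rss[2]))
  expect_true(is.na(blk3$beta[3, 2]))
})

test_that("permuted statistics are independent of the batch size", {
  g <- random_genotypes(25, 37, seed = 50)
  g <- maf_filter(g, 0.05)
  kin <- compute_grm(g)
  y <- withr::with_seed(51, rnorm(25))
  Z <- matrix(1, 25, 1)
  plan <- permutation_plan(25, 4, seed = 52, method = "x")
  # BLAS matrix products are not bitwise identical across operand shapes
  # (vector vs blocked kernels), so invariance is asserted at 1e-12
  ref <- suppressWarnings(permuted_association_stats(g$dosages, Z, y, plan, kin))
  for (bs in c(1L, 3L, 10L, 1000L)) {
    got <- suppressWarnings(
      permuted_association_stats(g$dosages, Z, y, plan, kin, batch_size = bs))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("the identity permutation reproduces the unpermuted scan", {
  g <- random_genotypes(20, 15, seed = 60)
  g <- maf_filter(g, 0.05)
  kin <- compute_grm(g)
  y <- withr::with_seed(61, rnorm(20))
  Z <- matrix(1, 20, 1)
  design <- gwas_design(g, kinship = kin)
  f_ref <- suppressWarnings(lmm_scan(design, setNames(y, g$sample_ids)))$f_stat
  for (method in c("x", "y")) {
    plan <- manual_plan(list(1:20), method = method)
    f_perm <- suppressWarnings(
      permuted_association_stats(g$dosages, Z, y, plan, kin))
    expect_equal(unname(f_perm[1, ]), f_ref, tolerance = 1e-10)
  }
})

test_that("permuting the fixed effects equals permuting phenotype and kinship", {
  # the algebraic equivalence behind population-aware permutations, checked
  # against a brute-force fit on the explicitly permuted covariance
  withr::with_seed(70, {
    n <- 12
    K <- random_kinship(n, seed = 71)
    y <- rnorm(n)
    s <- rbinom(n, 2, 0.4)
    Z <- cbind(1, rnorm(n))
    taus <- lapply(1:4, function(i) sample.int(n))
  })
  kin <- kinship_model(K)
  delta <- 0.7
  plan <- manual_plan(taus, method = "x", n = n)
  vc_fixed <- rep(list(list(delta = delta)), 4)
  f_pkg <- permuted_association_stats(cbind(s), Z, y, plan, kin, vc = vc_fixed)
  for (k in 1:4) {
    tau <- taus[[k]]
    f_oracle <- bf_fstat(y[tau], Z, s, K[tau, tau], delta)
    expect_equal(f_pkg[k, 1], f_oracle, tolerance = 1e-8)
  }
})

test_that("per-permutation variance components follow the documented rules", {
  g <- random_genotypes(30, 40, seed = 80)
  g <- maf_filter(g, 0.05)
  kin <- compute_grm(g)
  y <- simulate_phenotype(g, kin, heritability = 0.5, seed = 81)$value
  Z <- matrix(1, 30, 1)

  # x-permutations with an intercept-only design reuse the unpermuted fit
  plan_x <- permutation_plan(30, 3, seed = 82, method = "x")
  vc_x <- permutation_variance_components(y, Z, plan_x, kin)
  vc0 <- estimate_variance_components(drop(crossprod(kin$U, y)),
                                      crossprod(kin$U, Z), kin$d)
  expect_length(vc_x, 3L)
  for (v in vc_x) expect_identical(v$delta, vc0$delta)

  # y-permutations refit: each entry matches a direct fit on the shuffled y
  plan_y <- permutation_plan(30, 3, seed = 82, method = "y")
  vc_y <- suppressWarnings(permutation_variance_components(y, Z, plan_y, kin))
  for (k in 1:3) {
    yp <- y[plan_y$permutations[[k]]]
    direct <- suppressWarnings(
      estimate_variance_components(drop(crossprod(kin$U, yp)),
                                   crossprod(kin$U, Z), kin$d))
    expect_identical(vc_y[[k]]$delta, direct$delta)
  }
})

test_that("the batch engine matches a naive per-marker, per-permutation loop", {
  withr::with_seed(90, {
    n <- 30
    g <- random_genotypes(n, 20, seed = 91)
    g <- maf_filter(g, 0.05)
    kin <- compute_grm(g)
    y <- rnorm(n)
    Z <- cbind(1, rnorm(n))
  })
  m <- ncol(g$dosages)
  K <- kin$K
  for (method in c("x", "y")) {
    plan <- permutation_plan(n, 5, seed = 92, method = method)
    vc <- suppressWarnings(permutation_variance_components(y, Z, plan, kin))
    f_pkg <- suppressWarnings(
      permuted_association_stats(g$dosages, Z, y, plan, kin,
                                 batch_size = 7L, vc = vc))
    p_pkg <- suppressWarnings(
      permuted_association_stats(g$dosages, Z, y, plan, kin, statistic = "p",
                                 batch_size = 7L, vc = vc))
    for (k in 1:5) {
      tau <- plan$permutations[[k]]
      inv <- order(tau)
      for (j in seq_len(m)) {
        s <- g$dosages[, j]
        if (method == "x") {
          f_bf <- bf_fstat(y, Z[inv, , drop = FALSE], s[inv], K,
                           vc[[k]]$delta)
        } else {
          f_bf <- bf_fstat(y[tau], Z, s, K, vc[[k]]$delta)
        }
        expect_equal(f_pkg[k, j], f_bf, tolerance = 1e-8)
        expect_equal(p_pkg[k, j],
                     pf(f_bf, 1, n - 3, lower.tail = FALSE), tolerance = 1e-8)
      }
    }
  }
})
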