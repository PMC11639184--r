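# Shared fixtures and independent oracles. The brute-force routines work in
# original (unrotated) coordinates with explicit covariance inverses, so they
# never share code with the spectral/block implementation they check.

options(permlmm.quiet = TRUE)

# GLS via explicit H^-1 = (K + delta I)^-1
bf_gls <- function(y, X, K, delta) {
  H <- K + delta * diag(nrow(K))
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  beta <- drop(solve(XtHiX, t(X) %*% Hi %*% y))
  r <- y - drop(X %*% beta)
  list(beta = beta, rss = drop(t(r) %*% Hi %*% r), xhx_inv = solve(XtHiX))
}

# Marker p-value via two brute-force fits at fixed delta
bf_pvalue <- function(y, Z, s, K, delta) {
  f <- bf_fstat(y, Z, s, K, delta)
  pf(f, 1, length(y) - ncol(Z) - 1, lower.tail = FALSE)
}

bf_fstat <- function(y, Z, s, K, delta) {
  null_fit <- bf_gls(y, Z, K, delta)
  alt_fit <- bf_gls(y, cbind(Z, s), K, delta)
  n <- length(y)
  c_alt <- ncol(Z) + 1L
  max(null_fit$rss - alt_fit$rss, 0) / (alt_fit$rss / (n - c_alt))
}

# Random positive-definite kinship with unit mean diagonal
random_kinship <- function(n, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * (n + 5)), n)
    K <- tcrossprod(A) / (n + 5)
    K / mean(diag(K))
  })
}

# Small random genotype panel without population structure
random_genotypes <- function(n, m, seed = 1) {
  withr::with_seed(seed, {
    p <- runif(m, 0.1, 0.9)
    genotype_data(matrix(rbinom(n * m, 2, rep(p, each = n)), n, m))
  })
}

# Genotype object from an explicit dosage matrix
geno_from <- function(dos, chromosome = NULL, position = NULL) {
  genotype_data(as.matrix(dos), chromosome = chromosome, position = position)
}

# Sample skewness
skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / mean(x^2)^1.5
}

# Minimal SNP-major PLINK 1 writer (test fixture generator).
# codes: dosage 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
write_plink_fixture <- function(g, prefix) {
  dos <- g$dosages
  n <- nrow(dos); m <- ncol(dos)
  code <- matrix(3L, n, m)
  code[is.na(dos)] <- 1L
  code[!is.na(dos) & dos == 1] <- 2L
  code[!is.na(dos) & dos == 2] <- 0L
  bytes_per_marker <- ceiling(n / 4)
  out <- raw(3 + bytes_per_marker * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  pos <- 4L
  for (j in seq_len(m)) {
    padded <- c(code[, j], rep(0L, bytes_per_marker * 4 - n))
    for (b in seq_len(bytes_per_marker)) {
      q <- padded[(4 * (b - 1) + 1):(4 * b)]
      out[pos] <- as.raw(q[1] + 4L * q[2] + 16L * q[3] + 64L * q[4])
      pos <- pos + 1L
    }
  }
  writeBin(out, paste0(prefix, ".bed"))
  writeLines(paste(g$chromosome, g$marker_ids, 0, g$position, "A", "T",
                   sep = "\t"), paste0(prefix, ".bim"))
  writeLines(paste(g$sample_ids, g$sample_ids, 0, 0, 0, -9, sep = "\t"),
             paste0(prefix, ".fam"))
  invisible(prefix)
}

# Build a permutation plan with explicit permutations (bypasses the RNG)
manual_plan <- function(perms, method = "x", n = length(perms[[1]]), seed = 0L) {
  structure(list(q = length(perms), n = as.integer(n),
                 permutations = lapply(perms, as.integer),
                 seed = as.integer(seed), method = method),
            class = "permutation_plan")
}
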