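#' Simulate structured diploid genotypes (Balding-Nichols model)
#'
#' Each marker gets an ancestral allele frequency `p0 ~ Uniform(0.05, 0.95)`;
#' each subpopulation draws its own frequency from
#' `Beta(p0 (1 - F) / F, (1 - p0) (1 - F) / F)` with divergence `F` (Fst), and
#' diploid dosages are `Binomial(2, p_subpop)`. Samples are split evenly
#' across subpopulations; marker positions are drawn uniformly within
#' chromosomes (proportionally to chromosome length) and sorted within each
#' chromosome. `fst = 0` gives a panmictic population.
#'
#' @param n_samples,n_markers dimensions.
#' @param n_subpops number of subpopulations (>= 1).
#' @param fst divergence parameter in `[0, 1)`.
#' @param chromosome_lengths base-pair lengths; default five chromosomes
#'   totalling ~120 Mbp (an Arabidopsis-sized genome).
#' @param seed integer seed.
#' @return A [genotype_data] object; the subpopulation of each sample is in
#'   attribute `"subpop"`.
#' @export
simulate_genotypes <- function(n_samples, n_markers, n_subpops = 2L,
                               fst = 0.3,
                               chromosome_lengths = c(30e6, 20e6, 23e6, 19e6, 27e6),
                               seed = 1L) {
  if (n_samples < 1 || n_markers < 1) stop_pl("positive dimensions required")
  if (!is_scalar_number(fst) || fst < 0 || fst >= 1) stop_pl("fst must be in [0, 1)")
  if (n_subpops < 1) stop_pl("n_subpops must be >= 1")
  withr::with_seed(as.integer(seed), {
    subpop <- rep(seq_len(n_subpops), length.out = n_samples)
    subpop <- sort(subpop)
    p0 <- runif(n_markers, 0.05, 0.95)
    freq <- matrix(NA_real_, n_subpops, n_markers)
    if (fst == 0) {
      freq[] <- rep(p0, each = n_subpops)
    } else {
      a <- p0 * (1 - fst) / fst
      b <- (1 - p0) * (1 - fst) / fst
      for (s in seq_len(n_subpops)) freq[s, ] <- rbeta(n_markers, a, b)
      # guard degenerate draws so binomial sampling stays defined
      freq <- pmin(pmax(freq, 0), 1)
    }
    dos <- matrix(rbinom(n_samples * n_markers, 2L,
                         prob = freq[subpop, , drop = FALSE]),
                  n_samples, n_markers)
    # positions: markers allotted to chromosomes proportionally, uniform
    # positions sorted within each chromosome
    n_chr <- length(chromosome_lengths)
    chr_of <- sort(sample.int(n_chr, n_markers, replace = TRUE,
                              prob = chromosome_lengths / sum(chromosome_lengths)))
    pos <- integer(n_markers)
    for (ch in seq_len(n_chr)) {
      idx <- which(chr_of == ch)
      pos[idx] <- sort(sample.int(chromosome_lengths[ch], length(idx)))
    }
    g <- genotype_data(dos, sample_ids = sprintf("S%04d", seq_len(n_samples)),
                       marker_ids = paste0("chr", chr_of, ":", pos),
                       chromosome = paste0("chr", chr_of), position = pos)
    attr(g, "subpop") <- subpop
    g
  })
}

#' Simulate a phenotype with fixed heritability and causal explained variance
#'
#' Builds `y = beta_s s + u + eps` on the unit-variance scale: the causal
#' marker contributes `explained_variance` of the total, the polygenic
#' background `u` (Gaussian with covariance proportional to the kinship `K`)
#' contributes `heritability`, and the noise the remainder. Noise is Gaussian
#' or Gamma-distributed with the given shape (smaller shape = more skew,
#' skewness `2 / sqrt(shape)`), mean-centered after drawing.
#'
#' Scaling is empirical and exact per replicate: each component is centered,
#' orthogonalized against the preceding ones, and rescaled so its realized
#' sample variance equals its target share, so the realized shares sum to 1
#' exactly.
#'
#' @param g a [genotype_data] object.
#' @param kin a [kinship_model] on the same samples.
#' @param heritability polygenic-background share of total variance, in
#'   `(0, 1)`.
#' @param explained_variance causal-marker share, in `[0, 1)`;
#'   `heritability + explained_variance < 1`. Zero simulates a null phenotype
#'   without any causal marker.
#' @param noise `"gaussian"` or `"gamma"`.
#' @param shape Gamma shape parameter (used for `noise = "gamma"`).
#' @param causal_index marker column index of the causal SNP (required when
#'   `explained_variance > 0`).
#' @param seed integer seed.
#' @return tibble with `sample_id`, `value`; attributes `causal_marker`,
#'   `causal_chromosome`, `causal_position`, `spec`.
#' @export
simulate_phenotype <- function(g, kin, heritability, explained_variance = 0,
                               noise = c("gaussian", "gamma"), shape = 1,
                               causal_index = NULL, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(g, "genotype_data"), inherits(kin, "kinship_model"))
  check_probability(heritability, "heritability")
  if (!is_scalar_number(explained_variance) || explained_variance < 0 ||
      explained_variance >= 1) stop_pl("explained_variance must be in [0, 1)")
  if (heritability + explained_variance >= 1) {
    stop_pl("heritability + explained_variance must be < 1")
  }
  if (noise == "gamma" && (!is_scalar_number(shape) || shape <= 0)) {
    stop_pl("gamma shape must be > 0")
  }
  n <- nrow(g$dosages)
  scale_to <- function(x, v) {
    x <- x - mean(x)
    sx <- sqrt(var(x))
    if (sx == 0) stop_pl("degenerate component: zero variance")
    x * sqrt(v) / sx
  }
  # remove the projection of x onto the columns of basis (centered inputs)
  residualize <- function(x, basis) {
    if (is.null(basis)) return(x)
    x - basis %*% solve(crossprod(basis), crossprod(basis, x))
  }
  withr::with_seed(as.integer(seed), {
    comps <- NULL
    if (explained_variance > 0) {
      if (is.null(causal_index)) stop_pl("causal_index required when explained_variance > 0")
      s <- g$dosages[, causal_index]
      if (var(s) == 0) stop_pl("causal marker is monomorphic")
      s <- scale_to(s, explained_variance)
      comps <- cbind(comps, s)
    }
    u_raw <- drop(kin$U %*% (sqrt(kin$d) * rnorm(n)))
    u <- scale_to(drop(residualize(u_raw - mean(u_raw), comps)), heritability)
    comps <- cbind(comps, u)
    e_var <- 1 - heritability - explained_variance
    eps_raw <- if (noise == "gaussian") rnorm(n) else rgamma(n, shape = shape)
    eps <- scale_to(drop(residualize(eps_raw - mean(eps_raw), comps)), e_var)
    y <- rowSums(cbind(comps, eps))
  })
  out <- tibble::tibble(sample_id = g$sample_ids, value = unname(y))
  attr(out, "trait") <- "simulated"
  if (explained_variance > 0) {
    attr(out, "causal_marker") <- g$marker_ids[causal_index]
    attr(out, "causal_chromosome") <- g$chromosome[causal_index]
    attr(out, "causal_position") <- g$position[causal_index]
  }
  attr(out, "spec") <- list(heritability = heritability,
                            explained_variance = explained_variance,
                            noise = noise, shape = shape, seed = seed)
  out
}

#' Default simulation settings grid
#'
#' Noise families N (Gaussian) and Gamma with shapes 4, 3, 2, 1, 0.5, crossed
#' with heritabilities 0.1, 0.3, 0.5 and a causal marker explaining 20% of the
#' phenotypic variance.
#'
#' @return tibble with columns `setting`, `heritability`, `explained_variance`,
#'   `noise`, `shape`.
#' @export
default_battery_settings <- function() {
  grid <- expand.grid(shape = c(NA, 4, 3, 2, 1, 0.5),
                      heritability = c(0.1, 0.3, 0.5))
  tibble::tibble(
    noise = ifelse(is.na(grid$shape), "gaussian", "gamma"),
    shape = ifelse(is.na(grid$shape), 1, grid$shape),
    heritability = grid$heritability,
    explained_variance = 0.2,
    setting = paste0(ifelse(is.na(grid$shape), "N",
                            paste0("G", grid$shape)),
                     "_h", grid$heritability)
  )[, c("setting", "heritability", "explained_variance", "noise", "shape")]
}

#' Simulate a battery of phenotypes over one genotype panel
#'
#' For each settings row, draws `n_phenotypes` phenotypes with causal markers
#' sampled uniformly among markers with MAF above `causal_maf_min` (so the
#' signal is detectable at moderate sample sizes), each with its own recorded
#' seed, and binds everything to a manifest.
#'
#' @param g a [genotype_data] object.
#' @param kin a [kinship_model] on the same samples.
#' @param settings tibble like [default_battery_settings()].
#' @param n_phenotypes phenotypes per setting.
#' @param causal_maf_min MAF floor for causal-marker eligibility.
#' @param seed master seed; per-phenotype seeds are derived from it and stored
#'   in the manifest so any phenotype can be regenerated alone.
#' @return list with `Y` (n x total phenotype matrix) and `manifest` tibble
#'   (`phenotype_id`, `setting`, `seed`, `causal_marker`, `chromosome`,
#'   `position`, `heritability`, `ev`, `noise`, `shape`).
#' @export
simulation_battery <- function(g, kin, settings = default_battery_settings(),
                               n_phenotypes = 100L, causal_maf_min = 0.05,
                               seed = 1L) {
  stopifnot(inherits(g, "genotype_data"))
  maf <- minor_allele_frequency(g)
  eligible <- which(!is.na(maf) & maf > causal_maf_min)
  if (length(eligible) == 0) stop_pl("no markers with MAF > ", causal_maf_min)
  total <- nrow(settings) * n_phenotypes
  Y <- matrix(NA_real_, nrow(g$dosages), total)
  rows <- vector("list", total)
  causal_all <- withr::with_seed(as.integer(seed), {
    sample(eligible, total, replace = TRUE)
  })
  j <- 0L
  for (si in seq_len(nrow(settings))) {
    st <- settings[si, ]
    for (r in seq_len(n_phenotypes)) {
      j <- j + 1L
      pseed <- (as.integer(seed) + 7919L * j) %% 2147483647L
      ci <- if (st$explained_variance > 0) causal_all[j] else NA_integer_
      ph <- simulate_phenotype(g, kin,
                               heritability = st$heritability,
                               explained_variance = st$explained_variance,
                               noise = st$noise, shape = st$shape,
                               causal_index = if (is.na(ci)) NULL else ci,
                               seed = pseed)
      Y[, j] <- ph$value
      rows[[j]] <- tibble::tibble(
        phenotype_id = sprintf("%s_r%03d", st$setting, r),
        setting = st$setting, seed = pseed,
        causal_marker = if (is.na(ci)) NA_character_ else g$marker_ids[ci],
        chromosome = if (is.na(ci)) NA_character_ else g$chromosome[ci],
        position = if (is.na(ci)) NA_integer_ else g$position[ci],
        heritability = st$heritability, ev = st$explained_variance,
        noise = st$noise, shape = st$shape)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  colnames(Y) <- manifest$phenotype_id
  rownames(Y) <- g$sample_ids
  list(Y = Y, manifest = manifest)
}

#' Write / read a battery manifest
#'
#' @param manifest manifest tibble from [simulation_battery()].
#' @param path file path (comma-separated text).
#' @return `path` invisibly / the manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(chromosome = readr::col_character(),
                                          causal_marker = readr::col_character()))
}
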