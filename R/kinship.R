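#' Kinship model: genetic similarity matrix plus its eigendecomposition
#'
#' The eigendecomposition `K = U diag(d) U'` is the rotation basis reused by
#' every likelihood evaluation, so it is computed once and carried around with
#' the matrix. Eigenvalues below `1e-10` (floating-point negatives from a Gram
#' matrix) are clipped to 0.
#'
#' @param K symmetric n x n matrix with sample ids as dimnames.
#' @param sample_ids optional explicit sample ids.
#' @return An object of class `kinship_model` with fields `K`, `U`, `d`,
#'   `sample_ids`.
#' @export
kinship_model <- function(K, sample_ids = rownames(K)) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop_pl("kinship matrix must be square")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  dec <- spectral_decompose(K)
  dimnames(K) <- list(sample_ids, sample_ids)
  structure(list(K = K, U = dec$U, d = dec$d, sample_ids = as.character(sample_ids)),
            class = "kinship_model")
}

#' @export
print.kinship_model <- function(x, ...) {
  cat("<kinship_model> ", length(x$sample_ids), " samples, eigenvalues in [",
      format(min(x$d), digits = 4), ", ", format(max(x$d), digits = 4), "]\n",
      sep = "")
  invisible(x)
}

#' Spectral decomposition of a symmetric kinship matrix
#'
#' @param K symmetric matrix; asymmetry beyond `1e-8` relative to the largest
#'   entry is an error.
#' @param clip eigenvalues below this are set to 0.
#' @return list with orthogonal `U` (columns are eigenvectors, eigenvalues
#'   descending) and nonnegative vector `d`.
#' @export
spectral_decompose <- function(K, clip = 1e-10) {
  K <- as.matrix(K)
  scale <- max(abs(K), 1)
  if (max(abs(K - t(K))) > 1e-8 * scale) {
    stop_pl("matrix is not symmetric within tolerance")
  }
  dec <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- dec$values
  d[d < clip] <- 0
  list(U = dec$vectors, d = d)
}

#' Realized genomic relationship matrix
#'
#' Column-centers the dosage matrix to `W`, forms `W W' / m`, and rescales so
#' the mean diagonal equals 1. This is a centered (VanRaden-style) GRM without
#' per-marker variance standardization; set `standardize = TRUE` to divide each
#' centered marker by its standard deviation first. Association p-values are
#' invariant to the overall scale of K (it is absorbed into the genetic
#' variance component), so the normalization only fixes the reporting scale of
#' the variance ratio.
#'
#' @param g a [genotype_data] object with no missing values (see
#'   [impute_genotypes()]).
#' @param standardize divide centered markers by their sd (VanRaden II).
#' @return A [kinship_model].
#' @export
compute_grm <- function(g, standardize = FALSE) {
  stopifnot(inherits(g, "genotype_data"))
  X <- g$dosages
  if (anyNA(X)) stop_pl("missing dosages: run impute_genotypes() first")
  if (nrow(X) < 2) stop_pl("need at least 2 samples")
  W <- sweep(X, 2, colMeans(X))
  if (standardize) {
    s <- apply(X, 2, sd)
    keep <- s > 0
    W <- sweep(W[, keep, drop = FALSE], 2, s[keep], "/")
  }
  K <- tcrossprod(W) / ncol(W)
  md <- mean(diag(K))
  if (md <= 0) stop_pl("degenerate kinship: all markers constant")
  K <- K / md
  kinship_model(K, sample_ids = g$sample_ids)
}

#' Load a kinship matrix from delimited text
#'
#' Expects a square matrix with sample ids in the first row and column.
#' Asymmetry up to `1e-8` (relative) is symmetrized away; more is an error.
#'
#' @param path file path.
#' @return A [kinship_model].
#' @export
load_kinship <- function(path) {
  if (!file.exists(path)) stop_pl("kinship file not found: ", path)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  K <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(K) <- "double"
  if (nrow(K) != ncol(K)) stop_pl("kinship matrix is not square (",
                                  nrow(K), " x ", ncol(K), ")")
  if (!identical(ids, colnames(K))) stop_pl("kinship row/column ids disagree")
  rownames(K) <- ids
  kinship_model(K, sample_ids = ids)
}

#' Write a kinship matrix as delimited text
#' @param kin a [kinship_model].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(kin, path) {
  stopifnot(inherits(kin, "kinship_model"))
  tab <- tibble::as_tibble(kin$K, .name_repair = "minimal")
  names(tab) <- kin$sample_ids
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = kin$sample_ids), tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

# Restrict a kinship model (or plain matrix) to the given ids, re-decomposing.
subset_kinship <- function(kinship, ids) {
  K <- if (inherits(kinship, "kinship_model")) kinship$K else as.matrix(kinship)
  idx <- match(ids, rownames(K))
  if (anyNA(idx)) stop_pl("kinship is missing samples: ",
                          paste(head(ids[is.na(idx)], 5), collapse = ", "))
  if (identical(rownames(K), as.character(ids)) &&
      inherits(kinship, "kinship_model")) {
    return(kinship)
  }
  kinship_model(K[idx, idx, drop = FALSE], sample_ids = ids)
}
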