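#' Genotype container
#'
#' Bundles a sample x marker dosage matrix with marker coordinates. Dosages
#' count minor/alternate alleles and live in `[0, 2]`; heterozygous hard calls
#' are 1, imputed data may carry fractional dosages. Missing genotypes are
#' `NA`. Marker order is kept exactly as read; nothing is silently re-sorted.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns.
#' @param sample_ids character vector of row identifiers.
#' @param marker_ids character vector of column identifiers.
#' @param chromosome per-marker chromosome labels.
#' @param position per-marker 1-based base-pair positions.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, sample_ids = rownames(dosages),
                          marker_ids = colnames(dosages),
                          chromosome = NULL, position = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(m))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n) stop_pl("sample_ids length != nrow(dosages)")
  if (length(marker_ids) != m) stop_pl("marker_ids length != ncol(dosages)")
  if (is.null(chromosome) || is.null(position)) {
    parsed <- parse_marker_coords(marker_ids)
    if (is.null(chromosome)) chromosome <- parsed$chromosome
    if (is.null(position)) position <- parsed$position
  }
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  if (length(chromosome) != m || length(position) != m) {
    stop_pl("chromosome/position must have one entry per marker")
  }
  if (m > 0 && any(position <= 0L, na.rm = TRUE)) {
    stop_pl("positions must be strictly positive (1-based)")
  }
  rng <- range(dosages, na.rm = m > 0 && any(!is.na(dosages)))
  if (m > 0 && any(!is.na(dosages)) && (rng[1] < 0 || rng[2] > 2)) {
    stop_pl("dosages must lie in [0, 2] (missing values as NA)")
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids, marker_ids = marker_ids,
         chromosome = chromosome, position = position),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("<genotype_data> ", length(x$sample_ids), " samples x ",
      length(x$marker_ids), " markers, ",
      length(unique(x$chromosome)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

# "chr:pos" marker ids carry their own coordinates; anything else gets
# chromosome "1" and file-order positions.
parse_marker_coords <- function(marker_ids) {
  m <- length(marker_ids)
  hit <- grepl("^[^:]+:[0-9]+$", marker_ids)
  chromosome <- rep("1", m)
  position <- seq_len(m)
  if (any(hit)) {
    chromosome[hit] <- sub(":[0-9]+$", "", marker_ids[hit])
    position[hit] <- as.integer(sub("^[^:]+:", "", marker_ids[hit]))
  }
  list(chromosome = chromosome, position = as.integer(position))
}

#' Marker metadata as a tibble
#'
#' @param g a [genotype_data] object.
#' @return A tibble with columns `marker_id`, `chromosome`, `position`, `maf`.
#' @export
marker_info <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  tibble::tibble(marker_id = g$marker_ids, chromosome = g$chromosome,
                 position = g$position, maf = minor_allele_frequency(g))
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read genotypes
#'
#' Reads a genotype matrix from PLINK bed/bim/fam, VCF, or delimited text
#' (first column sample id, remaining columns one marker each, separator
#' auto-detected among comma and tab). VCF records that are not biallelic are
#' skipped with a logged count; dosages come from DS when present, else from GT.
#'
#' @param path file path. For `"plink-bed"` either the `.bed` file or the
#'   common prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @param format one of `"delimited"`, `"vcf"`, `"plink-bed"`; `"auto"` guesses
#'   from the file extension.
#' @return A [genotype_data] object.
#' @export
read_genotypes <- function(path, format = c("auto", "delimited", "vcf", "plink-bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.bed$", path) || file.exists(paste0(path, ".bed"))) "plink-bed"
      else "delimited"
  }
  if (format != "plink-bed" && !file.exists(path)) {
    stop_pl("genotype file not found: ", path)
  }
  switch(format,
    "delimited" = read_genotypes_delim(path),
    "vcf" = read_genotypes_vcf(path),
    "plink-bed" = read_genotypes_plink(path)
  )
}

read_genotypes_delim <- function(path) {
  delim <- guess_delim(path)
  # columns are read as character and converted with as.numeric (strtod),
  # which rounds correctly; readr's fast float path can be off by one ulp
  tab <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE, na = c("NA", ""),
                      col_types = readr::cols(.default = "c")),
    error = function(e) stop_pl("failed to parse delimited genotypes '", path,
                                "': ", conditionMessage(e))
  )
  if (ncol(tab) < 2) stop_pl("delimited genotype file needs sample id + >=1 marker column")
  ids <- as.character(tab[[1]])
  chr <- as.matrix(tab[, -1, drop = FALSE])
  mat <- suppressWarnings(matrix(as.numeric(chr), nrow(chr), ncol(chr),
                                 dimnames = dimnames(chr)))
  if (any(is.na(mat) & !is.na(chr))) {
    bad <- which(colSums(is.na(mat) & !is.na(chr)) > 0)[1]
    stop_pl("non-numeric dosages in column '", colnames(chr)[bad], "' of ", path)
  }
  genotype_data(mat, sample_ids = ids, marker_ids = colnames(mat))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1
  n_skip <- sum(!biallelic)
  if (n_skip > 0) pl_log("skipped ", n_skip, " non-biallelic VCF record(s)")
  if (!any(biallelic)) stop_pl("no biallelic records in ", path)
  v <- v[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    ds[clean %in% c("0/0")] <- 0
    ds[clean %in% c("0/1", "1/0")] <- 1
    ds[clean %in% c("1/1")] <- 2
    ds[clean %in% c("0")] <- 0   # haploid calls
    ds[clean %in% c("1")] <- 2
  }
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], ":", fix[miss_id, "POS"])
  genotype_data(t(ds), sample_ids = colnames(ds), marker_ids = ids,
                chromosome = fix[, "CHROM"], position = as.integer(fix[, "POS"]))
}

# Minimal SNP-major PLINK 1 .bed reader. Two-bit codes per sample:
# 00 -> 2 copies of allele A1, 10 -> 1, 11 -> 0, 01 -> missing.
read_genotypes_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_pl("PLINK file not found: ", f)
  }
  bim_tab <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                               col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_tab <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_tab)
  m <- nrow(bim_tab)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop_pl(bed, " is not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) stop_pl("only SNP-major .bed files are supported")
  bytes_per_marker <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_marker * m) {
    stop_pl(".bed size inconsistent with .bim/.fam dimensions")
  }
  # decode all two-bit fields at once
  mat0 <- matrix(as.integer(body), nrow = bytes_per_marker, ncol = m)
  lookup <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  dos <- matrix(NA_real_, nrow = n, ncol = m)
  for (shift in 0:3) {
    rows <- seq.int(shift + 1L, by = 4L, length.out = bytes_per_marker)
    rows <- rows[rows <= n]
    if (!length(rows)) next
    codes <- mat0[seq_along(rows), , drop = FALSE] %/% (4L^shift) %% 4L
    dos[rows, ] <- lookup[codes + 1L]
  }
  genotype_data(dos, sample_ids = as.character(fam_tab[[2]]),
                marker_ids = bim_tab$id,
                chromosome = as.character(bim_tab$chrom),
                position = bim_tab$pos)
}

#' Write genotypes as delimited text
#'
#' Comma-separated, first column `sample_id`, one column per marker named
#' `"<chromosome>:<position>"` so coordinates round-trip through
#' [read_genotypes()].
#'
#' @param g a [genotype_data] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_data"))
  cols <- paste0(g$chromosome, ":", g$position)
  if (anyDuplicated(cols)) cols <- make.unique(cols, sep = "_")
  # 17 significant digits make the decimal representation round-trip exactly
  chr <- apply(g$dosages, 2, function(x) format(x, digits = 17, trim = TRUE))
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(g$dosages))
  tab <- tibble::as_tibble(chr, .name_repair = "minimal")
  names(tab) <- cols
  tab <- dplyr::bind_cols(tibble::tibble(sample_id = g$sample_ids), tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with a sample-id column and one or more trait columns.
#'
#' @param path file path.
#' @param trait trait column to select; default the first non-id column.
#' @return A tibble with columns `sample_id` and `value`; the trait name is
#'   stored in the `trait` attribute. Missing values are dropped with a log.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  if (!file.exists(path)) stop_pl("phenotype file not found: ", path)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) stop_pl("phenotype file needs sample id + >=1 trait column")
  trait <- trait %||% names(tab)[2]
  if (!trait %in% names(tab)) stop_pl("trait '", trait, "' not in ", path)
  out <- tibble::tibble(sample_id = as.character(tab[[1]]),
                        value = as.numeric(tab[[trait]]))
  n_miss <- sum(is.na(out$value))
  if (n_miss > 0) {
    pl_log("dropped ", n_miss, " sample(s) with missing phenotype")
    out <- out[!is.na(out$value), ]
  }
  if (nrow(out) == 0) stop_pl("no non-missing phenotype values for '", trait, "'")
  attr(out, "trait") <- trait
  out
}

#' Read a covariate table into a fixed-effects matrix
#'
#' @param path delimited file: sample id column then numeric covariates.
#' @return A numeric matrix with sample ids as rownames (no intercept column;
#'   the intercept is added by the model code).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_pl("covariate file not found: ", path)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1]])
  mat
}

# Build the n x c fixed-effects matrix: intercept first, covariates after.
# Full column rank is checked here so collinear covariates fail early.
fixed_effects_matrix <- function(n, covariates = NULL, sample_ids = NULL) {
  Z <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_pl("covariate rows do not match sample count")
    Z <- cbind(Z, covariates)
  }
  if (qr(Z)$rank < ncol(Z)) stop_pl("fixed-effects matrix is rank deficient")
  if (!is.null(sample_ids)) rownames(Z) <- sample_ids
  Z
}

#' Align samples across genotype, phenotype, covariates and kinship
#'
#' Intersects sample ids, orders every source by the genotype's id order, and
#' drops (with a log) samples missing from any source.
#'
#' @param g a [genotype_data] object.
#' @param phenotype tibble with `sample_id`, `value` (see [read_phenotypes()]).
#' @param covariates optional matrix with sample ids as rownames.
#' @param kinship optional [kinship_model] or plain matrix with id dimnames.
#' @return A list with elements `genotypes`, `y` (named numeric), `covariates`,
#'   `kinship`, `sample_ids`.
#' @export
align_samples <- function(g, phenotype, covariates = NULL, kinship = NULL) {
  stopifnot(inherits(g, "genotype_data"))
  ids <- g$sample_ids
  ids <- ids[ids %in% phenotype$sample_id]
  if (!is.null(covariates)) ids <- ids[ids %in% rownames(covariates)]
  if (!is.null(kinship)) {
    kin_ids <- if (inherits(kinship, "kinship_model")) kinship$sample_ids
      else rownames(kinship)
    ids <- ids[ids %in% kin_ids]
  }
  if (length(ids) == 0) stop_pl("no samples shared across all inputs")
  n_drop <- length(union(g$sample_ids, phenotype$sample_id)) - length(ids)
  if (n_drop > 0) pl_log("dropped ", n_drop, " sample(s) absent from some input")
  gi <- match(ids, g$sample_ids)
  g2 <- genotype_data(g$dosages[gi, , drop = FALSE], sample_ids = ids,
                      marker_ids = g$marker_ids, chromosome = g$chromosome,
                      position = g$position)
  y <- setNames(phenotype$value[match(ids, phenotype$sample_id)], ids)
  cov2 <- if (is.null(covariates)) NULL
    else covariates[match(ids, rownames(covariates)), , drop = FALSE]
  kin2 <- if (is.null(kinship)) NULL else subset_kinship(kinship, ids)
  list(genotypes = g2, y = y, covariates = cov2, kinship = kin2,
       sample_ids = ids)
}

#' Per-marker minor allele frequency
#'
#' `f = mean(dosage) / 2` over non-missing samples; `MAF = min(f, 1 - f)`.
#' Markers with every value missing get `NA` and are flagged for removal by
#' [maf_filter()].
#'
#' @param g a [genotype_data] object.
#' @return numeric vector of length `m` in `[0, 0.5]` (or `NA`).
#' @export
minor_allele_frequency <- function(g) {
  stopifnot(inherits(g, "genotype_data"))
  f <- colMeans(g$dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  unname(pmin(f, 1 - f))
}

#' Filter markers by minor allele frequency
#'
#' Keeps markers with `MAF > threshold` (strict). Markers whose MAF is
#' undefined (all missing) are always removed.
#'
#' @param g a [genotype_data] object.
#' @param threshold real in `[0, 0.5]`.
#' @return A filtered [genotype_data] object.
#' @export
maf_filter <- function(g, threshold = 0.05) {
  stopifnot(inherits(g, "genotype_data"))
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 0.5) {
    stop_pl("threshold must be in [0, 0.5]")
  }
  maf <- minor_allele_frequency(g)
  keep <- !is.na(maf) & maf > threshold
  if (!any(keep)) stop_pl("no markers pass MAF > ", threshold)
  pl_log(sum(keep), " of ", length(keep), " markers pass MAF > ", threshold)
  genotype_data(g$dosages[, keep, drop = FALSE], sample_ids = g$sample_ids,
                marker_ids = g$marker_ids[keep], chromosome = g$chromosome[keep],
                position = g$position[keep])
}

#' Mean-impute missing genotypes
#'
#' Markers with more than `max_missing` missingness are dropped; remaining
#' `NA`s are replaced by the per-marker mean dosage so batch shapes stay
#' rectangular.
#'
#' @param g a [genotype_data] object.
#' @param max_missing highest tolerated per-marker missing fraction.
#' @return A [genotype_data] object with no missing values.
#' @export
impute_genotypes <- function(g, max_missing = 0.1) {
  stopifnot(inherits(g, "genotype_data"))
  miss <- colMeans(is.na(g$dosages))
  keep <- miss <= max_missing
  if (!any(keep)) stop_pl("every marker exceeds ", max_missing, " missingness")
  if (any(!keep)) pl_log("dropped ", sum(!keep), " marker(s) with > ",
                         100 * max_missing, "% missing genotypes")
  dos <- g$dosages[, keep, drop = FALSE]
  nas <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(dos, na.rm = TRUE)
    dos[nas] <- mu[nas[, 2]]
  }
  genotype_data(dos, sample_ids = g$sample_ids, marker_ids = g$marker_ids[keep],
                chromosome = g$chromosome[keep], position = g$position[keep])
}

#' Write association results (and optional permutation summary)
#'
#' The association table goes to `path` as comma-separated text with columns
#' `chromosome, position, marker_id, maf, beta, se_beta, f_stat, p_value`.
#' When a permutation summary is given, a second file `<path stem>_minp.csv`
#' holds one minimal p-value per permutation under a `#key=value` header
#' recording q, alpha, seed, method and threshold.
#'
#' @param assoc association tibble (see [lmm_scan()]).
#' @param path output file for the association table.
#' @param perm optional `permutation_summary` object.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(assoc, path, perm = NULL) {
  if (nrow(assoc) == 0) stop_pl("association table is empty")
  cols <- c("chromosome", "position", "marker_id", "maf", "beta", "se_beta",
            "f_stat", "p_value")
  readr::write_csv(dplyr::select(assoc, dplyr::all_of(cols)), path,
                   progress = FALSE)
  paths <- path
  if (!is.null(perm)) {
    stopifnot(inherits(perm, "permutation_summary"))
    ppath <- sub("(\\.[A-Za-z]+)?$", "_minp.csv", path)
    hdr <- c(paste0("#q=", perm$q), paste0("#alpha=", perm$alpha),
             paste0("#seed=", perm$seed), paste0("#method=", perm$method),
             paste0("#threshold=", format(perm$threshold, digits = 17)),
             paste0("#quantile=linear-interpolation"))
    writeLines(c(hdr, "min_p", format(perm$min_p, digits = 17)), ppath)
    paths <- c(paths, ppath)
  }
  invisible(paths)
}

#' Read back an association table written by [write_results()]
#' @param path file path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(chromosome = readr::col_character()))
}
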