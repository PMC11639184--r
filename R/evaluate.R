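#' Classify one phenotype's scan as true/false positive
#'
#' A phenotype counts as a true positive when any significant marker lies
#' within `window_bp` of the causal SNP on the same chromosome (two-sided,
#' boundary inclusive), and as a false positive when any significant marker
#' lies outside that window (any chromosome). A phenotype can be both at
#' once.
#'
#' @param assoc association tibble with `chromosome`, `position`, `p_value`.
#' @param threshold significance threshold on the p-value scale.
#' @param causal_chromosome,causal_position coordinates of the causal SNP.
#' @param window_bp half-width of the window in base pairs.
#' @return list with logicals `is_tp`, `is_fp`.
#' @export
classify_phenotype <- function(assoc, threshold, causal_chromosome,
                               causal_position, window_bp) {
  if (window_bp < 0) stop_pl("window_bp must be >= 0")
  if (!any(assoc$chromosome == causal_chromosome &
           assoc$position == causal_position)) {
    stop_pl("causal SNP ", causal_chromosome, ":", causal_position,
            " absent from the marker map")
  }
  sig <- !is.na(assoc$p_value) & assoc$p_value <= threshold
  in_window <- assoc$chromosome == causal_chromosome &
    abs(assoc$position - causal_position) <= window_bp
  list(is_tp = any(sig & in_window), is_fp = any(sig & !in_window))
}

#' Phenotype-wise false discovery rate
#'
#' `pFDR = FP / (TP + FP)` over a set of phenotype classifications, where TP
#' and FP count phenotypes (not markers). Undefined — returned as `NA` — when
#' no phenotype is positive at all.
#'
#' @param classifications list of `list(is_tp, is_fp)` as produced by
#'   [classify_phenotype()].
#' @return scalar in `[0, 1]` or `NA`.
#' @export
pfdr <- function(classifications) {
  if (length(classifications) == 0) stop_pl("no classifications")
  tp <- sum(vapply(classifications, `[[`, logical(1), "is_tp"))
  fp <- sum(vapply(classifications, `[[`, logical(1), "is_fp"))
  if (tp + fp == 0) return(NA_real_)
  fp / (tp + fp)
}

#' Evaluate a phenotype battery across threshold methods
#'
#' For every (setting, method) pair, classifies each phenotype with its
#' per-phenotype threshold and aggregates TP/FP counts into the phenotype-wise
#' FDR. The spread of the permutation thresholds per setting is reported
#' alongside (mean and quartiles), since adaptive thresholds — unlike
#' Bonferroni — vary across phenotypes.
#'
#' @param manifest battery manifest (see [simulation_battery()]).
#' @param results named list: one element per method, each a list (one entry
#'   per manifest row) of `list(assoc = tibble, threshold = scalar)`.
#' @param window_bp classification window half-width.
#' @return tibble with one row per (setting, method): `setting`, `method`,
#'   `n_phenotypes`, `tp`, `fp`, `pfdr`, `mean_threshold`, `threshold_q25`,
#'   `threshold_q75`.
#' @export
evaluate_battery <- function(manifest, results, window_bp) {
  methods <- names(results)
  if (is.null(methods) || any(methods == "")) stop_pl("results must be a named list of methods")
  out <- list()
  for (mth in methods) {
    res <- results[[mth]]
    if (length(res) != nrow(manifest)) {
      missing_idx <- setdiff(seq_len(nrow(manifest)), seq_along(res))
      stop_pl("method '", mth, "' lacks results for phenotype(s): ",
              paste(head(manifest$phenotype_id[missing_idx], 5), collapse = ", "))
    }
    for (st in unique(manifest$setting)) {
      idx <- which(manifest$setting == st)
      cls <- lapply(idx, function(i) {
        r <- res[[i]]
        if (is.null(r)) stop_pl("method '", mth, "' missing result for phenotype ",
                                manifest$phenotype_id[i])
        classify_phenotype(r$assoc, r$threshold,
                           manifest$chromosome[i], manifest$position[i],
                           window_bp)
      })
      thr <- vapply(idx, function(i) res[[i]]$threshold, numeric(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        setting = st, method = mth, n_phenotypes = length(idx),
        tp = sum(vapply(cls, `[[`, logical(1), "is_tp")),
        fp = sum(vapply(cls, `[[`, logical(1), "is_fp")),
        pfdr = pfdr(cls),
        mean_threshold = mean(thr),
        threshold_q25 = unname(quantile(thr, 0.25, type = 7)),
        threshold_q75 = unname(quantile(thr, 0.75, type = 7)))
    }
  }
  dplyr::bind_rows(out)
}

#' Write a battery evaluation summary
#' @param summary tibble from [evaluate_battery()].
#' @param path output file (comma-separated text).
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(summary, path) {
  readr::write_csv(summary, path, progress = FALSE)
  invisible(path)
}
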