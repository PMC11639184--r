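#' @importFrom rlang abort warn inform %||%
#' @importFrom stats pf qnorm quantile rbinom rgamma rnorm runif rbeta var sd optimize setNames
#' @importFrom utils head tail
NULL

# Internal messaging: every drop/skip count goes through here so pipelines can
# silence it with options(permlmm.quiet = TRUE).
pl_log <- function(...) {
  if (!isTRUE(getOption("permlmm.quiet", FALSE))) {
    rlang::inform(paste0(...), class = "permlmm_log")
  }
  invisible(NULL)
}

stop_pl <- function(..., class = "permlmm_error") {
  rlang::abort(paste0(...), class = class)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_probability <- function(x, name, open = TRUE) {
  if (!is_scalar_number(x)) stop_pl(name, " must be a single finite number")
  lo <- if (open) x > 0 else x >= 0
  hi <- if (open) x < 1 else x <= 1
  if (!lo || !hi) {
    stop_pl(name, " must lie in ", if (open) "(0, 1)" else "[0, 1]",
            ", got ", format(x))
  }
  invisible(x)
}

# Validate that tau is a bijection of 1..n
check_permutation <- function(tau, n) {
  if (length(tau) != n || !identical(sort(as.integer(tau)), seq_len(n))) {
    stop_pl("'tau' is not a permutation of 1..", n)
  }
  as.integer(tau)
}

# inverse permutation: inv[tau[i]] = i
invert_permutation <- function(tau) order(tau)
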