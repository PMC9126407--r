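#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats pnorm pt qnorm rnorm runif rbinom cor var sd qlogis plogis
#'   uniroot p.adjust complete.cases
#' @importFrom utils head
NULL

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when b >= a (difference
# underflows to an analytic zero, e.g. single-variant H3)
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` must lie in %s0, 1%s, got %g.", name,
                  if (open_left) "(" else "[", if (open_right) ")" else "]", x))
  }
  invisible(x)
}

# residuals of y (vector or matrix) on design X via QR; X must be full rank
resid_on <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort(sprintf("covariate design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  qr.resid(qr_x, y)
}

as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cm <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(cm)) abort("covariates must be numeric")
  if (nrow(cm) != n) abort("covariates must have one row per sample")
  if (is.null(colnames(cm))) colnames(cm) <- paste0("cov", seq_len(ncol(cm)))
  cm
}
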