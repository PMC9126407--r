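#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an hierarchical FDR fit
#'
#' @param x An `hfdr_result`.
#' @param level `"variants"` (default) or `"regions"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hfdr_result <- function(x, level = c("variants", "regions"), ...) {
  level <- match.arg(level)
  if (level == "regions") x$regions else x$variants
}

#' @rdname tidy.hfdr_result
#' @export
glance.hfdr_result <- function(x, ...) {
  tibble::tibble(m = x$m, k = x$k, alpha1 = x$alpha1, alpha2 = x$alpha2,
                 n_significant = sum(x$variants$significant))
}

#' Tidy a co-localization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Long tibble of hypotheses and posterior probabilities.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = c("H0", "H1", "H2", "H3", "H4"),
                 posterior = unname(x$pp))
}

#' @rdname tidy.coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(pp0 = x$pp[["pp0"]], pp1 = x$pp[["pp1"]],
                 pp2 = x$pp[["pp2"]], pp3 = x$pp[["pp3"]],
                 pp4 = x$pp[["pp4"]], n_variants = x$n_variants,
                 n_dropped = x$n_dropped, verdict = x$verdict)
}

#' Tidy a mediation chain
#'
#' @param x A `causal_chain`.
#' @param ... Unused.
#' @return Long tibble of the chain's effects with standard errors.
#' @export
tidy.causal_chain <- function(x, ...) {
  tibble::tibble(
    term = c("ge_pe", "pe_outcome", "indirect", "total", "difference"),
    estimate = c(x$beta1, x$beta2, x$indirect, x$total, x$diff),
    std.error = c(x$se1, x$se2, x$se_indirect, x$se_total,
                  sqrt(x$se_total^2 + x$se_indirect^2)))
}

#' @rdname tidy.causal_chain
#' @export
glance.causal_chain <- function(x, ...) {
  tibble::tibble(indirect = x$indirect, total = x$total,
                 diff_p = x$diff_p, verdict = x$verdict)
}
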