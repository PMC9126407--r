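#' Select a Mendelian-randomization instrument from a scan
#'
#' Returns the lead variant of the summary statistics if it passes the
#' genome-wide instrument threshold (`p < p_max`, default 5e-8); otherwise
#' returns an empty tibble and the exposure is excluded from MR.
#'
#' @param stats Summary-statistics tibble.
#' @param p_max Instrument p-value threshold (strict `<`).
#' @return One-row tibble (the instrument) or a zero-row tibble.
#' @export
select_instrument <- function(stats, p_max = 5e-8) {
  lead <- lead_variant(stats)
  if (lead$p < p_max) lead else lead[0, ]
}

#' Ratio (Wald) Mendelian-randomization estimate
#'
#' Single-instrument causal estimate \eqn{\hat\beta_{IV} = \beta_y / \beta_x}
#' with the delta-method standard error from the first two terms of the
#' Taylor expansion of the ratio:
#' \deqn{se_{IV} = \sqrt{\frac{se_y^2}{\beta_x^2} +
#'   \frac{\beta_y^2\, se_x^2}{\beta_x^4}},}
#' and a two-sided p-value from the standard normal reference.
#'
#' @param beta_x,se_x Instrument-exposure effect and SE (`beta_x` nonzero).
#' @param beta_y,se_y Instrument-outcome effect and SE.
#' @return One-row tibble: `beta_iv`, `se_iv`, `z`, `p` (vectorised inputs
#'   give one row each).
#' @export
#' @examples
#' mr_ratio(0.5, 0.05, 0.2, 0.04)
mr_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0)) abort("`beta_x` must be nonzero (degenerate instrument)")
  if (any(se_x < 0) || any(se_y < 0)) abort("standard errors must be non-negative")
  beta_iv <- beta_y / beta_x
  se_iv <- sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  z <- beta_iv / se_iv
  tibble::tibble(beta_iv = beta_iv, se_iv = se_iv, z = z,
                 p = 2 * pnorm(-abs(z)))
}

#' Run a battery of single-instrument MR tests with multiplicity control
#'
#' For each exposure (one pre-selected instrument per row), looks up the
#' instrument in the outcome summary statistics, computes the ratio estimate,
#' and adjusts the p-values either by Bonferroni (`p * n_tests`, the scheme
#' used for the protein -> disease stage) or by the hierarchical
#' Simes/Benjamini-Bogomolov scheme over genes and tissues (the scheme used
#' for the expression -> protein stage; requires `gene_id` and `tissue`
#' columns).
#'
#' @param instruments Tibble with one row per exposure test: identifier
#'   columns (e.g. `exposure_id` or `gene_id` + `tissue`), `variant_id`,
#'   `beta_x`, `se_x`.
#' @param outcome_stats Summary statistics of the outcome trait keyed by
#'   `variant_id` (columns `beta`, `se`).
#' @param correction `"bonferroni"` or `"hierarchical"`.
#' @param n_tests Number of tests for Bonferroni (default `nrow(instruments)`).
#' @param alpha Significance level applied to adjusted p-values.
#' @return `instruments` with `beta_y`, `se_y`, `beta_iv`, `se_iv`, `z`, `p`,
#'   `p_adj` (Bonferroni) or `significant` flag appended; instruments missing
#'   from the outcome stats are dropped with a message.
#' @export
mr_battery <- function(instruments, outcome_stats,
                       correction = c("bonferroni", "hierarchical"),
                       n_tests = NULL, alpha = 0.05) {
  correction <- match.arg(correction)
  hit <- match(instruments$variant_id, outcome_stats$variant_id)
  if (anyNA(hit)) {
    inform(sprintf("dropping %d instrument(s) absent from outcome statistics",
                   sum(is.na(hit))))
    instruments <- instruments[!is.na(hit), ]
    hit <- hit[!is.na(hit)]
  }
  if (nrow(instruments) == 0L) abort("no instruments resolvable in outcome stats")
  out <- instruments
  out$beta_y <- outcome_stats$beta[hit]
  out$se_y <- outcome_stats$se[hit]
  est <- mr_ratio(out$beta_x, out$se_x, out$beta_y, out$se_y)
  out <- dplyr::bind_cols(out, est)
  if (correction == "bonferroni") {
    n_tests <- n_tests %||% nrow(out)
    out$p_adj <- pmin(1, out$p * n_tests)
    out$significant <- out$p_adj <= alpha
  } else {
    if (!all(c("gene_id", "tissue") %in% names(out))) {
      abort("hierarchical correction needs `gene_id` and `tissue` columns")
    }
    fit <- hierarchical_fdr_tissues(out, alpha1 = alpha)
    out <- fit$variants
  }
  out
}
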