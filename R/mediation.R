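#' Mediation analysis of an expression -> protein -> disease chain
#'
#' Combines three single-instrument MR legs for one gene-tissue-protein
#' triple: expression on protein (\eqn{\beta_1}), protein on disease
#' (\eqn{\beta_2}) and the total expression-on-disease effect. The indirect
#' (mediated) effect is the product \eqn{\beta_1 \beta_2} with the
#' product-delta-method standard error
#' \eqn{se_{ind} = \sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}}; the
#' difference test compares total and indirect effects,
#' \eqn{z = (total - indirect) / \sqrt{se_{tot}^2 + se_{ind}^2}}, treating
#' the two as independent (a conservative simplification). The verdict is
#' `"complete_mediation"` when the total and indirect effects are both
#' significant at `alpha` but their difference is not; `"partial_mediation"`
#' when all three are significant; otherwise `"no_mediation"`. A chain with
#' any missing leg is returned as incomplete without a verdict.
#'
#' @param mr_ge_pe,mr_pe_cad,mr_ge_cad One-row MR results (as from
#'   [mr_ratio()]) for the three legs, or `NULL` for a missing leg.
#' @param gene_id,tissue Optional identifiers carried into the result.
#' @param alpha Significance level for the verdict.
#' @return A one-row `causal_chain` tibble: `beta1`, `se1`, `beta2`, `se2`,
#'   `indirect`, `se_indirect`, `indirect_p`, `total`, `se_total`, `total_p`,
#'   `diff`, `diff_z`, `diff_p`, `complete`, `verdict`.
#' @export
#' @examples
#' # IL6R-style worked example: two negative legs give a positive
#' # mediated effect on disease
#' ch <- mediation_chain(
#'   mr_ge_pe = list(beta_iv = -3.008, se_iv = 0.363),
#'   mr_pe_cad = list(beta_iv = -0.094, se_iv = 0.0125),
#'   mr_ge_cad = list(beta_iv = 0.28, se_iv = 0.05))
#' ch$indirect
mediation_chain <- function(mr_ge_pe, mr_pe_cad, mr_ge_cad,
                            gene_id = NA_character_, tissue = NA_character_,
                            alpha = 0.05) {
  leg <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(NULL)
    list(beta = x$beta_iv[1], se = x$se_iv[1])
  }
  l1 <- leg(mr_ge_pe); l2 <- leg(mr_pe_cad); lt <- leg(mr_ge_cad)
  if (is.null(l1) || is.null(l2) || is.null(lt)) {
    return(structure(tibble::tibble(
      gene_id = gene_id, tissue = tissue,
      beta1 = if (is.null(l1)) NA_real_ else l1$beta,
      se1 = if (is.null(l1)) NA_real_ else l1$se,
      beta2 = if (is.null(l2)) NA_real_ else l2$beta,
      se2 = if (is.null(l2)) NA_real_ else l2$se,
      indirect = NA_real_, se_indirect = NA_real_, indirect_p = NA_real_,
      total = if (is.null(lt)) NA_real_ else lt$beta,
      se_total = if (is.null(lt)) NA_real_ else lt$se,
      total_p = NA_real_, diff = NA_real_, diff_z = NA_real_,
      diff_p = NA_real_, complete = FALSE, verdict = NA_character_),
      class = c("causal_chain", "tbl_df", "tbl", "data.frame")))
  }
  indirect <- l1$beta * l2$beta
  se_ind <- sqrt(l1$beta^2 * l2$se^2 + l2$beta^2 * l1$se^2)
  indirect_p <- 2 * pnorm(-abs(indirect / se_ind))
  total_p <- 2 * pnorm(-abs(lt$beta / lt$se))
  diff <- lt$beta - indirect
  diff_se <- sqrt(lt$se^2 + se_ind^2)
  diff_z <- diff / diff_se
  diff_p <- 2 * pnorm(-abs(diff_z))
  verdict <- if (total_p <= alpha && indirect_p <= alpha && diff_p > alpha) {
    "complete_mediation"
  } else if (total_p <= alpha && indirect_p <= alpha) {
    "partial_mediation"
  } else "no_mediation"
  structure(tibble::tibble(
    gene_id = gene_id, tissue = tissue,
    beta1 = l1$beta, se1 = l1$se, beta2 = l2$beta, se2 = l2$se,
    indirect = indirect, se_indirect = se_ind, indirect_p = indirect_p,
    total = lt$beta, se_total = lt$se, total_p = total_p,
    diff = diff, diff_z = diff_z, diff_p = diff_p,
    complete = TRUE, verdict = verdict),
    class = c("causal_chain", "tbl_df", "tbl", "data.frame"))
}
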