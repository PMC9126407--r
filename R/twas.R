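#' Predict genetically regulated expression from a weight model
#'
#' Computes, per sample, the weighted dosage sum
#' \eqn{gGE = \sum_l w_l \, dosage_l} for one gene-tissue weight model.
#' Model variants absent from the genotype matrix are dropped with a message.
#'
#' @param geno A [genotype_matrix()].
#' @param weights Weight-model tibble with `variant_id`, `effect_allele`,
#'   `weight` (rows of one gene-tissue model).
#' @return Numeric vector of predicted expression, one value per sample.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_samples = 200, seed = 5))
#' w <- true_weight_models(study$truth)
#' gge <- predict_expression(study$geno, w[w$gene_id == "G01", ])
predict_expression <- function(geno, weights) {
  usable <- weights$variant_id %in% geno$variants$variant_id
  if (any(!usable)) {
    inform(sprintf("dropping %d model variant(s) absent from genotypes",
                   sum(!usable)))
  }
  weights <- weights[usable, ]
  if (nrow(weights) == 0L) abort("no usable model variants")
  # orient weights to the genotype effect allele
  meta <- geno$variants[match(weights$variant_id, geno$variants$variant_id), ]
  # NA effect allele means the weight is already oriented to the panel allele
  w <- ifelse(!is.na(weights$effect_allele) &
                weights$effect_allele != meta$effect_allele,
              -weights$weight, weights$weight)
  drop(geno$dosages[, weights$variant_id, drop = FALSE] %*% w)
}

#' Summary-statistics association of predicted expression with a trait
#'
#' The summary-level analogue of regressing a trait on predicted expression:
#' given per-variant trait summary statistics, a gene's variant weights and
#' an LD reference panel, the gene-level z-score is
#' \deqn{z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} \frac{\beta_l}{se_l}}
#' with \eqn{\sigma_l^2} the panel dosage variance of variant l and
#' \eqn{\sigma_g^2 = w^\top \Gamma w} the variance of the predicted
#' expression under the panel covariance \eqn{\Gamma}. The effect estimate
#' per unit of predicted expression is
#' \eqn{\sum_l w_l \sigma_l^2 \beta_l / \sigma_g^2}.
#'
#' @param stats Trait summary statistics (`variant_id`, `effect_allele`,
#'   `beta`, `se`).
#' @param weights One gene-tissue weight model (`gene_id`, `tissue`,
#'   `variant_id`, `effect_allele`, `weight`).
#' @param ld_ref A [genotype_matrix()] LD reference panel.
#' @return One-row `twas_result` tibble: `gene_id`, `tissue`, `effect`, `z`,
#'   `p`, `n_variants_used`.
#' @export
summary_twas <- function(stats, weights, ld_ref) {
  h <- dplyr::inner_join(
    dplyr::select(weights, "variant_id", w_ea = "effect_allele", "weight"),
    dplyr::select(stats, "variant_id", s_ea = "effect_allele",
                  s_oa = dplyr::any_of("other_allele"), "beta", "se"),
    by = "variant_id")
  h <- h[h$variant_id %in% ld_ref$variants$variant_id, ]
  if (nrow(h) == 0L) abort("no model variants usable in stats + LD panel")
  # orient stats to the model's effect allele (NA model allele: already aligned)
  flip <- !is.na(h$w_ea) & h$w_ea != h$s_ea
  h$beta[flip] <- -h$beta[flip]
  meta <- ld_ref$variants[match(h$variant_id, ld_ref$variants$variant_id), ]
  w <- ifelse(!is.na(h$w_ea) & h$w_ea != meta$effect_allele,
              -h$weight, h$weight)
  D <- ld_ref$dosages[, h$variant_id, drop = FALSE]
  Gam <- stats::cov(D)
  sig2_l <- diag(Gam)
  sig2_g <- drop(t(w) %*% Gam %*% w)
  if (sig2_g <= 0) abort("degenerate LD panel: predicted expression has zero variance")
  z <- sum(w * sqrt(sig2_l) / sqrt(sig2_g) * h$beta / h$se)
  effect <- sum(w * sig2_l * h$beta) / sig2_g
  tibble::tibble(
    gene_id = weights$gene_id[1] %||% NA_character_,
    tissue = weights$tissue[1] %||% NA_character_,
    effect = effect, z = z, p = 2 * pnorm(-abs(z)),
    n_variants_used = nrow(h))
}

#' Hierarchical FDR over gene-tissue association results
#'
#' Applies the two-level Simes + Benjamini-Bogomolov scheme of
#' [hierarchical_fdr()] with genes/proteins as the families (second level)
#' and tissues as the within-family tests (first level).
#'
#' @param results Tibble of per gene-tissue results with `gene_id`, `tissue`
#'   and `p` columns (e.g. stacked [summary_twas()] rows).
#' @param alpha1 Family-level FDR target.
#' @return An `hfdr_result` whose "regions" are genes and whose "variants"
#'   are gene-tissue pairs.
#' @export
hierarchical_fdr_tissues <- function(results, alpha1 = 0.05) {
  hierarchical_fdr(results, alpha1 = alpha1, region_col = "gene_id")
}

#' True weight models of a simulated study
#'
#' Exports the single-variant ground-truth prediction models implied by a
#' simulation truth table (weight = true per-allele expression effect at the
#' causal variant), in the standard weight-model layout, for every tissue.
#'
#' @param truth Output of [simulate_truth()].
#' @param tissues Tissue labels (default the blood-like tissue only).
#' @param geno Optional [genotype_matrix()] used to attach effect alleles.
#' @return Weight-model tibble: `gene_id`, `tissue`, `variant_id`,
#'   `effect_allele`, `weight`.
#' @export
true_weight_models <- function(truth, tissues = "tissue01", geno = NULL) {
  rows <- truth[!is.na(truth$causal_ge_id), ]
  out <- tidyr::expand_grid(tissue = tissues,
                            gene_id = rows$gene_id) |>
    dplyr::left_join(dplyr::select(rows, "gene_id",
                                   variant_id = "causal_ge_id",
                                   weight = "beta_ge"),
                     by = "gene_id")
  ea <- if (!is.null(geno)) {
    geno$variants$effect_allele[match(out$variant_id,
                                      geno$variants$variant_id)]
  } else NA_character_
  out$effect_allele <- ea
  dplyr::select(out, "gene_id", "tissue", "variant_id", "effect_allele",
                "weight")
}
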