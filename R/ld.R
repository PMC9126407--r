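#' Pairwise LD between two variants
#'
#' Squared Pearson correlation of the dosage columns, the standard
#' dosage-based r-squared.
#'
#' @param geno A [genotype_matrix()].
#' @param i,j Variant ids (character) or column indices.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(geno, i, j) {
  di <- geno$dosages[, i]
  dj <- geno$dosages[, j]
  if (sd(di) == 0 || sd(dj) == 0) abort("monomorphic variant: LD undefined")
  cor(di, dj)^2
}

# full pairwise r2 matrix for a set of variant ids
ld_r2_matrix <- function(geno, ids) {
  D <- geno$dosages[, ids, drop = FALSE]
  if (any(apply(D, 2, sd) == 0)) abort("monomorphic variant: LD undefined")
  cor(D)^2
}

#' Priority pruning of association signals by LD
#'
#' Greedy selection in ascending p-value order (ties resolved as in
#' [lead_variant()]): a variant is kept if and only if its LD r-squared with
#' every previously kept variant is below `r2_max`. The output is a set of
#' signals in approximate linkage equilibrium, ordered by p-value, and all
#' pairwise r-squared among kept variants are below the cap by construction.
#'
#' @param stats Summary-statistics tibble (typically already restricted to
#'   significant variants).
#' @param geno The [genotype_matrix()] providing the LD panel.
#' @param r2_max LD cap (default 0.1).
#' @return The kept rows of `stats`, ordered by ascending p.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, seed = 3))
#' st <- scan_region(study$geno, study$omics$pe[, 1])
#' nrow(priority_prune(st, study$geno))
priority_prune <- function(stats, geno, r2_max = 0.1) {
  if (nrow(stats) == 0L) return(stats)
  stats <- stats |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data$beta)), .data$variant_id)
  D <- geno$dosages[, stats$variant_id, drop = FALSE]
  kept <- integer(0)
  for (idx in seq_len(nrow(stats))) {
    if (length(kept) == 0L) {
      kept <- idx
      next
    }
    r2 <- cor(D[, idx], D[, kept, drop = FALSE])^2
    if (all(r2 < r2_max)) kept <- c(kept, idx)
  }
  stats[kept, ]
}
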