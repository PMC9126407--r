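#' Wakefield log approximate Bayes factor
#'
#' Evidence for association of a single variant from its effect estimate and
#' standard error under a normal prior with variance `W` on the true effect:
#' with \eqn{z = \beta / se}, \eqn{V = se^2} and \eqn{r = W / (V + W)},
#' \deqn{\log ABF = \tfrac{1}{2}\log(1 - r) + \tfrac{1}{2} z^2 r.}
#' `W = 0` collapses the prior to a point mass at zero and gives log ABF = 0
#' for any z.
#'
#' @param beta,se Effect estimate and standard error (vectorised).
#' @param W Prior variance of the true effect (default `0.15^2`, the
#'   standard quantitative-trait choice).
#' @return Log approximate Bayes factors.
#' @export
#' @examples
#' log_abf(0.5, 0.1)
log_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) abort("`se` must be positive")
  if (any(W < 0)) abort("`W` must be non-negative")
  z2 <- (beta / se)^2
  r <- W / (se^2 + W)
  0.5 * log1p(-r) + 0.5 * z2 * r
}

#' Priors for Bayesian co-localization
#'
#' Per-variant prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), and both traits (`p12`), plus the prior effect
#' variances used by [log_abf()] for each trait.
#'
#' @param p1,p2,p12 Per-variant priors; must satisfy `0 < p12 <= min(p1, p2)`
#'   and `p1 + p2 + p12 < 1`.
#' @param W1,W2 Prior effect variances for traits 1 and 2 (use `0.2^2`-style
#'   larger values for binary traits on the log-odds scale).
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         W1 = 0.15^2, W2 = 0.15^2) {
  if (p12 <= 0 || p12 > min(p1, p2)) abort("need 0 < p12 <= min(p1, p2)")
  if (p1 + p2 + p12 >= 1) abort("need p1 + p2 + p12 < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12, W1 = W1, W2 = W2),
            class = "coloc_priors")
}

# align two summary-stats tables on shared variants, flipping trait-2 betas
# whose effect/other alleles are swapped relative to trait 1; unresolvable
# allele pairs are dropped and counted
harmonize_stats <- function(stats1, stats2) {
  shared <- dplyr::inner_join(
    dplyr::select(stats1, "variant_id", ea1 = "effect_allele",
                  oa1 = dplyr::any_of("other_allele"),
                  beta1 = "beta", se1 = "se"),
    dplyr::select(stats2, "variant_id", ea2 = "effect_allele",
                  oa2 = dplyr::any_of("other_allele"),
                  beta2 = "beta", se2 = "se"),
    by = "variant_id")
  if (nrow(shared) == 0L) abort("no shared variants between the two traits")
  same <- shared$ea1 == shared$ea2
  flip <- if (!"oa1" %in% names(shared)) rep(FALSE, nrow(shared)) else {
    !same & shared$ea2 == shared$oa1 &
      (if (!"oa2" %in% names(shared)) TRUE else shared$oa2 == shared$ea1)
  }
  flip[is.na(flip)] <- FALSE
  keep <- same | flip
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d variant(s) with unresolvable alleles", n_dropped))
  }
  out <- shared[keep, ]
  out$beta2[flip[keep]] <- -out$beta2[flip[keep]]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Bayesian co-localization of two association signals
#'
#' Tests, from summary statistics alone, whether two traits' association
#' signals in one region are driven by the same causal variant. Five
#' hypotheses are weighed: H0 no association with either trait; H1/H2
#' association with one trait only; H3 two distinct causal variants; H4 one
#' shared causal variant. Per-variant Wakefield log-ABFs are combined over
#' single-causal-variant configurations in log space:
#' \deqn{H_1 \propto p_1 \sum_i ABF_{1i}, \quad
#'       H_2 \propto p_2 \sum_j ABF_{2j},}
#' \deqn{H_3 \propto p_1 p_2 \Big(\sum_i ABF_{1i} \sum_j ABF_{2j} -
#'       \sum_i ABF_{1i} ABF_{2i}\Big), \quad
#'       H_4 \propto p_{12} \sum_i ABF_{1i} ABF_{2i},}
#' normalised together with \eqn{H_0 \propto 1} to posterior probabilities.
#' The verdict is `"shared"` when PP4 >= `pp_threshold`, `"independent"`
#' when PP3 >= `pp_threshold`, else `"undecided"`. Effect directions play no
#' role: negating all betas of one trait leaves every posterior unchanged.
#'
#' @param stats1,stats2 Summary-statistics tibbles (`variant_id`,
#'   `effect_allele`, optionally `other_allele`, `beta`, `se`). Variants are
#'   aligned on the intersection of ids; swapped alleles are flipped,
#'   unresolvable ones dropped with a message.
#' @param priors A [coloc_priors()].
#' @param pp_threshold Posterior-probability decision threshold
#'   (default 0.75).
#' @return A `coloc_result`: posterior probabilities `pp0`..`pp4`,
#'   `n_variants`, `n_dropped`, `verdict`, and the per-variant log-ABF table.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_samples = 1000, seed = 4))
#' cv <- study$omics$covariates
#' s1 <- scan_region(study$geno, study$omics$pe[, 1], cv)
#' s2 <- scan_region(study$geno, study$omics$ge[[1]][, 1], cv)
#' colocalize(s1, s2)
colocalize <- function(stats1, stats2, priors = coloc_priors(),
                       pp_threshold = 0.75) {
  stopifnot(inherits(priors, "coloc_priors"))
  h <- harmonize_stats(stats1, stats2)
  l1 <- log_abf(h$beta1, h$se1, priors$W1)
  l2 <- log_abf(h$beta2, h$se2, priors$W2)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  lh <- c(h0 = 0,
          h1 = log(priors$p1) + lsum1,
          h2 = log(priors$p2) + lsum2,
          h3 = log(priors$p1) + log(priors$p2) +
            logdiffexp(lsum1 + lsum2, lsum12),
          h4 = log(priors$p12) + lsum12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  names(pp) <- paste0("pp", 0:4)
  verdict <- if (pp[["pp4"]] >= pp_threshold) "shared"
  else if (pp[["pp3"]] >= pp_threshold) "independent"
  else "undecided"
  structure(list(pp = pp, n_variants = nrow(h),
                 n_dropped = attr(h, "n_dropped"),
                 verdict = verdict, priors = priors,
                 pp_threshold = pp_threshold,
                 per_variant = tibble::tibble(
                   variant_id = h$variant_id, labf1 = l1, labf2 = l2)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variants; verdict: %s\n",
              x$n_variants, x$verdict))
  print(round(x$pp, 4))
  invisible(x)
}
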