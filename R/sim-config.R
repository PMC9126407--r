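#' Configure a synthetic multi-omics study
#'
#' Defines the ground-truth causal architecture of a simulated study linking
#' genotypes, tissue gene expression (GE), blood protein expression (PE) and a
#' binary disease outcome. Each genomic region carries one gene/protein pair
#' and one of three architectures:
#'
#' * `"shared"` — GE and PE are driven by the same causal variant,
#' * `"independent"` — GE and PE have distinct causal variants in low LD,
#' * `"null"` — no causal effect on either molecular layer.
#'
#' The `sign_pattern` controls whether the protein effect has the same
#' (`"concordant"`) or the opposite (`"discordant"`) direction as the
#' expression effect, emulating loci where transcript and protein move in
#' opposite directions. `sex_interaction` multiplies the male cis effect
#' relative to the female one, so values away from 1 create sex-specific QTLs.
#'
#' The disease model is logistic:
#' \eqn{\mathrm{logit}\, P(Y=1) = \alpha + \theta_{PE} PE + \theta_{dir} GE},
#' with the total expression effect `theta_total` split between the
#' protein-mediated path and the direct path by `mediation_fraction`
#' (`1` means complete mediation, i.e. \eqn{\theta_{dir} = 0}).
#'
#' @param n_samples Number of individuals.
#' @param n_variants_per_region Variants simulated per cis region (>= 2).
#' @param n_regions Number of independent cis regions (one gene/protein each).
#' @param n_tissues Number of tissues with a GE matrix; tissue 1 plays the
#'   role of whole blood.
#' @param maf_range Minor-allele-frequency range, inside (0.01, 0.5).
#' @param ld_decay First-order autoregressive correlation of adjacent latent
#'   haplotype Gaussians, in \[0, 1). 0 gives linkage equilibrium.
#' @param architecture Per-region architecture, recycled to `n_regions`;
#'   each element one of `"shared"`, `"independent"`, `"null"`.
#' @param sign_pattern Per-region direction pattern of the PE effect relative
#'   to GE, recycled; `"concordant"` or `"discordant"`.
#' @param h2_ge,h2_pe Target cis heritability of GE (per tissue) and PE, i.e.
#'   the fraction of unit trait variance explained by the causal variant.
#' @param ge_pe_coupling Linear effect of blood GE on PE (the causal
#'   GE -> PE path used by mediation simulations); 0 disables the path.
#' @param sex_interaction Per-region multiplier applied to male cis effects,
#'   recycled; 1 means no sexual dimorphism.
#' @param mediation_fraction Fraction of the total GE -> outcome effect routed
#'   through PE, in \[0, 1\].
#' @param theta_total Total GE -> outcome effect (log-odds per GE unit) in
#'   non-null regions.
#' @param prevalence Baseline outcome prevalence, in (0, 1).
#' @param age_range Uniform age range for the age covariate, years.
#' @param independent_r2_cap Maximum LD r-squared allowed between the GE and
#'   PE causal variants of an `"independent"` region.
#' @param seed Integer seed; identical configurations reproduce identical
#'   studies bit for bit.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_study()], [simulate_genotypes()]
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 500, n_regions = 2, seed = 1)
#' study <- simulate_study(cfg)
#' str(study$truth)
sim_config <- function(n_samples = 2000,
                       n_variants_per_region = 30,
                       n_regions = 1,
                       n_tissues = 2,
                       maf_range = c(0.05, 0.45),
                       ld_decay = 0.9,
                       architecture = "shared",
                       sign_pattern = "concordant",
                       h2_ge = 0.1,
                       h2_pe = 0.1,
                       ge_pe_coupling = 0,
                       sex_interaction = 1,
                       mediation_fraction = 1,
                       theta_total = 0.3,
                       prevalence = 0.3,
                       age_range = c(40, 80),
                       independent_r2_cap = 0.05,
                       seed = 1L) {
  if (n_variants_per_region < 2) abort("`n_variants_per_region` must be >= 2")
  if (length(maf_range) != 2L || maf_range[1] >= maf_range[2] ||
      maf_range[1] <= 0.01 || maf_range[2] >= 0.5) {
    abort("`maf_range` must be an increasing pair inside (0.01, 0.5)")
  }
  if (!is.numeric(ld_decay) || ld_decay < 0 || ld_decay >= 1) {
    abort("`ld_decay` must lie in [0, 1)")
  }
  architecture <- rep_len(match.arg(architecture,
                                    c("shared", "independent", "null"),
                                    several.ok = TRUE), n_regions)
  sign_pattern <- rep_len(match.arg(sign_pattern,
                                    c("concordant", "discordant"),
                                    several.ok = TRUE), n_regions)
  sex_interaction <- rep_len(sex_interaction, n_regions)
  if (h2_ge < 0 || h2_ge >= 1 || h2_pe < 0 || h2_pe >= 1) {
    abort("heritabilities must lie in [0, 1)")
  }
  assert_scalar_prob(mediation_fraction, "mediation_fraction",
                     open_left = FALSE, open_right = FALSE)
  assert_scalar_prob(prevalence, "prevalence", open_right = TRUE)
  if (mediation_fraction < 1 - 1e-12 && mediation_fraction > 0 &&
      theta_total != 0 && ge_pe_coupling == 0) {
    abort("partial mediation with `theta_total` != 0 requires a nonzero `ge_pe_coupling`")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants_per_region = as.integer(n_variants_per_region),
         n_regions = as.integer(n_regions),
         n_tissues = as.integer(n_tissues),
         maf_range = maf_range,
         ld_decay = ld_decay,
         architecture = architecture,
         sign_pattern = sign_pattern,
         h2_ge = h2_ge, h2_pe = h2_pe,
         ge_pe_coupling = ge_pe_coupling,
         sex_interaction = sex_interaction,
         mediation_fraction = mediation_fraction,
         theta_total = theta_total,
         prevalence = prevalence,
         age_range = age_range,
         independent_r2_cap = independent_r2_cap,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d samples, %d region(s) x %d variants, %d tissue(s)\n",
              x$n_samples, x$n_regions, x$n_variants_per_region, x$n_tissues))
  cat(sprintf("  architectures: %s\n",
              paste(unique(x$architecture), collapse = ", ")))
  cat(sprintf("  h2_ge = %g, h2_pe = %g, ld_decay = %g, seed = %d\n",
              x$h2_ge, x$h2_pe, x$ld_decay, x$seed))
  invisible(x)
}
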