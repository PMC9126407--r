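#' Draw the ground-truth causal architecture of a simulated study
#'
#' For each region, picks the causal variant(s) and translates the configured
#' cis heritabilities into per-allele effect sizes given the realised allele
#' frequencies: a causal variant with dosage variance \eqn{\sigma_g^2} and
#' target heritability \eqn{h^2} on a unit-variance trait gets
#' \eqn{\beta = \sqrt{h^2 / \sigma_g^2}}. In `"independent"` regions the PE
#' causal variant is drawn among variants whose empirical LD r-squared with
#' the GE causal variant is below `independent_r2_cap`; in `"shared"` regions
#' the two coincide; `"null"` regions carry zero effects. Discordant regions
#' flip the sign of the PE effect relative to GE.
#'
#' @param geno A [genotype_matrix()] from [simulate_genotypes()].
#' @param config The [sim_config()] used to generate `geno`.
#' @return A tibble with one row per region: causal indices (within-region),
#'   causal variant ids, female-baseline effect sizes per layer, the male
#'   multiplier, and the outcome-model coefficients `theta_pe`/`theta_direct`.
#' @export
simulate_truth <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants_per_region
  f <- config$mediation_fraction
  purrr::map_dfr(seq_len(config$n_regions), function(r) {
    arch <- config$architecture[r]
    region <- sprintf("R%02d", r)
    vmeta <- geno$variants[geno$variants$region == region, ]
    D <- geno$dosages[, vmeta$variant_id, drop = FALSE]
    if (arch == "null") {
      return(tibble::tibble(
        region = region, gene_id = sprintf("G%02d", r), architecture = arch,
        sign_pattern = config$sign_pattern[r],
        causal_ge = NA_integer_, causal_pe = NA_integer_,
        causal_ge_id = NA_character_, causal_pe_id = NA_character_,
        beta_ge = 0, beta_pe = 0,
        sex_multiplier = config$sex_interaction[r],
        theta_pe = 0, theta_direct = 0))
    }
    # central variant keeps the cis signal away from region edges
    idx_ge <- as.integer(ceiling(m / 2))
    if (arch == "shared") {
      idx_pe <- idx_ge
    } else {
      r2 <- suppressWarnings(cor(D[, idx_ge], D)^2)
      ok <- which(r2 < config$independent_r2_cap & seq_len(m) != idx_ge)
      if (!length(ok)) {
        abort(sprintf(
          "region %s: no variant with r2 < %g against the GE causal variant; lower ld_decay or raise the cap",
          region, config$independent_r2_cap))
      }
      idx_pe <- ok[sample.int(length(ok), 1L)]
    }
    var_ge <- var(D[, idx_ge])
    var_pe <- var(D[, idx_pe])
    beta_ge <- sqrt(config$h2_ge / var_ge)
    beta_pe <- sqrt(config$h2_pe / var_pe) *
      if (config$sign_pattern[r] == "discordant") -1 else 1
    delta <- config$ge_pe_coupling
    theta_pe <- if (f > 0) {
      if (delta == 0) 0 else f * config$theta_total / delta
    } else 0
    tibble::tibble(
      region = region, gene_id = sprintf("G%02d", r), architecture = arch,
      sign_pattern = config$sign_pattern[r],
      causal_ge = idx_ge, causal_pe = idx_pe,
      causal_ge_id = vmeta$variant_id[idx_ge],
      causal_pe_id = vmeta$variant_id[idx_pe],
      beta_ge = beta_ge, beta_pe = beta_pe,
      sex_multiplier = config$sex_interaction[r],
      theta_pe = theta_pe,
      theta_direct = (1 - f) * config$theta_total)
  })
}

#' Simulate tissue expression, protein levels and covariates
#'
#' Generates, per tissue, one gene-expression trait per region, and one blood
#' protein trait per region, from the causal architecture in `truth`:
#' \deqn{GE_t = \beta\, G_{ge} + c_{age} age^* + c_{sex} sex + \epsilon}
#' \deqn{PE = \gamma\, G_{pe} + \delta\, GE_{blood} + c_{age} age^* +
#'   c_{sex} sex + \epsilon}
#' where \eqn{age^*} is age centred and scaled to SD 1, male cis effects are
#' multiplied by the region's `sex_multiplier`, discordant regions carry
#' \eqn{\gamma} of opposite sign to \eqn{\beta}, and the noise SD is set so
#' the causal variant explains the configured heritability of a unit-variance
#' trait. Tissue 1 is the blood-like compartment feeding the GE -> PE path.
#'
#' @param geno A [genotype_matrix()].
#' @param truth Output of [simulate_truth()].
#' @param config The matching [sim_config()].
#' @return List with `ge` (list of `n_tissues` samples-by-genes matrices),
#'   `pe` (samples-by-proteins matrix), `covariates` (tibble of `age`, `sex`;
#'   sex coded 0 = female, 1 = male), and `sex` (the same 0/1 vector).
#' @export
simulate_omics <- function(geno, truth, config) {
  n <- nrow(geno$dosages)
  if (config$n_samples != n) abort("`geno` does not match `config`")
  sex <- rbinom(n, 1L, 0.5)
  age <- runif(n, config$age_range[1], config$age_range[2])
  age_std <- as.numeric(scale(age))
  c_age <- 0.05
  c_sex <- 0.2
  noise_sd_ge <- sqrt(max(1 - config$h2_ge, 1e-8))
  noise_sd_pe <- sqrt(max(1 - config$h2_pe, 1e-8))
  sexmul <- function(mult) ifelse(sex == 1L, mult, 1)
  ge <- replicate(config$n_tissues, {
    mat <- matrix(0, n, nrow(truth))
    colnames(mat) <- truth$gene_id
    mat
  }, simplify = FALSE)
  names(ge) <- sprintf("tissue%02d", seq_len(config$n_tissues))
  pe <- matrix(0, n, nrow(truth), dimnames = list(NULL, truth$gene_id))
  for (k in seq_len(nrow(truth))) {
    tr <- truth[k, ]
    g_ge <- if (is.na(tr$causal_ge_id)) 0 else geno$dosages[, tr$causal_ge_id]
    g_pe <- if (is.na(tr$causal_pe_id)) 0 else geno$dosages[, tr$causal_pe_id]
    for (t in seq_len(config$n_tissues)) {
      ge[[t]][, k] <- tr$beta_ge * sexmul(tr$sex_multiplier) * g_ge +
        c_age * age_std + c_sex * sex + noise_sd_ge * rnorm(n)
    }
    pe[, k] <- tr$beta_pe * sexmul(tr$sex_multiplier) * g_pe +
      config$ge_pe_coupling * ge[[1L]][, k] +
      c_age * age_std + c_sex * sex + noise_sd_pe * rnorm(n)
  }
  list(ge = ge, pe = pe,
       covariates = tibble::tibble(age = age, sex = sex),
       sex = sex)
}

#' Simulate a binary outcome mediated through protein levels
#'
#' Draws the outcome from the logistic model
#' \eqn{\mathrm{logit}\,P(Y=1) = \alpha + \sum_r (\theta_{PE,r} PE_r +
#' \theta_{dir,r} GE_{blood,r})}, with the intercept solved numerically so the
#' marginal prevalence matches `config$prevalence`. When
#' `mediation_fraction = 1` every `theta_direct` is zero and the genotype can
#' reach the outcome only through protein.
#'
#' @param pe Samples-by-proteins matrix from [simulate_omics()].
#' @param ge Blood-tissue samples-by-genes matrix (tissue 1).
#' @param truth Output of [simulate_truth()].
#' @param config The matching [sim_config()].
#' @return Integer 0/1 outcome vector.
#' @export
simulate_outcome <- function(pe, ge, truth, config) {
  assert_scalar_prob(config$prevalence, "prevalence", open_right = TRUE)
  lp <- drop(pe %*% truth$theta_pe + ge %*% truth$theta_direct)
  alpha <- uniroot(function(a) mean(plogis(a + lp)) - config$prevalence,
                   interval = c(-30, 30), tol = 1e-10)$root
  rbinom(length(lp), 1L, plogis(alpha + lp))
}

#' Split samples into disjoint exposure and outcome sets
#'
#' Emulates a two-sample Mendelian-randomization design: instrument-exposure
#' and instrument-outcome summary statistics are later computed on
#' non-overlapping halves of the cohort.
#'
#' @param n_samples Total available samples.
#' @param n_exposure,n_outcome Sizes of the two sets; their sum must not
#'   exceed `n_samples`.
#' @param seed Optional seed for a reproducible split.
#' @return List with integer index vectors `exposure` and `outcome`
#'   (disjoint by construction).
#' @export
#' @examples
#' s <- make_two_sample_split(2000, 1000, 1000, seed = 1)
#' length(intersect(s$exposure, s$outcome))
make_two_sample_split <- function(n_samples, n_exposure, n_outcome,
                                  seed = NULL) {
  if (n_exposure + n_outcome > n_samples) {
    abort(sprintf("split sizes %d + %d exceed n_samples = %d",
                  n_exposure, n_outcome, n_samples))
  }
  if (!is.null(seed)) set.seed(seed)
  picked <- sample.int(n_samples, n_exposure + n_outcome)
  list(exposure = sort(picked[seq_len(n_exposure)]),
       outcome = sort(picked[n_exposure + seq_len(n_outcome)]))
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulate_genotypes()], [simulate_truth()],
#' [simulate_omics()] and [simulate_outcome()] under the single seed in
#' `config`. Identical configurations reproduce identical studies.
#'
#' @param config A [sim_config()].
#' @return List with `geno`, `truth`, `omics` and `outcome`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  truth <- simulate_truth(geno, config)
  omics <- simulate_omics(geno, truth, config)
  outcome <- simulate_outcome(omics$pe, omics$ge[[1L]], truth, config)
  list(geno = geno, truth = truth, omics = omics, outcome = outcome)
}
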