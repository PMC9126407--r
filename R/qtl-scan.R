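#' Define a cis scan region around a gene
#'
#' The scan window runs from gene start minus `flank` to gene stop plus
#' `flank` (500 kb by default), floored at position 1. Coordinates are
#' 1-based inclusive.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome label.
#' @param gene_start,gene_stop Gene body coordinates (1-based, bp).
#' @param flank Flank size in bp on each side.
#' @return One-row tibble with `scan_start` and `scan_end`.
#' @export
#' @examples
#' cis_region("IL6R", "1", 154377669, 154441926)
cis_region <- function(gene_id, chromosome, gene_start, gene_stop,
                       flank = 5e5) {
  if (any(gene_stop < gene_start)) abort("gene_stop must be >= gene_start")
  tibble::tibble(
    gene_id = gene_id, chromosome = as.character(chromosome),
    gene_start = gene_start, gene_stop = gene_stop,
    scan_start = pmax(1, gene_start - flank),
    scan_end = gene_stop + flank)
}

#' Locus-wide additive association scan
#'
#' Fits, for every variant in the (optionally restricted) region, the
#' ordinary-least-squares model `trait ~ dosage + covariates` and reports the
#' per-allele effect, its standard error and the two-sided p-value from the t
#' reference for the dosage term. Computation residualises trait and dosages
#' on the covariate design once (Frisch-Waugh-Lovell), so the scan is a
#' single matrix product rather than per-variant `lm()` calls; estimates are
#' identical to the full fit.
#'
#' Monomorphic and rare variants (minor allele frequency below `min_maf`)
#' are dropped. Sex-stratified scans subset samples by `sex` and must not
#' include sex among the covariates (it would be constant, hence collinear).
#'
#' @param geno A [genotype_matrix()].
#' @param trait Numeric trait vector, one value per genotype row. Missing
#'   values are dropped listwise unless `impute_mean = TRUE`.
#' @param covariates Optional numeric data frame / matrix of covariates.
#' @param region Optional one-row region as from [cis_region()]; variants
#'   with positions outside `[scan_start, scan_end]` are excluded.
#' @param stratum `"combined"`, `"female"` or `"male"`.
#' @param sex 0/1 vector (0 = female, 1 = male); required for sex strata.
#' @param min_maf Minor-allele-frequency floor (default 0.01).
#' @param inverse_normal Apply a rank-based inverse-normal transform to the
#'   trait before fitting (off by default; protein units are kept as is).
#' @param impute_mean Replace missing trait values by the trait mean instead
#'   of dropping them.
#' @return Summary-statistics tibble: `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`, `stratum`, ordered by
#'   position.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_samples = 300, seed = 2))
#' scan_region(study$geno, study$omics$pe[, 1],
#'             covariates = study$omics$covariates)
scan_region <- function(geno, trait, covariates = NULL, region = NULL,
                        stratum = c("combined", "female", "male"),
                        sex = NULL, min_maf = 0.01,
                        inverse_normal = FALSE, impute_mean = FALSE) {
  stratum <- match.arg(stratum)
  D <- geno$dosages
  vmeta <- geno$variants
  n_all <- nrow(D)
  if (length(trait) != n_all) abort("`trait` must align with genotype rows")
  cm <- as_covariate_matrix(covariates, n_all)

  keep_samples <- rep(TRUE, n_all)
  if (stratum != "combined") {
    if (is.null(sex)) abort("sex-stratified scan needs a `sex` vector")
    keep_samples <- sex == (if (stratum == "male") 1L else 0L)
  }
  if (impute_mean) {
    trait[is.na(trait)] <- mean(trait, na.rm = TRUE)
  }
  keep_samples <- keep_samples & !is.na(trait) &
    (if (is.null(cm)) TRUE else complete.cases(cm))
  D <- D[keep_samples, , drop = FALSE]
  y <- trait[keep_samples]
  n <- length(y)
  if (n < 3L) abort("fewer than 3 usable samples")
  if (sd(y) == 0) abort("trait has zero variance")
  if (inverse_normal) {
    y <- qnorm((rank(y) - 0.5) / n)
  }

  if (!is.null(region)) {
    inside <- vmeta$position >= region$scan_start[1] &
      vmeta$position <= region$scan_end[1]
    vmeta <- vmeta[inside, ]
    D <- D[, inside, drop = FALSE]
  }
  eaf <- colMeans(D) / 2
  poly <- pmin(eaf, 1 - eaf) >= min_maf
  vmeta <- vmeta[poly, ]
  D <- D[, poly, drop = FALSE]
  eaf <- eaf[poly]
  if (ncol(D) == 0L) abort("no polymorphic variants left to scan")

  X <- cbind(`(Intercept)` = rep(1, n), if (!is.null(cm)) cm[keep_samples, , drop = FALSE])
  y_res <- resid_on(y, X)
  G_res <- resid_on(D, X)
  sgg <- colSums(G_res^2)
  beta <- colSums(G_res * y_res) / sgg
  df <- n - ncol(X) - 1L
  rss <- pmax(sum(y_res^2) - beta^2 * sgg, 0)
  se <- sqrt(rss / df / sgg)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)

  tibble::tibble(
    variant_id = vmeta$variant_id,
    region = vmeta$region,
    position = vmeta$position,
    effect_allele = vmeta$effect_allele,
    other_allele = vmeta$other_allele,
    eaf = unname(eaf),
    beta = unname(beta),
    se = unname(se),
    p = unname(pmax(p, .Machine$double.xmin)),
    n = n,
    stratum = stratum)
}

#' Logistic association of a binary outcome with selected variants
#'
#' Per-variant logistic regression `outcome ~ dosage + covariates`, reporting
#' the log-odds ratio per effect allele. Intended for the instrument variants
#' of the disease-outcome MR leg, where only a handful of variants are
#' needed, so each fit is an ordinary [stats::glm()].
#'
#' @param geno A [genotype_matrix()].
#' @param outcome 0/1 outcome vector aligned with genotype rows.
#' @param variant_ids Variants to test (default: all).
#' @param covariates Optional numeric covariate table.
#' @return Summary-statistics tibble (`beta` on the log-odds scale).
#' @export
binary_assoc <- function(geno, outcome, variant_ids = NULL,
                         covariates = NULL) {
  if (!all(outcome %in% c(0L, 1L))) abort("`outcome` must be 0/1")
  vmeta <- geno$variants
  if (!is.null(variant_ids)) {
    vmeta <- vmeta[match(variant_ids, vmeta$variant_id), ]
    if (anyNA(vmeta$variant_id)) abort("unknown variant id")
  }
  cm <- as_covariate_matrix(covariates, nrow(geno$dosages))
  purrr::map_dfr(seq_len(nrow(vmeta)), function(i) {
    g <- geno$dosages[, vmeta$variant_id[i]]
    dat <- data.frame(y = outcome, g = g)
    if (!is.null(cm)) dat <- cbind(dat, cm)
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
    cf <- summary(fit)$coefficients["g", ]
    tibble::tibble(variant_id = vmeta$variant_id[i],
                   region = vmeta$region[i],
                   effect_allele = vmeta$effect_allele[i],
                   other_allele = vmeta$other_allele[i],
                   eaf = mean(g) / 2,
                   beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                   p = cf[["Pr(>|z|)"]], n = length(outcome),
                   stratum = "combined")
  })
}

#' Lead variant of a scan
#'
#' Returns the variant with the smallest p-value; ties are broken first by
#' larger absolute effect, then lexicographically by variant id, so the lead
#' is deterministic.
#'
#' @param stats Summary-statistics tibble from [scan_region()].
#' @return One-row tibble.
#' @export
lead_variant <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0L) abort("empty summary statistics")
  stats |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data$beta)), .data$variant_id) |>
    dplyr::slice(1L)
}
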