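#' Genotype dosage container
#'
#' Bundles a samples-by-variants allele-dosage matrix (values in \[0, 2\],
#' counting copies of the effect allele) with a variant metadata table.
#'
#' @param dosages Numeric matrix, samples x variants, values in \[0, 2\].
#' @param variants Data frame with one row per dosage column and at least
#'   `variant_id`, `region`, `position`, `effect_allele`, `other_allele`,
#'   `maf`. Positions must be strictly increasing within each region.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  variants <- tibble::as_tibble(variants)
  if (ncol(dosages) != nrow(variants)) {
    abort("`variants` must have one row per dosage column")
  }
  if (anyNA(dosages) || min(dosages) < 0 || max(dosages) > 2) {
    abort("dosages must lie in [0, 2] with no missing values")
  }
  need <- c("variant_id", "region", "position", "effect_allele",
            "other_allele", "maf")
  miss <- setdiff(need, names(variants))
  if (length(miss)) abort(paste("variants table lacks:", paste(miss, collapse = ", ")))
  bad <- variants |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(ok = all(diff(.data$position) > 0), .groups = "drop")
  if (!all(bad$ok)) abort("positions must be strictly increasing within a region")
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants in %d region(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              dplyr::n_distinct(x$variants$region)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Extract dosage columns for one region
#' @param geno A [genotype_matrix()].
#' @param region Region label.
#' @return A `genotype_matrix` restricted to that region.
#' @export
subset_region <- function(geno, region) {
  keep <- which(geno$variants$region == region)
  if (!length(keep)) abort(sprintf("no variants in region '%s'", region))
  genotype_matrix(geno$dosages[, keep, drop = FALSE], geno$variants[keep, ])
}

#' Simulate LD-structured genotypes
#'
#' Draws two haplotypes per individual from a first-order autoregressive
#' latent-Gaussian model: adjacent variants' latent values have correlation
#' `ld_decay`, and an allele is the indicator that the latent value falls
#' below the MAF quantile. Summing the two haplotypes yields dosages in
#' \{0, 1, 2\} at Hardy-Weinberg proportions, with LD decaying geometrically
#' with variant distance. Regions are mutually unlinked. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix()]; column allele frequencies match the drawn
#'   MAFs up to binomial sampling noise.
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 200, seed = 7))
#' range(g$dosages)
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants_per_region
  rho <- config$ld_decay
  alleles <- c("A", "C", "G", "T")
  blocks <- vector("list", config$n_regions)
  meta <- vector("list", config$n_regions)
  for (r in seq_len(config$n_regions)) {
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    thr <- qnorm(mafs)
    haps <- matrix(0L, 2L * n, m)
    z <- rnorm(2L * n)
    haps[, 1] <- (z < thr[1])
    for (j in 2:m) {
      z <- rho * z + sqrt(1 - rho^2) * rnorm(2L * n)
      haps[, j] <- (z < thr[j])
    }
    blocks[[r]] <- haps[seq_len(n), , drop = FALSE] +
      haps[n + seq_len(n), , drop = FALSE]
    ea <- sample(alleles, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
    meta[[r]] <- tibble::tibble(
      variant_id = sprintf("r%02d_v%03d", r, seq_len(m)),
      region = sprintf("R%02d", r),
      position = 1000L + 1000L * seq_len(m),
      effect_allele = ea,
      other_allele = unname(oa),
      maf = mafs)
  }
  genotype_matrix(do.call(cbind, blocks), dplyr::bind_rows(meta))
}
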