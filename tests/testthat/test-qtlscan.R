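test_that("cis regions span gene +/- 500 kb and are floored at 1", {
  r <- cis_region("IL6R", "1", 154377669, 154441926)
  expect_equal(r$scan_start, 154377669 - 5e5)
  expect_equal(r$scan_end, 154441926 + 5e5)
  r2 <- cis_region("X", "2", 100, 200)
  expect_equal(r2$scan_start, 1)
  expect_error(cis_region("X", "2", 200, 100), "gene_stop")
})

test_that("an exactly linear trait yields beta = 2 with vanishing error", {
  st <- demo_study(seed = 1, n = 200)
  trait <- 2 * st$geno$dosages[, 5]
  stats <- scan_region(st$geno, trait)
  row <- stats[stats$variant_id == st$geno$variants$variant_id[5], ]
  expect_equal(row$beta, 2, tolerance = 1e-10)
  expect_lt(row$se, 1e-8)
  expect_lt(row$p, 1e-100)
})

test_that("scan matches the per-variant lm() oracle to 1e-8", {
  st <- demo_study(seed = 2, n = 150, n_variants_per_region = 8)
  y <- st$omics$pe[, 1]
  cv <- st$omics$covariates
  stats <- scan_region(st$geno, y, covariates = cv)
  oracle <- scan_lm_oracle(st$geno$dosages[, stats$variant_id], y,
                           as.data.frame(cv))
  expect_equal(stats$beta, unname(oracle[, "beta"]), tolerance = 1e-8)
  expect_equal(stats$se, unname(oracle[, "se"]), tolerance = 1e-8)
  expect_equal(stats$p, unname(oracle[, "p"]), tolerance = 1e-6)
})

test_that("p-values are internally consistent with beta/se under the t reference", {
  st <- demo_study(seed = 3, n = 300)
  stats <- scan_region(st$geno, st$omics$pe[, 1],
                       covariates = st$omics$covariates)
  df <- stats$n[1] - 3 - 1  # intercept + age + sex + dosage
  recomputed <- 2 * pt(-abs(stats$beta / stats$se), df)
  expect_equal(stats$p, recomputed, tolerance = 1e-6)
})

test_that("a permuted trait is null-calibrated and p-values are uniform", {
  cfg <- sim_config(n_samples = 600, n_regions = 4,
                    n_variants_per_region = 250, architecture = "null",
                    ld_decay = 0, seed = 13)
  st <- simulate_study(cfg)
  stats <- scan_region(st$geno, st$omics$pe[, 1])
  frac <- mean(stats$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(stats)) + 0.01)
  ks <- suppressWarnings(ks.test(stats$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a simulated strong pQTL is recovered within 2 SE (IL6R-scale effect)", {
  # per-allele effect 0.421 at EAF 0.380 as in the strongest protein locus
  set.seed(99)
  n <- 2000
  g <- rbinom(n, 2, 0.380)
  y <- 0.421 * g + rnorm(n, sd = 0.5)
  geno <- genotype_matrix(
    cbind(g, rbinom(n, 2, 0.2)),
    tibble::tibble(variant_id = c("v1", "v2"), region = "R01",
                   position = c(1000, 2000), effect_allele = c("T", "A"),
                   other_allele = c("C", "G"), maf = c(0.38, 0.2)))
  stats <- scan_region(geno, y)
  row <- stats[stats$variant_id == "v1", ]
  expect_lt(abs(row$beta - 0.421), 2 * row$se)
  expect_equal(row$eaf, 0.380, tolerance = 0.03)
})

test_that("monomorphic/rare variants are dropped and degenerate inputs error", {
  st <- demo_study(seed = 5, n = 300)
  D <- st$geno$dosages
  D[, 1] <- 0  # monomorphic
  geno <- genotype_matrix(D, st$geno$variants)
  stats <- scan_region(geno, st$omics$pe[, 1])
  expect_false(st$geno$variants$variant_id[1] %in% stats$variant_id)
  expect_error(scan_region(st$geno, rep(1, 300)), "zero variance")
  cv <- st$omics$covariates
  cv$dup <- cv$age  # collinear copy
  expect_error(scan_region(st$geno, st$omics$pe[, 1], covariates = cv),
               "dup")
})

test_that("sex-stratified scans use only the stratum's samples", {
  cfg <- sim_config(n_samples = 4000, sex_interaction = 3, h2_ge = 0.1,
                    seed = 15)
  st <- simulate_study(cfg)
  cid <- st$truth$causal_ge_id
  sf <- scan_region(st$geno, st$omics$ge[[1]][, 1], stratum = "female",
                    sex = st$omics$sex)
  sm <- scan_region(st$geno, st$omics$ge[[1]][, 1], stratum = "male",
                    sex = st$omics$sex)
  expect_equal(sf$n[1] + sm$n[1], 4000)
  bf <- sf$beta[sf$variant_id == cid]
  bm <- sm$beta[sm$variant_id == cid]
  expect_gt(bm / bf, 2)
  expect_error(scan_region(st$geno, st$omics$ge[[1]][, 1],
                           stratum = "male"), "sex")
})

test_that("region restriction excludes outside variants", {
  st <- demo_study(seed = 6, n = 200)
  reg <- tibble::tibble(scan_start = 3000, scan_end = 8000)
  stats <- scan_region(st$geno, st$omics$pe[, 1], region = reg)
  expect_true(all(stats$position >= 3000 & stats$position <= 8000))
})

test_that("missing trait values are dropped listwise or mean-imputed on request", {
  st <- demo_study(seed = 7, n = 400)
  y <- st$omics$pe[, 1]
  y[1:20] <- NA
  s_drop <- scan_region(st$geno, y)
  expect_equal(s_drop$n[1], 380)
  s_imp <- scan_region(st$geno, y, impute_mean = TRUE)
  expect_equal(s_imp$n[1], 400)
})

test_that("the inverse-normal switch standardises the trait", {
  st <- demo_study(seed = 8, n = 500)
  y <- exp(st$omics$pe[, 1])  # skewed units
  s <- scan_region(st$geno, y, inverse_normal = TRUE)
  expect_true(all(is.finite(s$beta)))
  # transformed scan on a monotone transform equals the scan on the original
  s0 <- scan_region(st$geno, st$omics$pe[, 1], inverse_normal = TRUE)
  expect_equal(s$beta, s0$beta, tolerance = 1e-12)
})

test_that("lead_variant applies the p, |beta|, id tie-break order", {
  base <- tibble::tibble(variant_id = c("a", "b", "c"),
                         beta = c(1, -2, 0.5), se = 1,
                         p = c(0.5, 1e-9, 0.01))
  expect_equal(lead_variant(base)$variant_id, "b")
  ties <- tibble::tibble(variant_id = c("a", "b"), beta = c(0.1, -0.4),
                         se = 1, p = c(0.02, 0.02))
  expect_equal(lead_variant(ties)$variant_id, "b")
  idtie <- tibble::tibble(variant_id = c("z", "a"), beta = c(0.4, -0.4),
                          se = 1, p = c(0.02, 0.02))
  expect_equal(lead_variant(idtie)$variant_id, "a")
  expect_equal(lead_variant(base[2, ])$variant_id, "b")
  expect_error(lead_variant(base[0, ]), "empty")
})

test_that("binary association recovers a log-odds effect", {
  set.seed(17)
  n <- 4000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * g))
  geno <- genotype_matrix(
    cbind(v1 = g),
    tibble::tibble(variant_id = "v1", region = "R01", position = 1000,
                   effect_allele = "A", other_allele = "C", maf = 0.3))
  st <- binary_assoc(geno, y)
  expect_lt(abs(st$beta - 0.4), 2 * st$se)
  expect_error(binary_assoc(geno, y + 5), "0/1")
})
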