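test_that("instrument selection applies the strict genome-wide threshold", {
  stats <- tibble::tibble(variant_id = c("a", "b"), beta = c(0.5, 0.1),
                          se = c(0.05, 0.05), p = c(1e-9, 0.2))
  expect_equal(select_instrument(stats)$variant_id, "a")
  weak <- dplyr::mutate(stats, p = c(1e-7, 0.2))
  expect_equal(nrow(select_instrument(weak)), 0)
  boundary <- dplyr::mutate(stats, p = c(5e-8, 0.2))
  expect_equal(nrow(select_instrument(boundary)), 0)  # strict <
  expect_error(select_instrument(stats[0, ]), "empty")
})

test_that("the ratio estimate and delta-method SE follow the closed forms", {
  r <- mr_ratio(2, 0, 1, 0.1)
  expect_equal(r$beta_iv, 0.5)
  expect_equal(r$se_iv, 0.05)
  r0 <- mr_ratio(2, 0.3, 0, 0.1)
  expect_equal(r0$beta_iv, 0)
  expect_equal(r0$se_iv, 0.1 / 2)
  r2 <- mr_ratio(0.5, 0.05, 0.2, 0.04)
  expect_equal(r2$se_iv,
               sqrt(0.04^2 / 0.5^2 + 0.2^2 * 0.05^2 / 0.5^4))
  expect_equal(r2$p, 2 * pnorm(-abs(r2$beta_iv / r2$se_iv)))
  expect_error(mr_ratio(0, 0.1, 0.2, 0.1), "nonzero")
})

test_that("rescaling the exposure rescales the causal estimate inversely", {
  r1 <- mr_ratio(0.5, 0.05, 0.2, 0.04)
  r2 <- mr_ratio(0.5 * 3, 0.05 * 3, 0.2, 0.04)
  expect_equal(r2$beta_iv, r1$beta_iv / 3, tolerance = 1e-12)
  expect_equal(r2$se_iv, r1$se_iv / 3, tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
})

test_that("the delta-method SE matches a large parametric bootstrap", {
  set.seed(51)
  bx <- 0.5; sx <- 0.05; by <- 0.2; sy <- 0.04
  est <- mr_ratio(bx, sx, by, sy)
  draws <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_lt(abs(est$se_iv - sd(draws)) / sd(draws), 0.05)
})

test_that("mr_battery applies Bonferroni arithmetic and resolves instruments", {
  instruments <- tibble::tibble(exposure_id = c("P1", "P2"),
                                variant_id = c("a", "b"),
                                beta_x = c(0.5, 0.4), se_x = c(0.05, 0.05))
  outcome <- tibble::tibble(variant_id = c("a", "b"),
                            beta = c(0.2, 0.001), se = c(0.04, 0.05))
  res <- mr_battery(instruments, outcome, correction = "bonferroni",
                    n_tests = 48)
  raw <- mr_ratio(0.5, 0.05, 0.2, 0.04)$p
  expect_equal(res$p_adj[1], min(1, raw * 48))
  # the worked arithmetic case: raw 0.002 with 48 tests is not significant
  expect_equal(min(1, 0.002 * 48), 0.096)
  expect_message(
    mr_battery(instruments,
               dplyr::filter(outcome, variant_id == "a"),
               correction = "bonferroni"),
    "dropping 1")
  expect_error(mr_battery(instruments, outcome, correction = "banana"))
})

test_that("hierarchical correction over one gene-tissue pair reduces to plain BH", {
  instruments <- tibble::tibble(gene_id = "g1", tissue = "t1",
                                variant_id = "a", beta_x = 0.5, se_x = 0.05)
  outcome <- tibble::tibble(variant_id = "a", beta = 0.3, se = 0.04)
  res <- mr_battery(instruments, outcome, correction = "hierarchical")
  expect_true(res$significant[1])
  expect_equal(res$p_within_adj[1], res$p[1])
})

test_that("two-sample MR recovers the simulated causal effect", {
  # continuous exposure -> continuous outcome leg: theta = the GE -> PE
  # coupling, protein has no independent cis effect
  theta <- 0.4
  ests <- purrr::map_dfr(1:60, function(i) {
    cfg <- sim_config(n_samples = 2000, n_variants_per_region = 5,
                      h2_ge = 0.15, h2_pe = 0, ge_pe_coupling = theta,
                      mediation_fraction = 0, theta_total = 0,
                      seed = 7000 + i)
    st <- simulate_study(cfg)
    split <- make_two_sample_split(2000, 1000, 1000)
    sub <- function(idx) genotype_matrix(st$geno$dosages[idx, , drop = FALSE],
                                         st$geno$variants)
    cv <- st$omics$covariates
    exp_stats <- scan_region(sub(split$exposure),
                             st$omics$ge[[1]][split$exposure, 1],
                             covariates = cv[split$exposure, ])
    inst <- select_instrument(exp_stats)
    out_stats <- scan_region(sub(split$outcome),
                             st$omics$pe[split$outcome, 1],
                             covariates = cv[split$outcome, ])
    hit <- out_stats[out_stats$variant_id == inst$variant_id, ]
    mr_ratio(inst$beta, inst$se, hit$beta, hit$se)
  })
  mc_se <- sd(ests$beta_iv) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests$beta_iv) - theta), 3 * mc_se + 0.01)
  covered <- abs(ests$beta_iv - theta) <= 1.96 * ests$se_iv
  expect_gt(mean(covered), 0.85)
})

test_that("mediation chains combine legs per the product delta method", {
  # worked IL6R-style example: negative GE->PE and negative PE->disease
  # legs make the mediated disease effect of expression positive
  ch <- mediation_chain(
    mr_ge_pe = list(beta_iv = -3.008, se_iv = 0.364),
    mr_pe_cad = list(beta_iv = -0.094, se_iv = 0.0125),
    mr_ge_cad = list(beta_iv = 0.29, se_iv = 0.06),
    gene_id = "IL6R", tissue = "whole_blood")
  expect_equal(ch$indirect, -3.008 * -0.094)
  expect_gt(ch$indirect, 0)
  expect_equal(ch$se_indirect,
               sqrt(3.008^2 * 0.0125^2 + 0.094^2 * 0.364^2))
  expect_equal(ch$verdict, "complete_mediation")

  # zero protein->disease leg: no mediated effect
  ch0 <- mediation_chain(list(beta_iv = -3, se_iv = 0.3),
                         list(beta_iv = 0, se_iv = 0.01),
                         list(beta_iv = 0.1, se_iv = 0.5))
  expect_equal(ch0$indirect, 0)
  expect_equal(ch0$se_indirect, 3 * 0.01)

  # a missing leg leaves the chain incomplete without a verdict
  chm <- mediation_chain(list(beta_iv = -3, se_iv = 0.3), NULL,
                         list(beta_iv = 0.1, se_iv = 0.5))
  expect_false(chm$complete)
  expect_true(is.na(chm$verdict))
})

test_that("no protein->disease effect keeps the indirect-effect test at its nominal level", {
  set.seed(52)
  rejections <- vapply(1:200, function(i) {
    b1 <- rnorm(1, 0.5, 0.05)  # strong GE->PE leg
    b2 <- rnorm(1, 0, 0.04)    # null PE->disease leg
    ind <- b1 * b2
    se <- sqrt(b1^2 * 0.04^2 + b2^2 * 0.05^2)
    2 * pnorm(-abs(ind / se)) < 0.05
  }, logical(1))
  expect_lt(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 200) + 0.02)
})
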