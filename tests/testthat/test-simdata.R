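test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(maf_range = c(0.3, 0.2)), "maf_range")
  expect_error(sim_config(maf_range = c(0.005, 0.3)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(n_variants_per_region = 1), "n_variants")
  expect_error(sim_config(prevalence = 1.2), "prevalence")
  expect_error(sim_config(mediation_fraction = 0.5, theta_total = 0.3,
                          ge_pe_coupling = 0), "coupling")
})

test_that("genotypes are valid dosages with conserved allele frequencies", {
  cfg <- sim_config(n_samples = 5000, n_variants_per_region = 20,
                    n_regions = 2, seed = 9)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages >= 0 & g$dosages <= 2))
  # empirical allele frequency within 3 binomial SDs of the declared MAF
  emp <- colMeans(g$dosages) / 2
  tol <- 3 * sqrt(g$variants$maf * (1 - g$variants$maf) / (2 * cfg$n_samples))
  expect_true(all(abs(emp - g$variants$maf) < tol))
  # positions strictly increasing within regions
  expect_true(all(tapply(g$variants$position, g$variants$region,
                         function(p) all(diff(p) > 0))))
})

test_that("identical seeds give bit-identical studies", {
  cfg <- sim_config(n_samples = 300, n_regions = 2, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$geno$dosages, s2$geno$dosages)
  expect_identical(s1$omics$pe, s2$omics$pe)
  expect_identical(s1$outcome, s2$outcome)
})

test_that("ld_decay = 0 gives unlinked variants and AR(1) LD matches the latent oracle", {
  g0 <- simulate_genotypes(sim_config(n_samples = 5000, ld_decay = 0,
                                      n_variants_per_region = 10, seed = 3))
  cors <- cor(g0$dosages)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)

  cfg <- sim_config(n_samples = 5000, ld_decay = 0.9,
                    n_variants_per_region = 12, seed = 4)
  g <- simulate_genotypes(cfg)
  adj <- vapply(1:11, function(j) cor(g$dosages[, j], g$dosages[, j + 1])^2,
                numeric(1))
  set.seed(11)
  oracle <- vapply(1:11, function(j) {
    ld_oracle_adjacent_r2(g$variants$maf[j], g$variants$maf[j + 1], 0.9)
  }, numeric(1))
  expect_lt(abs(mean(adj) - mean(oracle)), 0.02)
})

test_that("null regions carry no effects and shared/independent architectures are honoured", {
  cfg <- sim_config(n_samples = 2000, n_regions = 3,
                    architecture = c("shared", "independent", "null"),
                    independent_r2_cap = 0.05, seed = 21)
  st <- simulate_study(cfg)
  tr <- st$truth
  expect_identical(tr$causal_ge[1], tr$causal_pe[1])
  expect_false(tr$causal_ge[2] == tr$causal_pe[2])
  r2 <- ld_r2(st$geno, tr$causal_ge_id[2], tr$causal_pe_id[2])
  expect_lt(r2, 0.05)
  expect_true(all(tr$beta_ge[3] == 0, tr$beta_pe[3] == 0,
                  tr$theta_pe[3] == 0))
})

test_that("causal variant explains the target heritability (closed-form check)", {
  cfg <- sim_config(n_samples = 2000, h2_ge = 0.1, h2_pe = 0.1, seed = 31)
  st <- simulate_study(cfg)
  g <- st$geno$dosages[, st$truth$causal_ge_id]
  # h2 = beta^2 var(g) / var(trait)
  h2_hat <- st$truth$beta_ge^2 * var(g) / var(st$omics$ge[[1]][, 1])
  expect_lt(abs(h2_hat - 0.1), 0.02)
})

test_that("discordant regions flip the protein effect sign", {
  cfg <- sim_config(n_samples = 2000, sign_pattern = "discordant",
                    h2_ge = 0.2, h2_pe = 0.2, seed = 41)
  st <- simulate_study(cfg)
  g <- st$geno$dosages[, st$truth$causal_ge_id]
  expect_gt(cor(g, st$omics$ge[[1]][, 1]), 0)
  expect_lt(cor(g, st$omics$pe[, 1]), 0)
})

test_that("sex interaction scales male effects", {
  cfg <- sim_config(n_samples = 6000, sex_interaction = 2, h2_ge = 0.1,
                    seed = 51)
  st <- simulate_study(cfg)
  g <- st$geno$dosages[, st$truth$causal_ge_id]
  ge <- st$omics$ge[[1]][, 1]
  sex <- st$omics$sex
  b_f <- coef(lm(ge[sex == 0] ~ g[sex == 0]))[2]
  b_m <- coef(lm(ge[sex == 1] ~ g[sex == 1]))[2]
  expect_gt(b_m / b_f, 1.5)
})

test_that("outcome model hits the target prevalence and logistic refit recovers theta_pe", {
  cfg <- sim_config(n_samples = 20000, mediation_fraction = 1,
                    ge_pe_coupling = 0.5, theta_total = 0.25,
                    prevalence = 0.3, seed = 61)
  st <- simulate_study(cfg)
  expect_lt(abs(mean(st$outcome) - 0.3), 0.02)
  theta_pe <- st$truth$theta_pe   # 0.25 / 0.5
  fit <- glm(st$outcome ~ st$omics$pe[, 1] + st$omics$ge[[1]][, 1],
             family = binomial())
  expect_lt(abs(coef(fit)[2] - theta_pe), 0.05)
  # complete mediation: no direct expression path
  expect_identical(st$truth$theta_direct, 0)
})

test_that("two-sample splits are disjoint, seeded and size-checked", {
  s <- make_two_sample_split(2000, 1000, 1000, seed = 5)
  expect_length(intersect(s$exposure, s$outcome), 0)
  expect_length(s$exposure, 1000)
  s2 <- make_two_sample_split(2000, 1000, 1000, seed = 5)
  expect_identical(s, s2)
  expect_error(make_two_sample_split(100, 60, 60), "exceed")
})

test_that("best-associated variants coincide under shared and differ under independent architecture", {
  hits <- vapply(1:20, function(i) {
    cfg <- sim_config(n_samples = 1500, n_variants_per_region = 15,
                      architecture = if (i <= 10) "shared" else "independent",
                      h2_ge = 0.2, h2_pe = 0.2, ld_decay = 0.5,
                      independent_r2_cap = 0.05, seed = 600 + i)
    st <- simulate_study(cfg)
    ge_lead <- which.max(abs(cor(st$geno$dosages, st$omics$ge[[1]][, 1])))
    pe_lead <- which.max(abs(cor(st$geno$dosages, st$omics$pe[, 1])))
    ge_lead == pe_lead
  }, logical(1))
  expect_gte(mean(hits[1:10]), 0.9)
  expect_lte(mean(hits[11:20]), 0.1)
})
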