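# Independent reference implementations used to cross-check the package.
# Each is deliberately naive (quadratic loops, enumeration, quadrature,
# Monte-Carlo) and shares no code with the implementation it checks.

# quadratic-time Benjamini-Hochberg step-up: adj_i = min over j with
# p_j >= p_i (by rank) of m * p_j / rank_j, capped at 1
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Monte-Carlo oracle for the AR(1) latent-Gaussian haplotype model: expected
# genotype correlation of adjacent variants at given MAFs and decay rho
ld_oracle_adjacent_r2 <- function(maf1, maf2, rho, n_haps = 1e5) {
  z1 <- rnorm(n_haps)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_haps)
  h1 <- as.numeric(z1 < qnorm(maf1))
  h2 <- as.numeric(z2 < qnorm(maf2))
  # dosage correlation equals haplotype allele correlation for independent
  # haplotype pairs; use dosages directly for the full pathway
  half <- n_haps %/% 2
  d1 <- h1[seq_len(half)] + h1[half + seq_len(half)]
  d2 <- h2[seq_len(half)] + h2[half + seq_len(half)]
  cor(d1, d2)^2
}

# numeric-quadrature oracle for the Wakefield ABF: marginal likelihood of
# beta_hat under beta ~ N(0, W) divided by the likelihood under beta = 0
abf_quadrature_oracle <- function(beta, se, W) {
  marg <- stats::integrate(function(b) {
    stats::dnorm(beta, mean = b, sd = se) * stats::dnorm(b, sd = sqrt(W))
  }, lower = -Inf, upper = Inf, rel.tol = 1e-12)$value
  log(marg / stats::dnorm(beta, mean = 0, sd = se))
}

# exhaustive configuration-enumeration oracle for colocalization posteriors:
# sums plain (non-log) ABF products over all single-causal-variant
# configurations of each hypothesis
coloc_enumeration_oracle <- function(labf1, labf2, p1, p2, p12) {
  a1 <- exp(labf1)
  a2 <- exp(labf2)
  m <- length(a1)
  h0 <- 1
  h1 <- p1 * sum(a1)
  h2 <- p2 * sum(a2)
  h3 <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) h3 <- h3 + a1[i] * a2[j]
    }
  }
  h3 <- p1 * p2 * h3
  h4 <- p12 * sum(a1 * a2)
  u <- c(h0, h1, h2, h3, h4)
  stats::setNames(u / sum(u), paste0("pp", 0:4))
}

# brute-force greedy pruning oracle operating on an explicit r2 matrix
prune_oracle <- function(p, r2mat, r2_max) {
  ord <- order(p)
  kept <- integer(0)
  for (i in ord) {
    if (all(r2mat[i, kept] < r2_max)) kept <- c(kept, i)
  }
  sort(kept)
}

# precision-matrix oracle for the partial correlation of x and y given Z:
# -omega_xy / sqrt(omega_xx * omega_yy) from the inverse correlation matrix
pcor_precision_oracle <- function(x, y, Z) {
  R <- stats::cor(cbind(x, y, Z))
  Om <- solve(R)
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# per-variant OLS via lm(), the slow reference for scan_region
scan_lm_oracle <- function(D, y, covars = NULL) {
  t(vapply(seq_len(ncol(D)), function(j) {
    dat <- data.frame(y = y, g = D[, j])
    if (!is.null(covars)) dat <- cbind(dat, covars)
    fit <- stats::lm(y ~ ., data = dat)
    cf <- summary(fit)$coefficients["g", ]
    c(beta = cf[["Estimate"]], se = cf[["Std. Error"]],
      p = cf[["Pr(>|t|)"]])
  }, numeric(3)))
}

# small standard study used across tests
demo_study <- function(seed = 101, n = 800, ...) {
  simulate_study(sim_config(n_samples = n, seed = seed, ...))
}
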