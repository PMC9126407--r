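---
title: "Multi-omics causal chains: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics causal chains: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

omicschain links four layers of data — genetic variants, tissue gene
expression (GE), blood protein expression (PE) and a binary disease
outcome — through a chain of summary-statistics methods: cis-QTL scans,
hierarchical FDR, Bayesian co-localization, predicted-expression
association, two-sample Mendelian randomization (MR) and mediation
analysis. This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where reasonable alternatives
existed. Everything shown is computed by the package; the test suite
asserts the quantitative claims.

```{r setup}
library(omicschain)
```

## The cis-QTL scan

For a molecular trait $y$ (protein or expression level) and variant $l$
with allele dosage $g_l \in [0,2]$, the scan fits the additive model

$$y_i = \mu + \beta_l g_{il} + \boldsymbol\gamma^\top \mathbf{c}_i + \varepsilon_i$$

by ordinary least squares for every variant in the cis window (gene start
−500 kb to gene stop +500 kb, 1-based inclusive coordinates, floored at
position 1). `scan_region()` residualises the trait and all dosage columns
on the covariate design once and obtains every $\hat\beta_l$, its standard
error and the two-sided t-test p-value from a single matrix product; the
estimates are identical to per-variant `lm()` fits (asserted to $10^{-8}$
in the tests). Variants with minor allele frequency below `min_maf`
(default 0.01) are dropped. Sex-stratified scans subset the samples and
must not carry sex as a covariate. Protein units are kept as measured
(they are semi-quantitative log-scale units); an optional rank-based
inverse-normal transform (`inverse_normal = TRUE`) is available but off by
default, and missing trait values are dropped listwise unless
`impute_mean = TRUE`.

The lead variant is the smallest-p variant, with deterministic
tie-breaking: larger $|\hat\beta|$, then lexicographic variant id.

## Hierarchical FDR and LD pruning

Testing many variants in each of many gene regions is a two-level
multiplicity problem. `hierarchical_fdr()` implements the
Simes/Benjamini–Bogomolov selective-inference scheme:

1. within each region, Benjamini–Hochberg (BH) adjust the per-variant
   p-values; the region's Simes p-value is the minimum adjusted value;
2. BH-adjust the $m$ Simes p-values and select regions at level
   $\alpha_1 = 0.05$, giving $k$ selected regions;
3. declare variants significant within selected regions when their
   within-region BH-adjusted p-value is at most
   $\alpha_2 = \alpha_1 k / m$.

With one region the scheme reduces to plain BH at $\alpha_1$. The
region-level false discovery rate is controlled at $\alpha_1$; the test
suite measures it at roughly 0.04 over 500 simulated 92-region datasets
with 20% non-null regions. BH itself is `stats::p.adjust`; the hierarchy
is this package's code, and both are checked against a quadratic-time
step-up reference.

`priority_prune()` reduces significant variants to an approximately
independent subset: greedy in ascending p-value, keeping a variant only if
its dosage-correlation $r^2$ is below `r2_max` (default 0.1) against every
variant already kept. Pruning is applied per region by default; pooling
regions first gives the global variant (pass the pooled table). The output
invariant — all pairwise $r^2 < r^2_{max}$ — is asserted post hoc in the
tests.

## Bayesian co-localization

Whether a protein signal and an expression signal in the same region share
one causal variant is decided from summary statistics with per-variant
Wakefield approximate Bayes factors,

$$\log ABF_l = \tfrac12\log(1-r_l) + \tfrac12 z_l^2 r_l, \qquad
  r_l = \frac{W}{se_l^2 + W},$$

combined over the five standard hypotheses (H0 none, H1/H2 one trait only,
H3 two distinct causal variants, H4 one shared causal variant) in log
space with log-sum-exp, so posteriors never underflow to zero unless they
are analytically zero (H3 with a single variant). Effect directions cancel
in $z^2$: the decision is direction-blind by construction, and flipping
all betas of one trait leaves every posterior unchanged.

The priors default to the reference method's standard values
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and $W = 0.15^2$ for
quantitative traits; the source study never reports its priors, so the
defaults are exposed in `coloc_priors()` rather than hard-coded. Verdicts
use posterior probability $\ge 0.75$ for both "shared" (PP4) and
"independent" (PP3). The implementation is verified against an exhaustive
configuration-enumeration oracle to $10^{-9}$ on small regions, and a
numeric-quadrature oracle for the single-variant ABF.

## Predicted-expression association

`summary_twas()` is the summary-statistics analogue of regressing protein
level on genetically predicted expression
$gGE = \sum_l w_l g_l$:

$$z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} \frac{\beta_l}{se_l}, \qquad
  \sigma_g^2 = \mathbf{w}^\top \Gamma \mathbf{w},$$

with $\sigma_l^2$ and $\Gamma$ the dosage variances and covariance of an
LD reference panel. The reported effect is per unit of predicted
expression, $\sum_l w_l \sigma_l^2 \beta_l / \sigma_g^2$ (weight-model
training is out of scope; the generator supplies true models and
externally trained TSV weights can be imported). For a single-variant
model the statistic is exactly the variant's $\beta/se$; for multi-variant
models the identity with the individual-level regression is approximate,
with error growing like $z \cdot h^2/2$ because per-variant residual
variances differ from the gene-model residual variance. The equivalence
check therefore runs on the generator's true weight models (exact) plus a
modest-signal multi-variant sweep ($h^2 \le 0.03$), both within
$|\Delta z| < 0.1$ at $n = 2000$. Gene–tissue multiplicity uses the same
hierarchical scheme with genes as families and tissues as within-family
tests.

## Mendelian randomization and mediation

All MR is single-instrument: the lead cis variant, admitted only when its
association p-value is strictly below $5\times10^{-8}$ (exposures whose
best instrument misses the threshold are excluded, not rescued). The
causal estimate is the ratio $\hat\beta_{IV} = \beta_y/\beta_x$ with the
delta-method standard error from the first two Taylor terms,

$$se_{IV} = \sqrt{se_y^2/\beta_x^2 + \beta_y^2 se_x^2 / \beta_x^4},$$

checked against a $10^6$-draw parametric bootstrap (within 5%). Two-sample
designs are emulated by disjoint sample splits, so exposure and outcome
statistics never share individuals. Multiplicity is Bonferroni for the
protein→disease stage and hierarchical (tissues within genes) for the
expression→protein stage. Multi-instrument estimators (IVW, Egger) and
bidirectional MR are deliberately out of scope.

`mediation_chain()` combines three legs for one gene–tissue–protein
triple. The indirect effect is the product $\beta_1\beta_2$ with
$se_{ind} = \sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$; the difference
test compares total and indirect effects treating them as independent.
That independence is a conservative simplification — the two legs share
the outcome sample and, often, the instrument — and it biases the
difference test toward non-rejection, i.e. toward declaring complete
mediation only when the point estimates genuinely agree relative to their
(overstated) joint uncertainty. "Complete mediation" requires: total
significant, indirect significant, difference not significant. Because the
disease legs are logistic, both total and indirect estimates are on the
log-odds scale and are attenuated by the same non-collapsibility factor,
so the difference test remains centred under true complete mediation.

Two negative legs make a positive mediated effect: with the published
whole-blood legs $\beta_1 = -3.008$ (expression→protein) and
$\beta_2 = -0.094$ (protein→disease),

```{r}
chain <- mediation_chain(
  mr_ge_pe  = list(beta_iv = -3.008, se_iv = 0.364),
  mr_pe_cad = list(beta_iv = -0.094, se_iv = 0.0125),
  mr_ge_cad = list(beta_iv = 0.29, se_iv = 0.06))
chain$indirect
```

## Direction concordance and the evidence overlap

`direction_classify()` counts, among tissues where the eQTL is significant
(default $p \le 0.05$, configurable), those whose expression effect
opposes the protein effect. The "predominantly discordant" verdict
requires the discordant fraction to *strictly* exceed 0.75 ("more than
75%"), so 3 of 4 tissues is mixed, not discordant — the boundary is
deliberate and tested. `partial_correlation()` provides the
individual-level validation (Pearson correlation of covariate-residualised
vectors, t reference with $n-k-2$ df, checked against a precision-matrix
oracle), and `overlap_sets()` partitions the genes flagged by the three
strategies — negative predicted-expression association, negative MR
effect, discordant QTL directions — into the seven Venn cells, the central
cell being the genes with all three lines of evidence.

## The synthetic-data generator

`simulate_study()` makes every stage testable without access-restricted
cohort data. What it emulates, and how:

* **LD-structured genotypes.** Two haplotypes per individual from a
  first-order autoregressive latent-Gaussian process: adjacent variants'
  latent values correlate at `ld_decay` and an allele is the indicator of
  falling below the MAF quantile. This yields Hardy–Weinberg dosages whose
  LD decays geometrically with distance — the minimal structure under
  which pruning and co-localization behave realistically. MAFs are drawn
  uniformly inside `maf_range` (default 0.05–0.45).
* **Causal architectures.** Per region: `shared` (GE and PE driven by one
  central causal variant), `independent` (PE causal variant drawn among
  variants with $r^2 <$ `independent_r2_cap` against the GE one, default
  0.05), or `null`. `sign_pattern = "discordant"` flips the protein effect
  sign. Effect sizes derive from target cis heritabilities:
  $\beta = \sqrt{h^2/\mathrm{Var}(g)}$ on unit-variance traits, defaults
  $h^2_{GE} = h^2_{PE} = 0.1$ — strong but not extreme cis signals.
* **Covariates and sex effects.** Age uniform over 40–80 years and sex
  Bernoulli(1/2), with fixed small effects (0.05 SD per age SD, 0.2 per
  sex) on every trait; `sex_interaction` multiplies male cis effects.
  Only the covariate roles are reproduced, not any cohort's demographics.
* **Protein coupling and disease.** PE may depend on blood GE through the
  coupling `ge_pe_coupling` ($\delta$); real-data GE–PE residual
  correlation is unknown, so $\delta$ is a free parameter, not a
  calibrated one. The outcome is logistic with the total expression effect
  `theta_total` split by `mediation_fraction` between the protein-mediated
  path ($\theta_{PE} = f\,\theta_{total}/\delta$) and the direct path;
  the intercept is solved numerically to hit `prevalence` (default 0.3).
* **Two-sample designs** come from `make_two_sample_split()` — disjoint
  index sets of one simulated cohort, rather than two cohorts with
  different LD panels; LD-panel mismatch is out of scope.

What it does **not** emulate: realistic human LD maps and allele-frequency
spectra, imputation error, batch and plate effects, assay noise models,
population stratification, trans effects. Passing tests therefore show
that the statistical machinery is correct and calibrated under the stated
generative model, not that any particular real-data finding would
replicate.

## Numerical choices and degenerate inputs

* Log-sum-exp throughout the co-localization arithmetic; `logdiffexp`
  returns $-\infty$ (posterior exactly 0) when the H3 sum underflows
  analytically.
* Scan p-values are floored at the smallest positive double rather than
  printing 0.
* Rank-deficient covariate designs abort with the name of the collinear
  column; zero-variance traits and monomorphic variants abort or are
  dropped explicitly.
* All tie-breaks (lead variant, pruning order) are deterministic, so
  identical configurations reproduce identical reports bit for bit; every
  random draw in a study flows from the single `seed` in `sim_config()`.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to be
informative yet quick: 500 datasets of 92 regions × 200 variants for FDR
control; 500 replicates at $n = 4000$ (split 2000/2000) for MR recovery
and coverage; 200 shared plus 100 independent replicates at $n = 2000$,
30 variants, for co-localization; 100 genes at $n = 2000$ for the
summary/individual equivalence; 120 replicates at $n = 6000$ for
mediation; and ten 65-region studies (5 causal, 60 null) at $n = 1200$
for end-to-end recovery. These sizes are the package's own choices and are
stated here so they can be scaled up when more precision is wanted.

## Known limitations

Single-instrument MR inherits the usual caveats (no pleiotropy test, no
reverse-causation probe); the mediation difference test ignores the
dependence between total and indirect estimates; co-localization assumes
at most one causal variant per trait per region; and the generator's AR(1)
LD is far simpler than real haplotype structure. Each limitation marks the
boundary of what the package claims, not an approximation hidden inside a
result.
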