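#' Classify direction consistency of a pQTL against tissue eQTLs
#'
#' Counts, among tissues where the eQTL is significant (`p <= p_sig`), those
#' whose expression effect has the opposite sign to the protein effect.
#' The verdict is `"predominantly_discordant"` when the discordant fraction
#' strictly exceeds `threshold` (default 0.75, i.e. "more than 75% of
#' tissues"), `"concordant"` when no significant tissue is discordant, and
#' `"mixed"` otherwise — so a 3-of-4 split sits exactly on the boundary and
#' is mixed. Tissues with an exactly zero effect are excluded with a message.
#'
#' @param pqtl_beta Protein-level effect of the variant (scalar, nonzero).
#' @param eqtl Tibble of per-tissue expression effects: `tissue`, `beta`,
#'   `p`.
#' @param p_sig Per-tissue eQTL significance cut-off (default 0.05).
#' @param threshold Discordance fraction that must be strictly exceeded.
#' @return One-row tibble: `n_tissues_significant`, `n_discordant`,
#'   `fraction_discordant`, `verdict`.
#' @export
#' @examples
#' eq <- tibble::tibble(tissue = paste0("t", 1:18),
#'                      beta = c(rep(-1, 17), 1), p = rep(0.001, 18))
#' direction_classify(0.421, eq)
direction_classify <- function(pqtl_beta, eqtl, p_sig = 0.05,
                               threshold = 0.75) {
  if (length(pqtl_beta) != 1L || is.na(pqtl_beta) || pqtl_beta == 0) {
    abort("`pqtl_beta` must be a single nonzero effect")
  }
  zero <- eqtl$beta == 0
  if (any(zero)) {
    inform(sprintf("excluding %d tissue(s) with zero effect", sum(zero)))
    eqtl <- eqtl[!zero, ]
  }
  sig <- eqtl[eqtl$p <= p_sig, ]
  if (nrow(sig) == 0L) abort("no significant tissue to classify")
  disc <- sign(sig$beta) * sign(pqtl_beta) < 0
  frac <- mean(disc)
  verdict <- if (frac > threshold) "predominantly_discordant"
  else if (sum(disc) == 0L) "concordant"
  else "mixed"
  tibble::tibble(n_tissues_significant = nrow(sig),
                 n_discordant = sum(disc),
                 fraction_discordant = frac,
                 verdict = verdict)
}

#' Test for a sex difference between stratified effect estimates
#'
#' Compares female and male effect sizes with the two-sample statistic
#' \eqn{t = (\beta_f - \beta_m) / \sqrt{se_f^2 + se_m^2}} and a two-sided
#' p-value from the standard normal reference.
#'
#' @param beta_f,se_f Female-stratum effect and SE.
#' @param beta_m,se_m Male-stratum effect and SE.
#' @return Tibble with `t` and `p` (vectorised).
#' @export
#' @examples
#' sex_difference_test(0.4, 0.1, 0.1, 0.1)
sex_difference_test <- function(beta_f, se_f, beta_m, se_m) {
  if (any(se_f <= 0) || any(se_m <= 0)) abort("standard errors must be positive")
  t <- (beta_f - beta_m) / sqrt(se_f^2 + se_m^2)
  tibble::tibble(t = t, p = 2 * pnorm(-abs(t)))
}

#' Pearson partial correlation
#'
#' Correlation of `x` and `y` after removing linear covariate effects from
#' both: each is regressed on the covariates (plus intercept) and the
#' residuals are correlated. The p-value uses the t reference with
#' `n - k - 2` degrees of freedom, k the number of covariates. With no
#' covariates this is the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric data frame / matrix.
#' @return Tibble with `r`, `df`, `t`, `p`.
#' @export
#' @examples
#' partial_correlation(rnorm(50), rnorm(50))
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  cm <- as_covariate_matrix(covariates, n)
  k <- if (is.null(cm)) 0L else ncol(cm)
  ok <- !is.na(x) & !is.na(y) & (if (is.null(cm)) TRUE else complete.cases(cm))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < k + 3L) abort("need at least k + 3 complete observations")
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(cm)) cm[ok, , drop = FALSE])
  rx <- resid_on(x, X)
  ry <- resid_on(y, X)
  r <- cor(rx, ry)
  df <- n - k - 2L
  t <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, df = df, t = t, p = 2 * pt(-abs(t), df))
}

#' Three-way overlap of negative-link gene sets
#'
#' Partitions genes flagged by three analysis strategies — negative
#' predicted-expression association, negative MR effect, and predominantly
#' discordant QTL directions — into the seven exclusive cells of a three-set
#' Venn diagram. The central cell holds the genes supported by all three
#' lines of evidence.
#'
#' @param mx_negative,mr_negative,qtl_discordant Character vectors of gene
#'   ids.
#' @return An `overlap_report`: tibble with `cell`, `n` and a `genes`
#'   list-column; the central intersection is also in
#'   `attr(x, "center")`.
#' @export
#' @examples
#' overlap_sets(c("IL6R", "BLMH"), c("IL6R"), c("IL6R", "SFTPD"))
overlap_sets <- function(mx_negative, mr_negative, qtl_discordant) {
  a <- unique(as.character(mx_negative))
  b <- unique(as.character(mr_negative))
  c_ <- unique(as.character(qtl_discordant))
  cells <- list(
    mx_only = setdiff(a, union(b, c_)),
    mr_only = setdiff(b, union(a, c_)),
    qtl_only = setdiff(c_, union(a, b)),
    mx_mr = setdiff(intersect(a, b), c_),
    mx_qtl = setdiff(intersect(a, c_), b),
    mr_qtl = setdiff(intersect(b, c_), a),
    center = Reduce(intersect, list(a, b, c_)))
  out <- tibble::tibble(cell = names(cells),
                        n = unname(lengths(cells)),
                        genes = purrr::map(cells, sort))
  structure(out, center = sort(cells$center),
            class = c("overlap_report", class(out)))
}
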