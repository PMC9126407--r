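#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]), validated to the
#' (0, 1] domain: adjusted values are monotone in rank and capped at 1.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Simes p-value of a region
#'
#' The region-level test statistic of the hierarchical FDR scheme: the
#' minimum BH-adjusted p-value among the region's variants.
#'
#' @param p Raw per-variant p-values of one region, or a summary-statistics
#'   tibble with a `p` column.
#' @return A single probability.
#' @export
#' @examples
#' simes_p(c(0.01, 0.02, 0.03))
simes_p <- function(p) {
  if (is.data.frame(p)) p <- p$p
  if (length(p) == 0L) abort("empty region")
  min(bh_adjust(p))
}

#' Hierarchical two-level FDR across regions
#'
#' Implements the Simes + Benjamini-Bogomolov selective-inference scheme used
#' for region-wise QTL discovery:
#' 1. each region is summarised by its Simes p-value (minimum within-region
#'    BH-adjusted p);
#' 2. BH is applied across the `m` region Simes p-values and regions with
#'    adjusted value <= `alpha1` are selected (`k` of them);
#' 3. within each selected region, variants whose within-region BH-adjusted
#'    p-value is <= `alpha2 = alpha1 * k / m` are declared significant.
#'
#' With a single region the scheme degenerates to plain BH at `alpha1`.
#'
#' @param stats Long tibble of per-variant results with at least a p-value
#'   column and a region column.
#' @param alpha1 Family-level FDR target (default 0.05).
#' @param region_col,p_col Names of the region and p-value columns.
#' @return An `hfdr_result`: list with `regions` (tibble: region, `simes_p`,
#'   `region_q`, `selected`), `variants` (input rows plus `p_within_adj` and
#'   `significant`), and scalars `m`, `k`, `alpha1`, `alpha2`.
#' @export
#' @examples
#' stats <- tibble::tibble(region = rep(c("A", "B"), each = 3),
#'                         variant_id = paste0("v", 1:6),
#'                         p = c(1e-8, 0.2, 0.9, 0.4, 0.5, 0.6))
#' hierarchical_fdr(stats)
hierarchical_fdr <- function(stats, alpha1 = 0.05,
                             region_col = "region", p_col = "p") {
  stats <- tibble::as_tibble(stats)
  if (!region_col %in% names(stats) || !p_col %in% names(stats)) {
    abort(sprintf("`stats` needs columns '%s' and '%s'", region_col, p_col))
  }
  if (nrow(stats) == 0L) abort("no variants supplied")
  assert_scalar_prob(alpha1, "alpha1")

  stats <- stats |>
    dplyr::group_by(.data[[region_col]]) |>
    dplyr::mutate(p_within_adj = bh_adjust(.data[[p_col]])) |>
    dplyr::ungroup()
  regions <- stats |>
    dplyr::group_by(.data[[region_col]]) |>
    dplyr::summarise(simes_p = min(.data$p_within_adj), .groups = "drop")
  regions$region_q <- bh_adjust(regions$simes_p)
  regions$selected <- regions$region_q <= alpha1
  m <- nrow(regions)
  k <- sum(regions$selected)
  alpha2 <- alpha1 * k / m
  sel_regions <- regions[[region_col]][regions$selected]
  stats$significant <- stats[[region_col]] %in% sel_regions &
    stats$p_within_adj <= alpha2
  structure(list(regions = regions, variants = stats,
                 m = m, k = k, alpha1 = alpha1, alpha2 = alpha2,
                 region_col = region_col),
            class = "hfdr_result")
}

#' @export
print.hfdr_result <- function(x, ...) {
  cat(sprintf("<hfdr_result> %d / %d regions selected (alpha2 = %.4g); %d significant variants\n",
              x$k, x$m, x$alpha2, sum(x$variants$significant)))
  invisible(x)
}

#' Variants declared significant by a hierarchical FDR fit
#' @param x An `hfdr_result`.
#' @return Tibble of significant variant rows.
#' @export
significant_variants <- function(x) {
  stopifnot(inherits(x, "hfdr_result"))
  dplyr::filter(x$variants, .data$significant)
}
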