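#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_errorbar labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Posterior-probability bar chart of a co-localization result
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$hypothesis, y = .data$posterior)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = object$pp_threshold, linetype = 2) +
    labs(y = "posterior probability", x = NULL,
         title = paste("co-localization verdict:", object$verdict)) +
    theme_minimal()
}

#' Region-level view of a hierarchical FDR fit
#'
#' Plots each region's Simes p-value (log scale) with the selection
#' threshold.
#'
#' @param object An `hfdr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hfdr_result <- function(object, ...) {
  df <- object$regions
  df$region <- df[[object$region_col]]
  ggplot(df, aes(x = .data$region, y = .data$simes_p,
                 colour = .data$selected)) +
    geom_point() +
    scale_y_log10() +
    geom_hline(yintercept = object$alpha1, linetype = 2) +
    labs(y = "Simes p-value", x = NULL,
         title = sprintf("%d of %d regions selected (alpha2 = %.3g)",
                         object$k, object$m, object$alpha2)) +
    theme_minimal()
}

#' Effect decomposition plot of a mediation chain
#'
#' Shows the chain's path, indirect and total effects with approximate 95%
#' intervals.
#'
#' @param object A `causal_chain`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.causal_chain <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "difference", ]
  ggplot(df, aes(x = .data$term, y = .data$estimate)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$estimate - 1.96 * .data$std.error,
                      ymax = .data$estimate + 1.96 * .data$std.error),
                  width = 0.15) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = NULL, y = "effect (log-odds for outcome legs)",
         title = paste("mediation verdict:", object$verdict)) +
    theme_minimal()
}

#' Regional association plot of a summary-statistics scan
#'
#' -log10 p-values by position, highlighting the lead variant.
#'
#' @param stats Summary-statistics tibble from [scan_region()].
#' @return A ggplot.
#' @export
plot_region_scan <- function(stats) {
  lead <- lead_variant(stats)
  ggplot(stats, aes(x = .data$position, y = -log10(.data$p))) +
    geom_point(colour = "grey40") +
    geom_point(data = lead, colour = "red", size = 2.5) +
    labs(x = "position (bp)", y = expression(-log[10](p))) +
    theme_minimal()
}
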