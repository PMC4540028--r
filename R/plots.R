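#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_hline labs theme_minimal scale_x_log10 scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Standards as points with the fitted line, annotated with the linearity
#' statistic.
#'
#' @param object a `calibration_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot calibration_fit
#' @export
autoplot.calibration_fit <- function(object, ...) {
  df <- object$standards
  df$ratio <- df$analyte_response / df$is_response
  ggplot(df, aes(x = .data$amount_pg, y = .data$ratio)) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "grey40") +
    geom_point(colour = "#2c7fb8", size = 2) +
    labs(x = "amount on column (pg)", y = "response ratio (analyte / IS)",
         title = sprintf("%s calibration", object$metabolite),
         subtitle = sprintf("r = %.4f over %d levels (%g-%g pg)",
                            object$r, object$n_levels, object$range_low,
                            object$range_high)) +
    theme_minimal()
}

#' Plot a candidate screen
#'
#' Per-gene Pearson correlation against rank, coloured by candidate tier,
#' with the tier thresholds drawn.
#'
#' @param object a `candidate_screen` tibble.
#' @param r_min,r_strict thresholds to draw.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot candidate_screen
#' @export
autoplot.candidate_screen <- function(object, r_min = 0.8, r_strict = 0.9, ...) {
  df <- object[!object$undefined, ]
  df$rank <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$rank, y = .data$r, colour = .data$tier)) +
    geom_hline(yintercept = c(r_min, r_strict), linetype = "dashed",
               colour = "grey60") +
    geom_point(size = 1) +
    labs(x = "gene rank", y = "Pearson r vs metabolite",
         colour = "tier") +
    theme_minimal()
}

#' Bar chart of SSR canonical classes
#'
#' @param summary output of [summarize_ssrs()].
#' @param top number of classes to show.
#' @return a ggplot.
#' @export
plot_ssr_classes <- function(summary, top = 15) {
  df <- utils::head(summary$by_class, top)
  df$class <- factor(df$class, levels = rev(df$class))
  ggplot(df, aes(x = .data$n, y = .data$class)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = "loci", y = "canonical motif class") +
    theme_minimal()
}
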