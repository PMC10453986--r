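#' Delta-plot figure
#'
#' Group-mean delta plots (congruency effect against mean quantile) per
#' instruction, facetted by asynchrony, with a shaded band of +/- one
#' standard error of the mean across participants.
#'
#' @param dps Delta plots from [delta_plots()], or a `simon_analysis`
#'   bundle.
#' @return A ggplot object.
#' @export
plot_delta_plots <- function(dps) {
  if (inherits(dps, "simon_analysis")) dps <- dps$delta
  g <- dps |>
    dplyr::group_by(.data$instruction, .data$soa, .data$prob) |>
    dplyr::summarise(mx = mean(.data$x), my = mean(.data$y),
                     se = sd(.data$y) / sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(g, ggplot2::aes(x = .data$mx, y = .data$my,
                                  colour = .data$instruction,
                                  fill = .data$instruction)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$my - .data$se,
                                      ymax = .data$my + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~soa, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Mean quantile RT (ms)",
                  y = "Congruency effect (ms)",
                  colour = "Instruction", fill = "Instruction") +
    ggplot2::theme_minimal()
}

#' Binned error congruency-effect figure
#'
#' Group-mean congruency effect for error percentages in the six
#' reaction-time bins, per instruction, facetted by asynchrony.
#'
#' @param bins Output of [error_bin_ce()], or a `simon_analysis` bundle.
#' @return A ggplot object.
#' @export
plot_error_bins <- function(bins) {
  if (inherits(bins, "simon_analysis")) bins <- bins$error_bins
  g <- bins |>
    dplyr::group_by(.data$instruction, .data$soa, .data$bin) |>
    dplyr::summarise(ce = mean(.data$ce_error_pct, na.rm = TRUE),
                     se = sd(.data$ce_error_pct, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$ce_error_pct))),
                     .groups = "drop")
  ggplot2::ggplot(g, ggplot2::aes(x = factor(.data$bin), y = .data$ce,
                                  fill = .data$instruction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ce - .data$se,
                                        ymax = .data$ce + .data$se),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::facet_wrap(~soa, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Reaction-time bin",
                  y = "Error congruency effect (percentage points)",
                  fill = "Instruction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_delta_plots
#' @param object A `simon_analysis` bundle.
#' @param ... Unused.
#' @export
autoplot.simon_analysis <- function(object, ...) plot_delta_plots(object)
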