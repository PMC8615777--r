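#' Time-course panel of a morphological descriptor
#'
#' One panel per experiment in the style of the classical mono-/coculture
#' figures: mean descriptor value against sampling time, coloured by
#' vessel, solid points for fully evolved pellets and hollow points for
#' the hyphae/clumps fraction, with Student-t confidence bars.  Projected
#' area is drawn on a log10 axis.
#'
#' @param timecourse a `morph_timecourse` from [assemble_timecourse()].
#' @param parameter `"area"`, `"elongation"` or `"mo"`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse,
                            parameter = c("area", "elongation", "mo")) {
  parameter <- match.arg(parameter)
  ycol <- c(area = "mean_area_um2", elongation = "mean_elongation",
            mo = "mean_mo")[[parameter]]
  cicol <- sub("mean_", "ci_", ycol)
  ylab <- c(area = "projected area A (µm²)",
            elongation = "elongation E (-)",
            mo = "morphology number Mo (-)")[[parameter]]
  df <- dplyr::filter(timecourse, .data$present)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_h, y = .data[[ycol]],
    colour = .data$culture, group = interaction(.data$culture, .data$species,
                                                .data$fraction))) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[ycol]] - .data[[cicol]],
                                        ymax = .data[[ycol]] + .data[[cicol]]),
                           width = 3, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$fraction, fill = .data$culture),
                        size = 2) +
    ggplot2::scale_shape_manual(values = c(fully_evolved_pellet = 21,
                                           hyphae_or_clumps = 1)) +
    ggplot2::facet_wrap(~experiment) +
    ggplot2::labs(x = "time (h)", y = ylab, colour = "vessel",
                  fill = "vessel", shape = "fraction") +
    ggplot2::theme_minimal()
  if (parameter == "area") p <- p + ggplot2::scale_y_log10()
  p
}

#' @rdname plot_timecourse
#' @param object a `morph_timecourse`.
#' @param ... passed to [plot_timecourse()].
#' @method autoplot morph_timecourse
#' @export
autoplot.morph_timecourse <- function(object, ...) plot_timecourse(object, ...)

#' Evidence map of an outcome call
#'
#' Tiles the evaluation window per species: pellet presence in the
#' coculture and whether the projected-area comparison against the
#' monoculture was significantly smaller.
#'
#' @param object an `outcome_call`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot outcome_call
#' @export
autoplot.outcome_call <- function(object, ...) {
  ev <- object$evidence |>
    mutate(state = dplyr::case_when(
      .data$co_pellets == 0 ~ "pellets absent",
      .data$significantly_smaller ~ "pellets smaller (p<α)",
      TRUE ~ "pellets comparable"))
  ggplot2::ggplot(ev, ggplot2::aes(x = factor(.data$time_h), y = .data$species,
                                   fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(
      title = sprintf("%s: %s%s", object$experiment,
                      if (object$winner == "none") object$verdict
                      else sprintf("%s by species %s", object$verdict, object$winner),
                      if (object$conflict) " [conflict]" else ""),
      x = "time (h)", y = "species (as potential loser)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
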