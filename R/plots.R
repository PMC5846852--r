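#' Plot the force-displacement curves of a cohort
#'
#' @param object An `fsu_cohort`.
#' @param arm `"computational"` (noise-free) or `"experimental"` (noisy).
#' @param ... Unused.
#' @return A ggplot of all curves coloured by group.
#' @export
autoplot.fsu_cohort <- function(object,
                                arm = c("computational", "experimental"),
                                ...) {
  arm <- match.arg(arm)
  col <- if (arm == "computational") "curve" else "curve_noisy"
  df <- tidyr::unnest(
    tibble::tibble(id = object$id, group = object$group,
                   curve = purrr::map(object[[col]], tibble::as_tibble)),
    "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement_mm,
                                   y = .data$force_N,
                                   group = .data$id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "displacement (mm)", y = "force (N)",
                  colour = "group",
                  title = paste0("Axial compression curves (", arm, " arm)"))
}

#' Boxplots of tri-linear metrics by group
#'
#' @param fits A fit table from [fit_cohort()].
#' @param metrics Metric columns to show.
#' @return A faceted ggplot of per-group boxplots.
#' @export
plot_group_metrics <- function(fits, metrics = trilinear_metrics) {
  stopifnot(is.data.frame(fits), all(metrics %in% names(fits)))
  df <- tidyr::pivot_longer(fits, dplyr::all_of(metrics),
                            names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Tri-linear metrics by group")
}
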