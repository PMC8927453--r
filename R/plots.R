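#' Plot nominal stress-strain curves
#'
#' One line per specimen, colored by tissue when metadata are given.
#'
#' @param curves Raw records (`sample_id`, `displacement_mm`, `force_N`).
#' @param meta Per-specimen metadata (required to convert to stress-strain).
#' @return A ggplot object.
#' @export
plot_stress_strain <- function(curves, meta) {
  ss <- curves |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::mutate(
      strain = .data$displacement_mm / .data$L0_mm,
      stress = .data$force_N / .data$A0_mm2
    )
  ggplot2::ggplot(ss, ggplot2::aes(.data$strain, .data$stress,
                                   group = .data$sample_id,
                                   colour = .data$tissue)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rate_mm_s), labeller = "label_both") +
    ggplot2::labs(x = "nominal strain", y = "nominal stress (MPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of the five mechanical properties by tissue and rate
#'
#' @param properties A property table.
#' @return A ggplot object (free y scales, one panel per property).
#' @export
plot_property_boxes <- function(properties) {
  long <- tidyr::pivot_longer(properties, dplyr::all_of(property_cols()),
                              names_to = "property", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$rate_mm_s), .data$value,
                                     fill = .data$tissue)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$property), scales = "free_y") +
    ggplot2::labs(x = "loading rate (mm/s)", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a Veronda-Westmann fit
#'
#' Observed pre-peak stress-strain points with the fitted model curve.
#'
#' @param object A `vw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vw_fit
#' @export
autoplot.vw_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$strain)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$stress), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "firebrick") +
    ggplot2::labs(
      x = "nominal strain", y = "nominal stress (MPa)",
      subtitle = sprintf("mu = %.4g MPa, gamma = %.4g, R^2 = %.4f",
                         object$mu, object$gamma, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a classification report
#'
#' Per-feature contribution shares for one LOOCV classification task.
#'
#' @param object A `tissue_classifier`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tissue_classifier
#' @export
autoplot.tissue_classifier <- function(object, ...) {
  ggplot2::ggplot(object$contributions,
                  ggplot2::aes(stats::reorder(.data$feature, .data$share),
                               .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "contribution share",
      subtitle = sprintf("task %s: accuracy %.3f",
                         object$task_label, object$metrics$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
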