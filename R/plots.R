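#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman difference-vs-mean plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: per-pair differences against pair means, with the bias
#'   (solid) and the 1.96-SD limits of agreement (dashed).
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "Mean of manual and automated counts",
                  y = "Difference (manual - automated)",
                  title = sprintf("Bland-Altman: bias %.2f, LoA (%.2f, %.2f)",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Mixture-fit density plot with the positivity gate
#'
#' @param object A [fit_gmm2()] result.
#' @param values Optional raw vector the fit was computed on, drawn as a
#'   histogram underneath the component densities.
#' @param ... Unused.
#' @return A ggplot: the two weighted Gaussian densities and a vertical
#'   line at the gate (mean of the positive component).
#' @export
autoplot.gmm_fit <- function(object, values = NULL, ...) {
  lims <- range(object$means + c(-4, 4) * sqrt(max(object$variances)))
  grid <- tibble::tibble(x = seq(lims[1], lims[2], length.out = 400))
  dens <- dplyr::bind_rows(
    dplyr::mutate(grid, component = "negative",
                  density = object$weights[1] *
                    stats::dnorm(.data$x, object$means[1], sqrt(object$variances[1]))),
    dplyr::mutate(grid, component = "positive",
                  density = object$weights[2] *
                    stats::dnorm(.data$x, object$means[2], sqrt(object$variances[2])))
  )
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                          color = .data$component))
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(v = values),
      ggplot2::aes(x = .data$v, y = ggplot2::after_stat(density)),
      bins = 60, inherit.aes = FALSE, fill = "grey85", color = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = object$means[2], linetype = "dashed") +
    ggplot2::labs(x = "Normalized intensity (log10 scale)", y = "Density",
                  title = sprintf("%s: gate at positive-component peak %.3f",
                                  ifelse(is.na(object$marker), "marker",
                                         object$marker), object$means[2])) +
    ggplot2::theme_minimal()
}

#' Per-ROI percent-positive bar plot for a scored section
#'
#' @param object A [score_section()] result.
#' @param ... Unused.
#' @return A ggplot of per-ROI percent positive with the section mean line.
#' @export
autoplot.section_score <- function(object, ...) {
  ggplot2::ggplot(object$roi_scores,
                  ggplot2::aes(x = .data$roi_id, y = .data$percent_positive)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$summary$mean_percent_positive,
                        linetype = "dashed") +
    ggplot2::labs(x = "ROI", y = "Percent positive cells",
                  title = sprintf("Section %s: %.1f%% +/- %.1f%%",
                                  object$section_id,
                                  object$summary$mean_percent_positive,
                                  object$summary$sd_percent_positive)) +
    ggplot2::theme_minimal()
}

#' Cohort percent-positive bar plot with the classification cutoff
#'
#' @param object A [summarize_cohort()] result.
#' @param ... Unused.
#' @return A ggplot of per-sample percent positive colored by class, with
#'   the cutoff line.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  rec <- dplyr::arrange(object$records, dplyr::desc(.data$percent_positive))
  rec$sample_id <- factor(rec$sample_id, levels = rec$sample_id)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$sample_id,
                                    y = .data$percent_positive,
                                    fill = .data$p16_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Percent p16-positive cells", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
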