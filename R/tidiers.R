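#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(term = c("bias", "sd_diff", "loa_low", "loa_high",
                          "ci_low", "ci_high"),
                 estimate = c(x$bias, x$sd_diff, x$loa_low, x$loa_high,
                              x$ci_low, x$ci_high))
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(component = c("negative", "positive"),
                 weight = x$weights, mean = x$means, variance = x$variances)
}

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, log_likelihood = x$log_likelihood,
                 n_iterations = x$n_iterations, converged = x$converged)
}

#' @export
tidy.calibration_report <- function(x, ...) x$candidates

#' @export
glance.calibration_report <- function(x, ...) {
  tibble::tibble(selected_threshold = x$selected_threshold,
                 n_candidates = nrow(x$candidates),
                 n_images = x$candidates$n[1])
}

#' @export
tidy.section_score <- function(x, ...) x$roi_scores

#' @export
glance.section_score <- function(x, ...) {
  dplyr::mutate(x$summary, section_id = x$section_id, .before = 1)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$records

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_deficient = x$n_deficient,
                 proportion_deficient = x$proportion_deficient,
                 cutoff = x$cutoff)
}

#' @export
tidy.condition_summary <- function(x, ...) x$condition_stats

#' @export
glance.condition_summary <- function(x, ...) {
  tibble::tibble(n_conditions = length(unique(x$condition_stats$condition)),
                 n_markers = length(unique(x$condition_stats$marker)),
                 n_comparisons = nrow(x$comparisons))
}
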