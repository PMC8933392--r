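#' Parameters for the synthetic single-cell intensity generator
#'
#' Emulates the statistical structure the gating model assumes: per marker,
#' log10 intensities are a two-component Gaussian mixture (negative and
#' positive populations), each sample shifted by an additive log10 offset
#' that emulates sample-to-sample staining/exposure scale differences. Raw
#' intensities are `10^x`.
#'
#' @param markers A tibble/data.frame with one row per marker and columns
#'   `marker`, `negative_mean`, `positive_mean`, `sd`, `positive_fraction`
#'   (means and sd on the log10 scale). The default single marker uses the
#'   canonical well-separated pair: negative mean 1, positive mean 3,
#'   sd 0.1, positive fraction 0.5.
#' @param n_cells_per_sample Cells simulated per sample.
#' @param n_samples Number of samples.
#' @param sample_shifts Additive log10 offset per sample (length
#'   `n_samples`; default all 0).
#' @param seed Integer seed.
#' @return A list of class `cycif_sim_params`.
#' @export
cycif_sim_params <- function(markers = default_marker_panel(),
                             n_cells_per_sample = 2000,
                             n_samples = 1,
                             sample_shifts = rep(0, n_samples),
                             seed = 1L) {
  markers <- tibble::as_tibble(markers)
  need <- c("marker", "negative_mean", "positive_mean", "sd", "positive_fraction")
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0) {
    rlang::abort(paste0("`markers` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  ok <- all(markers$positive_mean > markers$negative_mean) &&
    all(markers$sd > 0) &&
    all(markers$positive_fraction >= 0 & markers$positive_fraction <= 1) &&
    n_cells_per_sample >= 0 && n_samples >= 1 &&
    length(sample_shifts) == n_samples
  if (!ok) {
    rlang::abort("invalid `cycif_sim_params`: need positive_mean > negative_mean, sd > 0, fractions in [0,1], one shift per sample")
  }
  structure(list(markers = markers, n_cells_per_sample = n_cells_per_sample,
                 n_samples = n_samples, sample_shifts = sample_shifts,
                 seed = as.integer(seed)),
            class = "cycif_sim_params")
}

#' Default one-marker panel for the intensity simulator
#' @return A one-row tibble (marker `"marker1"`, log10 means 1 and 3, sd
#'   0.1, positive fraction 0.5).
#' @export
default_marker_panel <- function() {
  tibble::tibble(marker = "marker1", negative_mean = 1, positive_mean = 3,
                 sd = 0.1, positive_fraction = 0.5)
}

#' Marker panel mirroring the rule-based phenotyping thresholds
#'
#' Panel of the seven phenotyping markers with component means placed so
#' each marker's rule threshold separates the two populations; used to
#' exercise cell typing against planted labels.
#'
#' @param sd Common log10 sd (default 0.1, i.e. >= 5 sigma separation).
#' @param positive_fraction Common positive fraction per marker.
#' @return A tibble usable as the `markers` argument of
#'   [cycif_sim_params()].
#' @export
typing_marker_panel <- function(sd = 0.1, positive_fraction = 0.4) {
  rules <- c(cytokeratin = 2.5, LaminB1 = 3.3, cleaved_caspase3 = 1.9,
             pH2Ax = 2.9, p16 = 2.8, p_RB = 2.7, PCNA = 3.3)
  tibble::tibble(
    marker = names(rules),
    negative_mean = unname(rules) - 1,
    positive_mean = unname(rules) + 1,
    sd = sd,
    positive_fraction = positive_fraction
  )
}

#' Simulate a cells x markers raw-intensity table with known labels
#'
#' Per marker and sample, draws component labels, samples log10 intensity
#' from the labelled Gaussian, adds the sample's scale shift, and
#' exponentiates to the raw scale.
#'
#' @param params A [cycif_sim_params()] object.
#' @return A list with `table` (tibble: `cell_id`, `sample_id`, one raw
#'   intensity column per marker) and `labels` (tibble: `cell_id`,
#'   `sample_id`, `marker`, `positive`).
#' @examples
#' sim <- simulate_intensity_table(cycif_sim_params(n_cells_per_sample = 100))
#' head(sim$table)
#' @export
simulate_intensity_table <- function(params = cycif_sim_params()) {
  if (!inherits(params, "cycif_sim_params")) {
    rlang::abort("`params` must be built by cycif_sim_params()")
  }
  p <- params
  n <- p$n_cells_per_sample
  withr::with_seed(p$seed, {
    per_sample <- purrr::map(seq_len(p$n_samples), function(s) {
      sample_id <- sprintf("sample%02d", s)
      cells <- tibble::tibble(
        cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
        sample_id = sample_id
      )
      lab_rows <- list()
      for (k in seq_len(nrow(p$markers))) {
        m <- p$markers[k, ]
        positive <- stats::runif(n) < m$positive_fraction
        mu <- ifelse(positive, m$positive_mean, m$negative_mean)
        logval <- stats::rnorm(n, mu, m$sd) + p$sample_shifts[s]
        cells[[m$marker]] <- 10^logval
        lab_rows[[k]] <- tibble::tibble(
          cell_id = cells$cell_id, sample_id = sample_id,
          marker = m$marker, positive = positive
        )
      }
      list(cells = cells, labels = dplyr::bind_rows(lab_rows))
    })
  })
  list(
    table = dplyr::bind_rows(purrr::map(per_sample, "cells")),
    labels = dplyr::bind_rows(purrr::map(per_sample, "labels"))
  )
}
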