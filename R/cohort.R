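#' Classify a sample as p16-positive or p16-deficient
#'
#' A sample is positive when its percent of p16-positive cancer cells
#' strictly exceeds the cutoff (default 30%); otherwise deficient. Exactly
#' 30% therefore falls deficient, keeping one consistent strict-`>` rule.
#'
#' @param percent_positive Numeric vector of section-level percent-positive
#'   values in `[0, 100]`.
#' @param cutoff Cutoff percentage (default 30).
#' @return A factor with levels `deficient`, `positive`.
#' @examples
#' classify_sample(c(0, 30, 30.1, 100))
#' @export
classify_sample <- function(percent_positive, cutoff = 30) {
  if (any(!is.finite(percent_positive)) ||
      any(percent_positive < 0 | percent_positive > 100)) {
    rlang::abort("`percent_positive` must lie in [0, 100]")
  }
  factor(ifelse(percent_positive > cutoff, "positive", "deficient"),
         levels = c("deficient", "positive"))
}

#' Summarize a scored cohort
#'
#' Classifies every sample at the cutoff, tabulates the deficient
#' proportion, summarizes percent-positive by tissue source, and — when at
#' least three matched PDX/patient pairs exist — reports the matched-pair
#' Pearson correlation and an unpaired two-sided t-test between sources.
#'
#' @param records Tibble with columns `sample_id`, `percent_positive`, and
#'   optionally `tissue_source` (`PDX`/`patient`), `matched_id`, `subtype`,
#'   `cdkn2a_cnv` (annotation only; never used for classification).
#' @param cutoff Classification cutoff percentage (default 30).
#' @return An object of class `cohort_summary`: `records` (input plus
#'   `p16_class`), `n_total`, `n_deficient`, `proportion_deficient`,
#'   `by_source` (mean, sd, n per tissue source), `matched` (the
#'   [concordance_pdx_patient()] row, or a not-computable placeholder).
#'   Supports `tidy()` and `glance()`.
#' @export
summarize_cohort <- function(records, cutoff = 30) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) rlang::abort("cohort is empty")
  if (!all(c("sample_id", "percent_positive") %in% names(records))) {
    rlang::abort("records need `sample_id` and `percent_positive` columns")
  }
  records$p16_class <- classify_sample(records$percent_positive, cutoff)
  n_total <- nrow(records)
  n_deficient <- sum(records$p16_class == "deficient")

  by_source <- if ("tissue_source" %in% names(records)) {
    records |>
      dplyr::group_by(.data$tissue_source) |>
      dplyr::summarise(
        mean_percent = mean(.data$percent_positive),
        sd_percent = if (dplyr::n() > 1) stats::sd(.data$percent_positive) else NA_real_,
        n = dplyr::n(), .groups = "drop"
      )
  } else tibble::tibble(tissue_source = character(0), mean_percent = numeric(0),
                        sd_percent = numeric(0), n = integer(0))

  matched <- tryCatch(
    concordance_pdx_patient(records),
    error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
                                       t_p = NA_real_, n_pairs = 0L,
                                       computable = FALSE)
  )

  structure(list(records = records, n_total = n_total,
                 n_deficient = n_deficient,
                 proportion_deficient = n_deficient / n_total,
                 cutoff = cutoff, by_source = by_source, matched = matched),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d/%d (%.0f%%) deficient at the %g%% cutoff\n",
              x$n_deficient, x$n_total, 100 * x$proportion_deficient, x$cutoff))
  if (nrow(x$by_source) > 0) print(x$by_source)
  invisible(x)
}

#' Concordance between matched PDX and patient scores
#'
#' Pearson correlation (with two-sided p) over matched percent-positive
#' pairs, plus an unpaired two-sided t-test between the two tissue-source
#' groups (paired available by flag).
#'
#' @param records Cohort tibble with `tissue_source`, `matched_id`,
#'   `percent_positive`; matched pairs are `matched_id`s present in both
#'   sources. At least 3 pairs required.
#' @param paired Use a paired t-test over the matched pairs instead of the
#'   unpaired group comparison.
#' @return A one-row tibble: `r`, `p`, `t_p`, `n_pairs`, `computable`.
#' @export
concordance_pdx_patient <- function(records, paired = FALSE) {
  records <- tibble::as_tibble(records)
  need <- c("tissue_source", "matched_id", "percent_positive")
  if (!all(need %in% names(records))) {
    rlang::abort("records need `tissue_source`, `matched_id`, `percent_positive`")
  }
  pdx <- records[records$tissue_source == "PDX" & !is.na(records$matched_id), ]
  pat <- records[records$tissue_source == "patient" & !is.na(records$matched_id), ]
  ids <- intersect(pdx$matched_id, pat$matched_id)
  if (length(ids) < 3) {
    rlang::abort("need at least 3 matched PDX/patient pairs",
                 class = "ihcgate_not_computable")
  }
  a <- pdx$percent_positive[match(ids, pdx$matched_id)]
  b <- pat$percent_positive[match(ids, pat$matched_id)]
  pc <- pearson_concordance(a, b)
  tt <- if (paired) {
    stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  } else {
    stats::t.test(records$percent_positive[records$tissue_source == "PDX"],
                  records$percent_positive[records$tissue_source == "patient"],
                  var.equal = TRUE, alternative = "two.sided")
  }
  tibble::tibble(r = pc$r, p = pc$p, t_p = tt$p.value,
                 n_pairs = length(ids), computable = TRUE)
}
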