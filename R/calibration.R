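#' Pearson concordance between two observers' counts
#'
#' Standard Pearson correlation with the two-sided t-distributed p-value,
#' used to check that manual calling of DAB-stained cells agrees between
#' observers.
#'
#' @param counts_a,counts_b Equal-length numeric vectors, `n >= 3`, each
#'   with nonzero variance.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @examples
#' pearson_concordance(c(1, 2, 3, 4), c(2, 4, 5, 9))
#' @export
pearson_concordance <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) rlang::abort("count vectors must have equal length")
  if (length(counts_a) < 3) rlang::abort("need at least 3 paired counts")
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    rlang::abort("correlation undefined: one vector has zero variance",
                 class = "ihcgate_zero_variance")
  }
  ct <- stats::cor.test(counts_a, counts_b, method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(counts_a))
}

#' Bland-Altman agreement between manual and automated counts
#'
#' For paired measurements, differences are `d_i = manual_i - automated_i`;
#' the bias is their mean, the limits of agreement are
#' `bias +/- 1.96 * sd(d)`, and the 95% confidence interval of the bias is
#' `bias +/- t_{0.975, n-1} * sd(d) / sqrt(n)`. Both intervals are reported
#' and labelled; they answer different questions (spread of individual
#' differences vs uncertainty of the mean difference).
#'
#' @param manual,automated Equal-length numeric vectors, `n >= 2`. By the
#'   calibration convention `manual` is the across-observer mean count.
#' @return An object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `ci_low`, `ci_high`, plus the per-pair `data`
#'   tibble (`mean`, `diff`) for plotting. Supports `tidy()`, `glance()`
#'   and `autoplot()`.
#' @examples
#' bland_altman(c(100, 200), c(90, 210))
#' @export
bland_altman <- function(manual, automated) {
  if (length(manual) != length(automated)) rlang::abort("inputs must have equal length")
  n <- length(manual)
  if (n < 2) rlang::abort("Bland-Altman needs at least 2 pairs")
  d <- manual - automated
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  half_ci <- stats::qt(0.975, df = n - 1) * sd_diff / sqrt(n)
  structure(
    list(n = n, bias = bias, sd_diff = sd_diff,
         loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
         ci_low = bias - half_ci, ci_high = bias + half_ci,
         data = tibble::tibble(mean = (manual + automated) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.3f (95%% CI %.3f, %.3f), LoA (%.3f, %.3f)\n",
              x$n, x$bias, x$ci_low, x$ci_high, x$loa_low, x$loa_high))
  invisible(x)
}

#' Calibrate the DAB positivity threshold against manual observers
#'
#' For each candidate threshold, scores every test image with the automated
#' pipeline at that DAB threshold, compares the automated DAB-positive
#' counts to the across-observer mean manual counts by Bland-Altman
#' analysis, and selects the candidate minimizing the absolute bias. Ties
#' are broken toward the larger (more conservative) threshold. Pairwise
#' inter-observer Pearson concordance is reported alongside.
#'
#' @param images List of [stained_image()] objects (the manual test images).
#' @param observer_counts Tibble with columns `image_id`, `observer_id`,
#'   `dab_count` (and optionally `hema_count`); `image_id` must match the
#'   images' order (`img1`, `img2`, ... or the images' own `roi_id`s).
#' @param candidates Numeric vector of candidate DAB OD thresholds
#'   (default the tested grid 0.15, 0.25, 0.3).
#' @param config Base [scoring_config()]; its `dab_threshold` is replaced
#'   by each candidate in turn.
#' @param mode Compare `"counts"` (default, DAB-positive cell counts) or
#'   `"percent"` (percent-positive values; requires `hema_count`).
#' @return An object of class `calibration_report`: `candidates` tibble
#'   (one Bland-Altman row per threshold), `selected_threshold`,
#'   `observer_pearson` (pairwise `r`, `p`), `counts` (per image: manual
#'   mean and automated count per candidate). Supports `tidy()` and
#'   `glance()`.
#' @export
calibrate_dab_threshold <- function(images, observer_counts,
                                    candidates = c(0.15, 0.25, 0.30),
                                    config = scoring_config(),
                                    mode = c("counts", "percent")) {
  mode <- match.arg(mode)
  observer_counts <- tibble::as_tibble(observer_counts)
  if (length(images) < 2) rlang::abort("need at least 2 test images")
  if (nrow(observer_counts) == 0) rlang::abort("observer counts are empty")
  if (length(candidates) < 1) rlang::abort("need at least 1 candidate threshold")
  need <- c("image_id", "observer_id", "dab_count")
  missing <- setdiff(need, names(observer_counts))
  if (length(missing) > 0) {
    rlang::abort(paste0("observer counts lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (mode == "percent" && !"hema_count" %in% names(observer_counts)) {
    rlang::abort("percent mode needs a `hema_count` column")
  }

  image_ids <- purrr::map_chr(seq_along(images), function(i) {
    img <- images[[i]]
    if (inherits(img, "stained_image") && !is.na(img$roi_id)) img$roi_id
    else sprintf("img%d", i)
  })
  unknown <- setdiff(unique(observer_counts$image_id), image_ids)
  if (length(unknown) > 0) {
    rlang::abort(paste0("observer counts reference unknown image(s): ",
                        paste(unknown, collapse = ", ")))
  }

  # manual reference: per-image mean across observers
  manual <- observer_counts |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      manual_dab = mean(.data$dab_count),
      manual_hema = if ("hema_count" %in% names(observer_counts)) {
        mean(.data$hema_count)
      } else NA_real_,
      .groups = "drop"
    )
  manual <- manual[match(image_ids, manual$image_id), ]
  if (anyNA(manual$image_id)) {
    rlang::abort("every image needs observer counts")
  }

  # automated counts: one detection pass per image per candidate threshold
  auto <- purrr::map_dfr(seq_along(images), function(i) {
    od <- rgb_to_od(images[[i]], config$background_rgb)
    maps <- deconvolve_stains(od, config$stain_vectors)
    purrr::map_dfr(candidates, function(th) {
      cfg <- config
      cfg$dab_threshold <- th
      cells <- tryCatch(
        detect_cells(maps$hema, maps$dab, cfg),
        error = function(e) rlang::abort(
          sprintf("scoring failed on image %s: %s", image_ids[i], conditionMessage(e)))
      )
      tibble::tibble(image_id = image_ids[i], threshold = th,
                     auto_dab = sum(cells$dab_positive),
                     auto_hema = nrow(cells))
    })
  })

  per_candidate <- purrr::map_dfr(candidates, function(th) {
    a <- auto[auto$threshold == th, ]
    a <- a[match(image_ids, a$image_id), ]
    if (mode == "counts") {
      ba <- bland_altman(manual$manual_dab, a$auto_dab)
    } else {
      ba <- bland_altman(percent_positive(manual$manual_dab, manual$manual_hema),
                         percent_positive(a$auto_dab, a$auto_hema))
    }
    tibble::tibble(threshold = th, n = ba$n, bias = ba$bias,
                   sd_diff = ba$sd_diff, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, ci_low = ba$ci_low,
                   ci_high = ba$ci_high, abs_bias = abs(ba$bias))
  })

  # argmin |bias|; ties broken by the larger threshold
  best <- per_candidate[order(per_candidate$abs_bias, -per_candidate$threshold), ]
  selected <- best$threshold[1]

  observers <- unique(observer_counts$observer_id)
  pairs <- if (length(observers) >= 2) utils::combn(observers, 2, simplify = FALSE) else list()
  observer_pearson <- purrr::map_dfr(pairs, function(pr) {
    a <- observer_counts$dab_count[observer_counts$observer_id == pr[1]][
      match(image_ids, observer_counts$image_id[observer_counts$observer_id == pr[1]])]
    b <- observer_counts$dab_count[observer_counts$observer_id == pr[2]][
      match(image_ids, observer_counts$image_id[observer_counts$observer_id == pr[2]])]
    res <- tryCatch(pearson_concordance(a, b),
                    error = function(e) tibble::tibble(r = NA_real_, p = NA_real_,
                                                       n = length(a)))
    dplyr::mutate(res, observer_a = pr[1], observer_b = pr[2], .before = 1)
  })

  structure(
    list(candidates = per_candidate, selected_threshold = selected,
         observer_pearson = observer_pearson,
         counts = dplyr::left_join(
           tidyr::pivot_wider(auto, names_from = "threshold",
                              values_from = c("auto_dab", "auto_hema")),
           manual, by = "image_id")),
    class = "calibration_report"
  )
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> selected DAB threshold: %.2f\n",
              x$selected_threshold))
  print(x$candidates)
  invisible(x)
}
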