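#' Parameters for the synthetic manual-observer generator
#'
#' Emulates manual scoring of test images by several observers: each
#' observer's count is the true count plus a fixed per-observer bias plus
#' Gaussian miscount noise, floored at zero and rounded.
#'
#' @param n_observers Number of observers (>= 1).
#' @param miscount_dispersion Standard deviation of the miscount noise, in
#'   cells (>= 0).
#' @param bias_per_observer Signed per-observer count offsets; length 1
#'   (recycled) or `n_observers`.
#' @param seed Integer seed.
#' @return A list of class `observer_sim_params`.
#' @export
observer_sim_params <- function(n_observers = 3,
                                miscount_dispersion = 0,
                                bias_per_observer = 0,
                                seed = 1L) {
  if (n_observers < 1 || miscount_dispersion < 0) {
    rlang::abort("need n_observers >= 1 and miscount_dispersion >= 0")
  }
  if (length(bias_per_observer) == 1) {
    bias_per_observer <- rep(bias_per_observer, n_observers)
  }
  if (length(bias_per_observer) != n_observers) {
    rlang::abort("`bias_per_observer` must have length 1 or n_observers")
  }
  structure(list(n_observers = n_observers,
                 miscount_dispersion = miscount_dispersion,
                 bias_per_observer = bias_per_observer,
                 seed = as.integer(seed)),
            class = "observer_sim_params")
}

#' Simulate per-observer counts from per-image true counts
#'
#' @param truth A tibble/data.frame with columns `image_id` plus one or both
#'   of `dab_count` and `hema_count` holding the true counts; must be
#'   nonempty.
#' @param params An [observer_sim_params()] object.
#' @return A tibble with `image_id`, `observer_id`, and noisy versions of
#'   each count column: `max(0, round(true + bias + noise))`, deterministic
#'   per seed.
#' @examples
#' truth <- tibble::tibble(image_id = paste0("img", 1:3),
#'                         dab_count = c(40, 80, 120))
#' simulate_observer_counts(truth, observer_sim_params(miscount_dispersion = 0))
#' @export
simulate_observer_counts <- function(truth,
                                     params = observer_sim_params()) {
  truth <- tibble::as_tibble(truth)
  if (nrow(truth) == 0) rlang::abort("`truth` must be nonempty")
  if (!"image_id" %in% names(truth)) rlang::abort("`truth` needs an `image_id` column")
  count_cols <- intersect(c("dab_count", "hema_count"), names(truth))
  if (length(count_cols) == 0) {
    rlang::abort("`truth` needs a `dab_count` and/or `hema_count` column")
  }
  p <- params
  withr::with_seed(p$seed, {
    out <- purrr::map(seq_len(p$n_observers), function(j) {
      obs <- tibble::tibble(image_id = truth$image_id,
                            observer_id = sprintf("observer%d", j))
      for (col in count_cols) {
        noise <- if (p$miscount_dispersion > 0) {
          stats::rnorm(nrow(truth), 0, p$miscount_dispersion)
        } else 0
        obs[[col]] <- pmax(0, round(truth[[col]] + p$bias_per_observer[j] + noise))
      }
      obs
    })
  })
  dplyr::bind_rows(out)
}
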