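#' Normalize a multi-sample single-cell intensity table
#'
#' Per marker, raw intensities are mapped to `log10(x + 1)` and each
#' sample receives an additive shift aligning its median to the pooled
#' (all-sample) median. The transform is order-preserving within sample
#' and exactly invertible: `raw = 10^(normalized - shift) - 1`. A sample
#' whose intensities are all zero for a marker is flagged and gets shift 0.
#'
#' @param table Tibble with `cell_id`, `sample_id` and one raw-intensity
#'   column per marker (nonnegative).
#' @param markers Marker column names; default every column other than
#'   `cell_id`/`sample_id`.
#' @return An object of class `cycif_norm`: `table` (same shape, marker
#'   columns normalized), `transforms` (tibble `marker`, `sample_id`,
#'   `shift`, `flagged`), `markers`.
#' @export
normalize_intensities <- function(table, markers = NULL) {
  table <- tibble::as_tibble(table)
  if (!all(c("cell_id", "sample_id") %in% names(table))) {
    rlang::abort("table needs `cell_id` and `sample_id` columns")
  }
  if (is.null(markers)) markers <- setdiff(names(table), c("cell_id", "sample_id"))
  if (length(markers) == 0) rlang::abort("no marker columns found")
  if (nrow(table) == 0) rlang::abort("table has no cells")
  for (m in markers) {
    if (any(table[[m]] < 0, na.rm = TRUE)) {
      rlang::abort(sprintf("marker `%s` has negative intensities", m))
    }
  }
  samples <- unique(table$sample_id)
  if (any(table(table$sample_id) < 1)) rlang::abort("every sample needs >= 1 cell")

  out <- table
  transforms <- purrr::map_dfr(markers, function(m) {
    logv <- log10(table[[m]] + 1)
    pooled_median <- stats::median(logv)
    tr <- purrr::map_dfr(samples, function(s) {
      sel <- table$sample_id == s
      flagged <- all(table[[m]][sel] == 0)
      shift <- if (flagged) 0 else pooled_median - stats::median(logv[sel])
      tibble::tibble(marker = m, sample_id = s, shift = shift, flagged = flagged)
    })
    shifts <- tr$shift[match(table$sample_id, tr$sample_id)]
    out[[m]] <<- logv + shifts
    tr
  })
  structure(list(table = out, transforms = transforms, markers = markers),
            class = "cycif_norm")
}

#' Invert the normalization for one marker/sample
#'
#' @param normalized Numeric vector on the normalized scale.
#' @param marker,sample_id Which stored transform to invert.
#' @param transforms The `transforms` tibble from [normalize_intensities()]
#'   (or a `cycif_norm` object).
#' @return Raw-scale intensities `10^(normalized - shift) - 1`.
#' @export
denormalize_intensities <- function(normalized, marker, sample_id, transforms) {
  if (inherits(transforms, "cycif_norm")) transforms <- transforms$transforms
  row <- transforms[transforms$marker == marker & transforms$sample_id == sample_id, ]
  if (nrow(row) != 1) {
    rlang::abort(sprintf("no stored transform for marker `%s`, sample `%s`",
                         marker, sample_id))
  }
  10^(normalized - row$shift) - 1
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization with multiple restarts: the first restart
#' splits the data at the median, further restarts split at random
#' quantiles (seeded). Convergence when the log-likelihood gain drops
#' below `tol` or at `max_iter` iterations; variances are floored at
#' `var_floor` to prevent component collapse. Components are reordered so
#' `mu1 < mu2`; the positive population is component 2.
#'
#' @param values Numeric vector of normalized intensities, `n >= 20`,
#'   nonzero variance.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of EM restarts (best final log-likelihood kept).
#' @param max_iter,tol EM stopping rule (default 500 iterations, 1e-8 gain).
#' @param var_floor Lower bound on component variances.
#' @param marker Optional marker name carried into the fit.
#' @return An object of class `gmm_fit`: `weights`, `means`, `variances`
#'   (each length 2, means increasing), `n_iterations`, `log_likelihood`,
#'   `log_likelihood_trace` (of the winning restart), `converged`, `n`,
#'   `marker`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 1, 0.1), rnorm(200, 3, 0.1))
#' fit_gmm2(x, seed = 1)
#' @export
fit_gmm2 <- function(values, seed = 1L, n_restarts = 5, max_iter = 500,
                     tol = 1e-8, var_floor = 1e-6, marker = NA_character_) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) rlang::abort("need at least 20 values to fit the mixture")
  if (stats::sd(values) == 0) {
    rlang::abort("values have zero variance; mixture undefined",
                 class = "ihcgate_zero_variance")
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    split_qs <- c(0.5, stats::runif(max(0, n_restarts - 1), 0.2, 0.8))
    for (q in split_qs[seq_len(n_restarts)]) {
      fit <- em_gmm2_once(values, split_q = q, max_iter = max_iter,
                          tol = tol, var_floor = var_floor)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
  })
  ord <- order(best$means)
  structure(
    list(marker = marker,
         weights = best$weights[ord], means = best$means[ord],
         variances = best$variances[ord],
         n_iterations = best$n_iterations,
         log_likelihood = best$log_likelihood,
         log_likelihood_trace = best$trace,
         converged = best$converged, n = n),
    class = "gmm_fit"
  )
}

# one EM run from a quantile-split initialization
em_gmm2_once <- function(x, split_q, max_iter, tol, var_floor) {
  n <- length(x)
  cut <- stats::quantile(x, split_q, names = FALSE)
  lo <- x[x <= cut]; hi <- x[x > cut]
  if (length(lo) < 2 || length(hi) < 2) {
    ord <- sort(x)
    lo <- ord[1:floor(n / 2)]; hi <- ord[(floor(n / 2) + 1):n]
  }
  mu <- c(mean(lo), mean(hi))
  sig2 <- pmax(c(stats::var(lo), stats::var(hi)), var_floor)
  w <- c(length(lo), length(hi)) / n

  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # E step in log space for stability
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(sig2[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(sig2[2]), log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    new_loglik <- sum(lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) && new_loglik - loglik < tol) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    g1 <- exp(l1 - lse)
    g2 <- 1 - g1
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-10 || n2 < 1e-10) break   # component collapsed
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sig2 <- pmax(c(sum(g1 * (x - mu[1])^2) / n1,
                   sum(g2 * (x - mu[2])^2) / n2), var_floor)
    w <- c(n1, n2) / n
  }
  list(weights = w, means = mu, variances = sig2, n_iterations = it,
       log_likelihood = loglik, trace = trace, converged = converged)
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit>%s n=%d: w=(%.3f, %.3f) mu=(%.3f, %.3f) sd=(%.3f, %.3f)%s\n",
    if (is.na(x$marker)) "" else paste0(" ", x$marker), x$n,
    x$weights[1], x$weights[2], x$means[1], x$means[2],
    sqrt(x$variances[1]), sqrt(x$variances[2]),
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Derive the positivity gate from a fitted mixture
#'
#' The positive threshold is the peak of the positive (higher-mean)
#' Gaussian component, i.e. its mean `mu2` on the normalized scale; it is
#' mapped back to the raw scale per sample through the stored
#' normalization shifts.
#'
#' @param fit A [fit_gmm2()] result (must have converged unless
#'   `allow_unconverged = TRUE`).
#' @param transforms The `transforms` tibble from [normalize_intensities()]
#'   (or the `cycif_norm` object); only the fit's marker rows are used.
#' @param marker Marker name; defaults to the fit's marker.
#' @param allow_unconverged Proceed despite a non-converged fit.
#' @return An object of class `gate_result`: `marker`,
#'   `threshold_normalized` (= mu2) and `thresholds` (tibble `sample_id`,
#'   `shift`, `threshold_raw`).
#' @export
gate_marker <- function(fit, transforms, marker = fit$marker,
                        allow_unconverged = FALSE) {
  if (!inherits(fit, "gmm_fit")) rlang::abort("`fit` must be a gmm_fit")
  if (!fit$converged && !allow_unconverged) {
    rlang::abort("mixture fit did not converge; pass allow_unconverged = TRUE to override")
  }
  if (inherits(transforms, "cycif_norm")) transforms <- transforms$transforms
  tr <- if (is.na(marker)) transforms else transforms[transforms$marker == marker, ]
  if (nrow(tr) == 0) rlang::abort("no stored transforms for this marker")
  mu2 <- fit$means[2]
  thresholds <- tibble::tibble(
    sample_id = tr$sample_id, shift = tr$shift,
    threshold_raw = 10^(mu2 - tr$shift) - 1
  )
  if (any(thresholds$threshold_raw <= 0)) {
    rlang::abort("raw threshold is not strictly positive; check the normalization shifts")
  }
  structure(list(marker = marker, threshold_normalized = mu2,
                 thresholds = thresholds),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %s: normalized threshold %.4f (raw per sample below)\n",
              x$marker, x$threshold_normalized))
  print(x$thresholds)
  invisible(x)
}

#' Call per-cell positivity from a gate
#'
#' A cell is positive for the marker iff its normalized value strictly
#' exceeds the gate's normalized threshold (equivalently its raw value
#' strictly exceeds that sample's raw threshold). A value exactly at the
#' threshold is negative.
#'
#' @param norm A `cycif_norm` object (or its normalized `table`).
#' @param gate A [gate_marker()] result.
#' @return A tibble `cell_id`, `sample_id`, `value_normalized`, `positive`.
#' @export
call_positive <- function(norm, gate) {
  table <- if (inherits(norm, "cycif_norm")) norm$table else tibble::as_tibble(norm)
  m <- gate$marker
  if (!m %in% names(table)) {
    rlang::abort(sprintf("marker `%s` not present in table", m))
  }
  unknown <- setdiff(unique(table$sample_id), gate$thresholds$sample_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("gate does not cover sample(s): ",
                        paste(unknown, collapse = ", ")))
  }
  tibble::tibble(
    cell_id = table$cell_id, sample_id = table$sample_id,
    value_normalized = table[[m]],
    positive = table[[m]] > gate$threshold_normalized
  )
}

#' Normalize, fit and gate every marker of an intensity table
#'
#' End-to-end convenience for the gating stage: [normalize_intensities()],
#' then per marker [fit_gmm2()] on the pooled normalized values,
#' [gate_marker()], and [call_positive()].
#'
#' @inheritParams normalize_intensities
#' @param seed Seed passed to the mixture fits.
#' @param per_sample Fit mixtures per sample instead of pooled (off by
#'   default; the pooled fit after cross-sample normalization is the
#'   standard route).
#' @return A list of class `cycif_gating`: `norm` (the `cycif_norm`),
#'   `fits` (named list of `gmm_fit`), `gates` (named list of
#'   `gate_result`), `calls` (tibble `cell_id`, `sample_id`, one logical
#'   column per marker).
#' @export
gate_cycif <- function(table, markers = NULL, seed = 1L, per_sample = FALSE) {
  norm <- normalize_intensities(table, markers)
  fits <- list(); gates <- list()
  calls <- norm$table[, c("cell_id", "sample_id")]
  samples <- unique(norm$table$sample_id)
  for (m in norm$markers) {
    if (per_sample) {
      # non-default route: one mixture and one gate per sample
      sample_fits <- purrr::map(samples, function(s) {
        fit_gmm2(norm$table[[m]][norm$table$sample_id == s], seed = seed,
                 marker = m)
      })
      names(sample_fits) <- samples
      fits[[m]] <- sample_fits
      tr <- norm$transforms[norm$transforms$marker == m, ]
      mu2 <- purrr::map_dbl(sample_fits, function(f) f$means[2])
      shift <- tr$shift[match(samples, tr$sample_id)]
      gates[[m]] <- structure(
        list(marker = m, threshold_normalized = mu2,
             thresholds = tibble::tibble(sample_id = samples, shift = shift,
                                         threshold_raw = 10^(mu2 - shift) - 1)),
        class = "gate_result")
      thr <- mu2[match(norm$table$sample_id, samples)]
      calls[[m]] <- norm$table[[m]] > thr
    } else {
      fits[[m]] <- fit_gmm2(norm$table[[m]], seed = seed, marker = m)
      gates[[m]] <- gate_marker(fits[[m]], norm)
      calls[[m]] <- call_positive(norm, gates[[m]])$positive
    }
  }
  structure(list(norm = norm, fits = fits, gates = gates, calls = calls),
            class = "cycif_gating")
}
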