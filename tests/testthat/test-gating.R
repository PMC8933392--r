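test_that("normalization is log10(x+1) plus a median-aligning shift, invertible", {
  # single sample: shift 0, normalized = log10(x+1)
  tb <- tibble::tibble(cell_id = paste0("c", 1:5), sample_id = "s1",
                       m = c(0, 9, 99, 999, 9999))
  norm <- normalize_intensities(tb)
  expect_equal(norm$transforms$shift, 0)
  expect_equal(norm$table$m, log10(tb$m + 1))

  # round trip through the stored transform
  back <- denormalize_intensities(norm$table$m, "m", "s1", norm)
  expect_equal(back, tb$m, tolerance = 1e-9)

  # all-zero sample is flagged with shift 0
  tb2 <- dplyr::bind_rows(tb, tibble::tibble(cell_id = paste0("z", 1:3),
                                             sample_id = "s2", m = 0))
  norm2 <- normalize_intensities(tb2)
  tr2 <- norm2$transforms[norm2$transforms$sample_id == "s2", ]
  expect_true(tr2$flagged)
  expect_equal(tr2$shift, 0)

  expect_error(normalize_intensities(dplyr::mutate(tb, m = -m)), "negative")
})

test_that("normalization recovers a planted sample-to-sample scale shift", {
  p <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0.4), n_cells_per_sample = 2000, n_samples = 2,
    sample_shifts = c(0, 1), seed = 21)
  sim <- simulate_intensity_table(p)
  norm <- normalize_intensities(sim$table)
  shifts <- norm$transforms$shift[match(c("sample01", "sample02"),
                                        norm$transforms$sample_id)]
  # the estimated shifts must differ by the planted offset of 1
  expect_equal(shifts[1] - shifts[2], 1, tolerance = 0.05)
  # inversion reproduces the raw table exactly
  for (s in c("sample01", "sample02")) {
    sel <- norm$table$sample_id == s
    expect_equal(denormalize_intensities(norm$table$m[sel], "m", s, norm),
                 sim$table$m[sel], tolerance = 1e-9)
  }
})

test_that("EM recovers well-separated mixture parameters with monotone log-likelihood", {
  x <- draw_mixture(4000, 0.5, c(1, 3), 0.1, seed = 11)
  fit <- fit_gmm2(x, seed = 11)
  expect_true(fit$converged)
  expect_true(fit$means[1] > 0.95 && fit$means[1] < 1.05)
  expect_true(fit$means[2] > 2.95 && fit$means[2] < 3.05)
  expect_true(fit$weights[1] > 0.45 && fit$weights[1] < 0.55)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$log_likelihood_trace) >= -1e-9))
  expect_lt(fit$means[1], fit$means[2])

  # permuting the input leaves the fit unchanged
  fit_perm <- fit_gmm2(withr::with_seed(1, sample(x)), seed = 11)
  expect_equal(fit_perm$means, fit$means, tolerance = 1e-6)
  expect_equal(fit_perm$weights, fit$weights, tolerance = 1e-6)
})

test_that("EM is robust to a degenerate one-mode input with outliers", {
  x <- c(withr::with_seed(5, rnorm(500, 2, 0.05)), c(8, 8.1, 8.2, 7.9, 8.05))
  fit <- fit_gmm2(x, seed = 5)
  expect_s3_class(fit, "gmm_fit")
  expect_lt(fit$weights[2], 0.05)
  expect_true(all(diff(fit$log_likelihood_trace) >= -1e-9))

  expect_error(fit_gmm2(rep(1, 100)), class = "ihcgate_zero_variance")
  expect_error(fit_gmm2(rnorm(5)), "at least 20")
})

test_that("the gate sits at the positive-component peak and maps back exactly", {
  fit <- structure(list(marker = "m", weights = c(0.5, 0.5), means = c(1, 3),
                        variances = c(0.01, 0.01), n_iterations = 10,
                        log_likelihood = 0, log_likelihood_trace = 0,
                        converged = TRUE, n = 100),
                   class = "gmm_fit")
  transforms <- tibble::tibble(marker = "m",
                               sample_id = c("s1", "s2"),
                               shift = c(0, 0.5), flagged = FALSE)
  gate <- gate_marker(fit, transforms)
  expect_equal(gate$threshold_normalized, 3)
  raw <- gate$thresholds$threshold_raw
  expect_equal(raw[1], 999, tolerance = 1e-9)            # 10^3 - 1
  expect_equal(raw[2], 10^2.5 - 1, tolerance = 1e-9)     # ~315.23

  # equal shifts give identical raw thresholds
  tr_same <- tibble::tibble(marker = "m", sample_id = c("s1", "s2"),
                            shift = 0, flagged = FALSE)
  expect_equal(unique(gate_marker(fit, tr_same)$thresholds$threshold_raw), 999)

  fit_bad <- fit; fit_bad$converged <- FALSE
  expect_error(gate_marker(fit_bad, transforms), "converge")
  expect_s3_class(gate_marker(fit_bad, transforms, allow_unconverged = TRUE),
                  "gate_result")
})

test_that("positivity calls use a strict threshold and match a brute-force oracle", {
  p <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0.4), n_cells_per_sample = 5000, seed = 7)
  sim <- simulate_intensity_table(p)
  gating <- gate_cycif(sim$table, seed = 7)
  gate <- gating$gates$m

  # oracle: apply the same rule (normalized value > mu2) by hand
  norm_vals <- gating$norm$table$m
  oracle <- norm_vals > gate$threshold_normalized
  expect_equal(gating$calls$m, oracle)
  # gating at the positive peak keeps ~half the positive population
  expect_lt(abs(mean(gating$calls$m) - 0.4 / 2), 0.02)

  # a value exactly at the threshold is negative
  norm_one <- list(table = tibble::tibble(cell_id = "c", sample_id = "sample01",
                                          m = gate$threshold_normalized))
  class(norm_one) <- "cycif_norm"
  expect_false(call_positive(norm_one, gate)$positive)

  # unknown sample errors
  norm_bad <- list(table = tibble::tibble(cell_id = "c", sample_id = "sX",
                                          m = 1))
  class(norm_bad) <- "cycif_norm"
  expect_error(call_positive(norm_bad, gate), "does not cover")
})

test_that("gate thresholds are invariant to sample relabeling", {
  p <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0.4), n_cells_per_sample = 1000, n_samples = 2,
    sample_shifts = c(0, 0.3), seed = 13)
  sim <- simulate_intensity_table(p)
  g1 <- gate_cycif(sim$table, seed = 2)
  relabeled <- dplyr::mutate(sim$table, sample_id = dplyr::recode(
    sample_id, sample01 = "B", sample02 = "A"))
  g2 <- gate_cycif(relabeled, seed = 2)
  expect_equal(g2$gates$m$threshold_normalized,
               g1$gates$m$threshold_normalized, tolerance = 1e-9)
  thr1 <- g1$gates$m$thresholds
  thr2 <- g2$gates$m$thresholds
  expect_equal(thr2$threshold_raw[thr2$sample_id == "B"],
               thr1$threshold_raw[thr1$sample_id == "sample01"],
               tolerance = 1e-9)
})
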