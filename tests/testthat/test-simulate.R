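test_that("ihc simulator honors cell counts, exact assignment, and the empty case", {
  empty <- simulate_ihc_image(ihc_sim_params(n_cells = 0, seed = 1,
                                             background_noise_sd = 0))
  expect_equal(nrow(empty$ground_truth), 0)
  expect_true(all(empty$image$rgb == 255))

  sim <- simulate_ihc_image(ihc_sim_params(n_cells = 200,
                                           true_positive_fraction = 0.3,
                                           seed = 7))
  expect_equal(nrow(sim$ground_truth), 200)
  expect_equal(sum(sim$ground_truth$dab_positive), 60)  # round(0.3 * 200)

  # Bernoulli mode does not force the exact count but respects n_cells
  bern <- simulate_ihc_image(small_ihc_params(n_cells = 40, fraction = 0.5,
                                              seed = 3,
                                              exact_assignment = FALSE))
  expect_equal(nrow(bern$ground_truth), 40)
})

test_that("all three simulators are bit-reproducible under a fixed seed", {
  p <- small_ihc_params(n_cells = 50, fraction = 0.5, seed = 1)
  a <- simulate_ihc_image(p)
  b <- simulate_ihc_image(p)
  expect_identical(a$image$rgb, b$image$rgb)
  expect_identical(a$ground_truth, b$ground_truth)

  cp <- cycif_sim_params(n_cells_per_sample = 200, seed = 4)
  expect_identical(simulate_intensity_table(cp), simulate_intensity_table(cp))

  truth <- tibble::tibble(image_id = paste0("img", 1:5),
                          dab_count = c(10, 20, 30, 40, 50))
  op <- observer_sim_params(n_observers = 3, miscount_dispersion = 5, seed = 2)
  expect_identical(simulate_observer_counts(truth, op),
                   simulate_observer_counts(truth, op))
})

test_that("every DAB-positive simulated cell carries DAB OD at the stated level", {
  p <- small_ihc_params(n_cells = 30, fraction = 0.5, seed = 9,
                        cytoplasm_dab_fraction = 0.5)
  sim <- simulate_ihc_image(p)
  od <- rgb_to_od(sim$image)
  maps <- deconvolve_stains(od)
  gt <- sim$ground_truth
  floor_od <- p$dab_od_level - 3 * p$background_noise_sd
  for (i in which(gt$dab_positive)) {
    r <- round(gt$row[i]); c <- round(gt$col[i])
    if (gt$dab_compartment[i] == "nucleus") {
      expect_gte(maps$dab[r, c], floor_od - 0.05)  # 0.05 budget: 8-bit quantization
    } else {
      ring_r <- round(gt$row[i] + gt$radius_px[i] + 1.5)
      expect_gte(maps$dab[ring_r, c], floor_od - 0.05)
    }
  }
})

test_that("placement fails loudly when the field cannot hold the nuclei", {
  expect_error(
    simulate_ihc_image(ihc_sim_params(n_cells = 500,
                                      field_size_px = c(100, 100),
                                      max_tries = 20, seed = 1)),
    "could not place"
  )
  expect_error(ihc_sim_params(true_positive_fraction = 1.2), "invalid")
  expect_error(ihc_sim_params(dab_od_level = -1), "invalid")
})

test_that("intensity simulator reproduces its mixture parameters", {
  # positive_fraction 0 gives all-negative labels
  p0 <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0), n_cells_per_sample = 100, seed = 2)
  expect_false(any(simulate_intensity_table(p0)$labels$positive))

  # sample shift +1 multiplies raw medians by ~10
  p2 <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0.4), n_cells_per_sample = 2000, n_samples = 2,
    sample_shifts = c(0, 1), seed = 8)
  sim2 <- simulate_intensity_table(p2)
  med <- tapply(sim2$table$m, sim2$table$sample_id, stats::median)
  expect_equal(unname(med[2] / med[1]), 10, tolerance = 0.2)

  # label-conditional log10 means within +/-0.02 of (1, 3) at n=5000
  p5 <- cycif_sim_params(markers = tibble::tibble(
    marker = "m", negative_mean = 1, positive_mean = 3, sd = 0.1,
    positive_fraction = 0.5), n_cells_per_sample = 5000, seed = 11)
  sim5 <- simulate_intensity_table(p5)
  lab <- sim5$labels$positive
  logv <- log10(sim5$table$m)
  expect_equal(mean(logv[!lab]), 1, tolerance = 0.02)
  expect_equal(mean(logv[lab]), 3, tolerance = 0.02)
})

test_that("observer counts follow truth + bias + dispersion noise", {
  truth <- tibble::tibble(image_id = paste0("img", 1:4),
                          dab_count = c(15, 30, 45, 60),
                          hema_count = c(100, 100, 100, 100))
  exact <- simulate_observer_counts(truth, observer_sim_params(
    n_observers = 2, miscount_dispersion = 0, bias_per_observer = 0, seed = 1))
  expect_equal(exact$dab_count, rep(truth$dab_count, 2))
  expect_equal(exact$hema_count, rep(truth$hema_count, 2))

  biased <- simulate_observer_counts(truth, observer_sim_params(
    n_observers = 1, miscount_dispersion = 0, bias_per_observer = 5, seed = 1))
  expect_equal(biased$dab_count, truth$dab_count + 5)

  # mean of 20 noisy reads of a true count of 100 stays within +/-7
  truth100 <- tibble::tibble(image_id = paste0("img", 1:20),
                             dab_count = rep(100, 20))
  noisy <- simulate_observer_counts(truth100, observer_sim_params(
    n_observers = 1, miscount_dispersion = 10, seed = 3))
  expect_lt(abs(mean(noisy$dab_count) - 100), 7)

  expect_error(simulate_observer_counts(truth[0, ], observer_sim_params()),
               "nonempty")
})
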