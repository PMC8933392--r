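make_typed_table <- function(...) {
  defaults <- list(cytokeratin = 3, LaminB1 = 1, cleaved_caspase3 = 1,
                   pH2Ax = 1, p16 = 1, p_RB = 1, PCNA = 1)
  vals <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(c(list(cell_id = "c1", sample_id = "s1"), vals))
}

test_that("typing applies the strict threshold rules per cell", {
  # cytokeratin above/at/below the 2.5 tumor rule
  expect_true(type_cells(make_typed_table(cytokeratin = 3.0))$is_tumor)
  expect_false(type_cells(make_typed_table(cytokeratin = 2.5))$is_tumor)
  expect_false(type_cells(make_typed_table(cytokeratin = 2.0))$is_tumor)

  # tumor cell with pH2Ax above 2.9 is pH2Ax positive
  typed <- type_cells(make_typed_table(pH2Ax = 3.5))
  expect_true(typed$pH2Ax_positive)
  expect_false(typed$p16_positive)

  # marker flags of non-tumor cells are NA
  nontumor <- type_cells(make_typed_table(cytokeratin = 1, pH2Ax = 3.5))
  expect_true(is.na(nontumor$pH2Ax_positive))

  # the full default rule set, one marker at a time
  rules <- typing_rules()
  for (m in names(rules$marker_rules)) {
    th <- rules$marker_rules[[m]]
    args_hi <- stats::setNames(list(th + 0.1), m)
    args_at <- stats::setNames(list(th), m)
    expect_true(do.call(make_typed_table, args_hi) |>
                  type_cells() |> dplyr::pull(paste0(m, "_positive")))
    expect_false(do.call(make_typed_table, args_at) |>
                   type_cells() |> dplyr::pull(paste0(m, "_positive")))
  }

  expect_error(type_cells(make_typed_table()[, -3]), "cytokeratin")
})

test_that("conjunctive Lamin B1 mode requires cleaved caspase-3 as well", {
  tb <- make_typed_table(LaminB1 = 3.5, cleaved_caspase3 = 1.0)
  expect_true(type_cells(tb)$LaminB1_positive)
  expect_false(type_cells(tb, typing_rules(laminb1_requires_caspase3 = TRUE))$LaminB1_positive)
  tb2 <- make_typed_table(LaminB1 = 3.5, cleaved_caspase3 = 2.0)
  expect_true(type_cells(tb2, typing_rules(laminb1_requires_caspase3 = TRUE))$LaminB1_positive)
})

test_that("typing is deterministic, row-order equivariant, and threshold-monotone", {
  p <- cycif_sim_params(markers = typing_marker_panel(), n_cells_per_sample = 500,
                        seed = 31)
  sim <- simulate_intensity_table(p)
  norm <- normalize_intensities(sim$table)
  typed <- type_cells(norm)

  perm <- withr::with_seed(2, sample(nrow(norm$table)))
  typed_perm <- type_cells(norm$table[perm, ])
  expect_equal(typed_perm, typed[perm, ])

  # raising the p16 threshold never increases the p16-positive fraction
  sweep <- seq(2.0, 4.0, by = 0.5)
  fracs <- vapply(sweep, function(th) {
    rules <- typing_rules(marker_rules = c(p16 = th))
    mean(type_cells(norm, rules)$p16_positive, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fracs) <= 0))
})

test_that("typing reproduces planted labels at >= 95% accuracy at 5-sigma separation", {
  p <- cycif_sim_params(markers = typing_marker_panel(sd = 0.1),
                        n_cells_per_sample = 2000, seed = 17)
  sim <- simulate_intensity_table(p)
  typed <- type_cells(normalize_intensities(sim$table))
  labels <- tidyr::pivot_wider(sim$labels, names_from = "marker",
                               values_from = "positive")
  expect_gt(mean(typed$is_tumor == labels$cytokeratin), 0.95)
  tumor <- typed$is_tumor & labels$cytokeratin
  for (m in c("LaminB1", "p16", "PCNA", "pH2Ax")) {
    acc <- mean(typed[[paste0(m, "_positive")]][tumor] == labels[[m]][tumor])
    expect_gt(acc, 0.95)
  }
})

test_that("condition summaries aggregate per section and compare conditions", {
  # hand-built typed table: 3 sections, fractions 0.1/0.2/0.3 for one marker
  typed <- purrr::map_dfr(1:3, function(s) {
    n_pos <- s; n <- 10
    tibble::tibble(cell_id = sprintf("s%d_c%d", s, 1:n),
                   sample_id = sprintf("smp%d", s), is_tumor = TRUE,
                   p16_positive = c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
  })
  meta <- tibble::tibble(sample_id = sprintf("smp%d", 1:3),
                         section_id = sprintf("sec%d", 1:3),
                         condition = "control")
  summ <- summarize_by_condition(typed, meta)
  expect_equal(summ$condition_stats$mean_fraction, 0.2)
  expect_equal(summ$condition_stats$sd_fraction, 0.1)
  expect_equal(nrow(summ$comparisons), 0)

  # two identical conditions: t = 0, p = 1
  typed2 <- dplyr::bind_rows(
    typed,
    dplyr::mutate(typed, cell_id = paste0("b_", cell_id),
                  sample_id = paste0("b_", sample_id)))
  meta2 <- dplyr::bind_rows(
    meta,
    dplyr::mutate(meta, sample_id = paste0("b_", sample_id),
                  section_id = paste0("b_", section_id),
                  condition = "treated"))
  summ2 <- summarize_by_condition(typed2, meta2)
  expect_equal(summ2$comparisons$t_statistic, 0)
  expect_equal(summ2$comparisons$p_value, 1)

  # planted 0.2 vs 0.6 difference over 4 sections/arm is detected at p < 0.01
  make_arm <- function(frac, arm, n_sections = 4, n_cells = 400, seed = 1) {
    withr::with_seed(seed, purrr::map_dfr(seq_len(n_sections), function(s) {
      frac_s <- min(1, max(0, frac + rnorm(1, 0, 0.02)))
      tibble::tibble(
        cell_id = sprintf("%s%d_c%d", arm, s, seq_len(n_cells)),
        sample_id = sprintf("%s_smp%d", arm, s), is_tumor = TRUE,
        p16_positive = runif(n_cells) < frac_s)
    }))
  }
  typed3 <- dplyr::bind_rows(make_arm(0.2, "lo", seed = 5),
                             make_arm(0.6, "hi", seed = 6))
  meta3 <- tibble::tibble(
    sample_id = unique(typed3$sample_id),
    section_id = unique(typed3$sample_id),
    condition = rep(c("lo", "hi"), each = 4))
  summ3 <- summarize_by_condition(typed3, meta3)
  expect_lt(summ3$comparisons$p_value, 0.01)

  # a condition with < 2 sections is flagged not computable
  summ4 <- summarize_by_condition(
    dplyr::bind_rows(typed, dplyr::mutate(typed[1:10, ],
                                          sample_id = "solo",
                                          cell_id = paste0("x", 1:10))),
    dplyr::bind_rows(meta, tibble::tibble(sample_id = "solo",
                                          section_id = "solo",
                                          condition = "single")))
  expect_false(all(summ4$comparisons$computable))

  expect_error(summarize_by_condition(typed, meta[-1, ]), "unmapped")
})
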