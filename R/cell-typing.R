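#' Rule set for single-cell phenotyping
#'
#' Tumor cells are identified by cytokeratin expression above 2.5 on the
#' normalized (log10-aligned) scale; tumor cells are then flagged positive
#' for each functional marker whose normalized value strictly exceeds its
#' threshold: Lamin B1 > 3.3, cleaved caspase-3 > 1.9, pH2Ax > 2.9,
#' p16 > 2.8, p-RB > 2.7, PCNA > 3.3. The Lamin B1 and cleaved caspase-3
#' rules are independent by default; `laminb1_requires_caspase3 = TRUE`
#' gives the conjunctive reading (Lamin B1 positive only when both exceed
#' their thresholds) for sensitivity analysis.
#'
#' @param tumor_marker,tumor_threshold The tumor-identity rule.
#' @param marker_rules Named numeric vector of per-marker thresholds.
#' @param laminb1_requires_caspase3 Conjunctive Lamin B1 rule (off by
#'   default).
#' @return A list of class `typing_rules`.
#' @export
typing_rules <- function(tumor_marker = "cytokeratin",
                         tumor_threshold = 2.5,
                         marker_rules = c(LaminB1 = 3.3,
                                          cleaved_caspase3 = 1.9,
                                          pH2Ax = 2.9,
                                          p16 = 2.8,
                                          p_RB = 2.7,
                                          PCNA = 3.3),
                         laminb1_requires_caspase3 = FALSE) {
  if (tumor_threshold <= 0 || any(marker_rules <= 0)) {
    rlang::abort("thresholds must be > 0")
  }
  if (is.null(names(marker_rules)) || any(names(marker_rules) == "")) {
    rlang::abort("`marker_rules` must be a named vector")
  }
  structure(list(tumor_marker = tumor_marker, tumor_threshold = tumor_threshold,
                 marker_rules = marker_rules,
                 laminb1_requires_caspase3 = isTRUE(laminb1_requires_caspase3)),
            class = "typing_rules")
}

#' Type cells by thresholding normalized intensities
#'
#' Applies the rule set per cell: `is_tumor` iff the tumor marker strictly
#' exceeds its threshold; for tumor cells each rule marker is flagged iff
#' its value strictly exceeds the rule threshold; marker flags of
#' non-tumor cells are `NA` (not meaningful).
#'
#' @param table A normalized intensity tibble (`cell_id`, `sample_id`,
#'   marker columns) or a `cycif_norm` object.
#' @param rules A [typing_rules()] object.
#' @return A tibble: `cell_id`, `sample_id`, `is_tumor`, one
#'   `<marker>_positive` logical column per rule marker.
#' @examples
#' tb <- tibble::tibble(cell_id = "c1", sample_id = "s1", cytokeratin = 3,
#'                      LaminB1 = 3.5, cleaved_caspase3 = 1, pH2Ax = 3,
#'                      p16 = 1, p_RB = 3, PCNA = 2)
#' type_cells(tb)
#' @export
type_cells <- function(table, rules = typing_rules()) {
  if (inherits(table, "cycif_norm")) table <- table$table
  table <- tibble::as_tibble(table)
  needed <- c(rules$tumor_marker, names(rules$marker_rules))
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing marker column(s): ", paste(missing, collapse = ", ")))
  }
  is_tumor <- table[[rules$tumor_marker]] > rules$tumor_threshold
  out <- tibble::tibble(cell_id = table$cell_id, sample_id = table$sample_id,
                        is_tumor = is_tumor)
  for (m in names(rules$marker_rules)) {
    flag <- table[[m]] > rules$marker_rules[[m]]
    flag[!is_tumor] <- NA
    out[[paste0(m, "_positive")]] <- flag
  }
  if (rules$laminb1_requires_caspase3 &&
      all(c("LaminB1_positive", "cleaved_caspase3_positive") %in% names(out))) {
    out$LaminB1_positive <- out$LaminB1_positive & out$cleaved_caspase3_positive
  }
  out
}

#' Summarize marker-positive tumor fractions by condition
#'
#' Per section, the fraction of tumor cells positive for each marker; per
#' condition, the mean and sample SD of those fractions across sections,
#' with pairwise two-sided unpaired t-tests between conditions (Student's
#' equal-variance by default, Welch by flag). Conditions with fewer than
#' two sections are flagged not-computable in the comparisons.
#'
#' @param typed Output of [type_cells()].
#' @param metadata Tibble mapping `sample_id` to `section_id` and
#'   `condition`; every cell's sample must appear.
#' @param welch Use Welch's t-test instead of Student's.
#' @return An object of class `condition_summary`: `section_fractions`
#'   (section x marker tibble), `condition_stats` (mean, sd, n per
#'   condition and marker), `comparisons` (pairwise t-tests). `tidy()`
#'   returns `condition_stats`.
#' @export
summarize_by_condition <- function(typed, metadata, welch = FALSE) {
  metadata <- tibble::as_tibble(metadata)
  need <- c("sample_id", "section_id", "condition")
  missing <- setdiff(need, names(metadata))
  if (length(missing) > 0) {
    rlang::abort(paste0("metadata lacks column(s): ", paste(missing, collapse = ", ")))
  }
  unmapped <- setdiff(unique(typed$sample_id), metadata$sample_id)
  if (length(unmapped) > 0) {
    rlang::abort(paste0("cells from unmapped sample(s): ",
                        paste(unmapped, collapse = ", ")))
  }
  marker_cols <- grep("_positive$", names(typed), value = TRUE)
  joined <- dplyr::left_join(typed, metadata, by = "sample_id")

  section_fractions <- joined |>
    dplyr::filter(.data$is_tumor) |>
    dplyr::group_by(.data$condition, .data$section_id) |>
    dplyr::summarise(
      n_tumor_cells = dplyr::n(),
      dplyr::across(dplyr::all_of(marker_cols), ~ mean(.x, na.rm = TRUE),
                    .names = "{.col}"),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(marker_cols), names_to = "marker",
                        values_to = "fraction_positive") |>
    dplyr::mutate(marker = sub("_positive$", "", .data$marker))

  condition_stats <- section_fractions |>
    dplyr::group_by(.data$condition, .data$marker) |>
    dplyr::summarise(
      mean_fraction = mean(.data$fraction_positive),
      sd_fraction = if (dplyr::n() > 1) stats::sd(.data$fraction_positive) else NA_real_,
      n_sections = dplyr::n(),
      n_tumor_cells = sum(.data$n_tumor_cells),
      .groups = "drop"
    )

  conditions <- unique(section_fractions$condition)
  pairs <- if (length(conditions) >= 2) {
    utils::combn(as.character(conditions), 2, simplify = FALSE)
  } else list()
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(unique(section_fractions$marker), function(m) {
      a <- section_fractions$fraction_positive[
        section_fractions$condition == pr[1] & section_fractions$marker == m]
      b <- section_fractions$fraction_positive[
        section_fractions$condition == pr[2] & section_fractions$marker == m]
      computable <- length(a) >= 2 && length(b) >= 2
      if (!computable) {
        return(tibble::tibble(marker = m, condition_a = pr[1], condition_b = pr[2],
                              t_statistic = NA_real_, p_value = NA_real_,
                              computable = FALSE))
      }
      tt <- tryCatch(
        stats::t.test(a, b, var.equal = !welch, alternative = "two.sided"),
        error = function(e) NULL
      )
      if (is.null(tt)) {
        # zero pooled variance: identical groups give t = 0, p = 1;
        # constant but different groups are off-scale significant
        if (isTRUE(all.equal(mean(a), mean(b)))) {
          return(tibble::tibble(marker = m, condition_a = pr[1],
                                condition_b = pr[2], t_statistic = 0,
                                p_value = 1, computable = TRUE))
        }
        return(tibble::tibble(marker = m, condition_a = pr[1],
                              condition_b = pr[2],
                              t_statistic = sign(mean(a) - mean(b)) * Inf,
                              p_value = 0, computable = TRUE))
      }
      tibble::tibble(marker = m, condition_a = pr[1], condition_b = pr[2],
                     t_statistic = unname(tt$statistic), p_value = tt$p.value,
                     computable = TRUE)
    })
  })

  structure(list(section_fractions = section_fractions,
                 condition_stats = condition_stats,
                 comparisons = comparisons),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$condition_stats)
  if (nrow(x$comparisons) > 0) print(x$comparisons)
  invisible(x)
}
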