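#' Configuration for DAB-IHC cell scoring
#'
#' Thresholds are in optical-density units. The hematoxylin threshold
#' defines the denominator cell population (a uniform 0.3 across all
#' samples); the DAB threshold calls positivity, with 0.3 the calibrated
#' default. Positivity uses strict `>`: a compartment exactly at the
#' threshold falls negative.
#'
#' @param hema_threshold Hematoxylin OD threshold for nucleus detection
#'   (default 0.3).
#' @param dab_threshold DAB OD threshold for positivity (default 0.3).
#' @param min_nucleus_area_px Minimum nucleus area in pixels after opening.
#' @param annulus_width_px Width of the cytoplasmic annulus measured around
#'   each nucleus.
#' @param background_rgb Per-channel unstained background level.
#' @param stain_vectors Stain basis from [hdab_stain_vectors()].
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(hema_threshold = 0.3,
                           dab_threshold = 0.3,
                           min_nucleus_area_px = 20,
                           annulus_width_px = 3,
                           background_rgb = c(255, 255, 255),
                           stain_vectors = hdab_stain_vectors()) {
  if (hema_threshold <= 0 || dab_threshold <= 0) {
    rlang::abort("thresholds must be > 0")
  }
  if (min_nucleus_area_px < 1 || annulus_width_px < 0) {
    rlang::abort("need min_nucleus_area_px >= 1 and annulus_width_px >= 0")
  }
  structure(list(hema_threshold = hema_threshold, dab_threshold = dab_threshold,
                 min_nucleus_area_px = min_nucleus_area_px,
                 annulus_width_px = annulus_width_px,
                 background_rgb = background_rgb,
                 stain_vectors = stain_vectors),
            class = "scoring_config")
}

#' Detect cells on deconvolved stain maps and call DAB positivity
#'
#' Nuclei are connected components of `hema_map > hema_threshold` after a
#' 3x3 morphological opening, filtered by minimum area. Per nucleus the
#' mean DAB OD is measured over the nucleus and over a cytoplasmic annulus
#' (Euclidean dilation by `annulus_width_px`, excluding all nuclei); a cell
#' is DAB positive if either compartment mean exceeds `dab_threshold`
#' (strict), i.e. staining above background in nucleus or cytoplasm.
#'
#' @param hema_map,dab_map Same-shape numeric matrices of per-pixel stain
#'   concentrations (OD units) from [deconvolve_stains()].
#' @param config A [scoring_config()].
#' @return A tibble with one row per detected cell: `cell_id`, `row`,
#'   `col` (centroid), `nucleus_area_px`, `nucleus_mean_hema_od`,
#'   `nucleus_mean_dab_od`, `cytoplasm_mean_dab_od`, `dab_positive`.
#'   An image with no detectable nuclei gives zero rows, not an error.
#' @export
detect_cells <- function(hema_map, dab_map, config = scoring_config()) {
  if (!all(dim(hema_map) == dim(dab_map))) {
    rlang::abort("`hema_map` and `dab_map` must have the same shape")
  }
  empty <- tibble::tibble(
    cell_id = integer(0), row = numeric(0), col = numeric(0),
    nucleus_area_px = integer(0), nucleus_mean_hema_od = numeric(0),
    nucleus_mean_dab_od = numeric(0), cytoplasm_mean_dab_od = numeric(0),
    dab_positive = logical(0)
  )
  mask <- open3(hema_map > config$hema_threshold)
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= config$min_nucleus_area_px)
  if (length(keep) == 0) return(empty)

  nr <- nrow(lab)
  pix <- which(lab > 0L)
  pix_lab <- lab[pix]
  pix_row <- ((pix - 1L) %% nr) + 1L
  pix_col <- ((pix - 1L) %/% nr) + 1L
  w <- config$annulus_width_px

  rows <- purrr::map(seq_along(keep), function(i) {
    id <- keep[i]
    sel <- pix_lab == id
    pr <- pix_row[sel]; pc <- pix_col[sel]; pidx <- pix[sel]
    # annulus: Euclidean dilation of this nucleus within an expanded
    # bounding box, minus every nucleus pixel
    r0 <- max(1, min(pr) - w); r1 <- min(nrow(lab), max(pr) + w)
    c0 <- max(1, min(pc) - w); c1 <- min(ncol(lab), max(pc) + w)
    sub_lab <- lab[r0:r1, c0:c1, drop = FALSE]
    sub_self <- sub_lab == id
    ann <- dilate_disk(sub_self, w) & sub_lab == 0L
    cyto_mean <- if (any(ann)) {
      mean(dab_map[r0:r1, c0:c1, drop = FALSE][ann])
    } else 0
    nuc_dab <- mean(dab_map[pidx])
    tibble::tibble(
      cell_id = i,
      row = mean(pr), col = mean(pc),
      nucleus_area_px = length(pidx),
      nucleus_mean_hema_od = mean(hema_map[pidx]),
      nucleus_mean_dab_od = nuc_dab,
      cytoplasm_mean_dab_od = cyto_mean,
      dab_positive = nuc_dab > config$dab_threshold ||
        cyto_mean > config$dab_threshold
    )
  })
  dplyr::bind_rows(rows)
}

#' Score one brightfield ROI image
#'
#' Convenience wrapper running OD conversion, H-DAB deconvolution and
#' [detect_cells()] on one image.
#'
#' @param image A [stained_image()] or RGB array.
#' @param config A [scoring_config()].
#' @return The [detect_cells()] tibble.
#' @export
score_image <- function(image, config = scoring_config()) {
  od <- rgb_to_od(image, config$background_rgb)
  maps <- deconvolve_stains(od, config$stain_vectors)
  detect_cells(maps$hema, maps$dab, config)
}

#' Percent-positive statistic
#'
#' `100 * n_dab / n_hema`: DAB-positive cells over hematoxylin-positive
#' cells within one ROI.
#'
#' @param n_dab,n_hema Nonnegative counts with `n_dab <= n_hema`,
#'   `n_hema > 0`.
#' @return The percentage (0-100).
#' @examples
#' percent_positive(25, 100) # 25
#' @export
percent_positive <- function(n_dab, n_hema) {
  if (any(n_hema == 0)) {
    rlang::abort("percent positive is undefined when no hematoxylin-positive cells were found",
                 class = "ihcgate_undefined_score")
  }
  if (any(n_dab < 0 | n_hema < 0)) rlang::abort("counts must be nonnegative")
  if (any(n_dab > n_hema)) {
    rlang::abort("DAB-positive count cannot exceed the hematoxylin-positive count")
  }
  100 * n_dab / n_hema
}

#' Aggregate per-ROI percent-positive values into a section score
#'
#' Section-level summary is the mean and sample standard deviation
#' (n - 1 denominator) over the ROI percentages; a single ROI reports
#' SD 0 with `sd_defined = FALSE`.
#'
#' @param percents Numeric vector of per-ROI percent-positive values.
#' @return A one-row tibble: `n_rois`, `mean_percent_positive`,
#'   `sd_percent_positive`, `sd_defined`.
#' @export
aggregate_roi_percents <- function(percents) {
  percents <- percents[!is.na(percents)]
  if (length(percents) == 0) rlang::abort("no ROI percentages to aggregate")
  tibble::tibble(
    n_rois = length(percents),
    mean_percent_positive = mean(percents),
    sd_percent_positive = if (length(percents) > 1) stats::sd(percents) else 0,
    sd_defined = length(percents) > 1
  )
}

#' Score a tumor section from its ROI images
#'
#' Runs the full per-ROI pipeline (OD conversion, deconvolution, detection,
#' percent positive) and aggregates to the section-level mean +/- SD over
#' ROIs. Sections are conventionally three ROIs; a different count warns
#' but proceeds. A ROI with zero hematoxylin-positive cells is flagged,
#' excluded from the aggregate, and reported with a warning.
#'
#' @param rois A list of [stained_image()] objects (or RGB arrays), one per
#'   ROI.
#' @param config A [scoring_config()].
#' @param section_id Optional identifier carried into the result.
#' @return An object of class `section_score`: list with `roi_scores`
#'   (tibble: `roi_id`, `n_hema_cells`, `n_dab_cells`, `percent_positive`,
#'   `flagged`), `summary` (the [aggregate_roi_percents()] row), and
#'   `section_id`. `tidy()` returns the ROI table, `glance()` the summary.
#' @export
score_section <- function(rois, config = scoring_config(),
                          section_id = NA_character_) {
  if (inherits(rois, "stained_image")) rois <- list(rois)
  if (length(rois) < 1) rlang::abort("need at least one ROI image")
  if (length(rois) != 3) {
    rlang::warn(sprintf("expected 3 ROIs per section, got %d", length(rois)))
  }
  roi_scores <- purrr::map_dfr(seq_along(rois), function(i) {
    img <- rois[[i]]
    roi_id <- if (inherits(img, "stained_image") && !is.na(img$roi_id)) {
      img$roi_id
    } else sprintf("roi%d", i)
    cells <- score_image(img, config)
    n_hema <- nrow(cells)
    n_dab <- sum(cells$dab_positive)
    tibble::tibble(
      roi_id = roi_id, n_hema_cells = n_hema, n_dab_cells = n_dab,
      percent_positive = if (n_hema > 0) percent_positive(n_dab, n_hema) else NA_real_,
      flagged = n_hema == 0
    )
  })
  if (any(roi_scores$flagged)) {
    rlang::warn(sprintf(
      "%d ROI(s) had zero hematoxylin-positive cells and were excluded from the section mean",
      sum(roi_scores$flagged)))
  }
  usable <- roi_scores$percent_positive[!roi_scores$flagged]
  if (length(usable) == 0) {
    rlang::abort("no ROI produced a defined percent-positive value",
                 class = "ihcgate_undefined_score")
  }
  structure(
    list(roi_scores = roi_scores, summary = aggregate_roi_percents(usable),
         section_id = section_id),
    class = "section_score"
  )
}

#' @export
print.section_score <- function(x, ...) {
  cat(sprintf("<section_score> %s: %.1f%% +/- %.1f%% positive over %d ROI(s)\n",
              x$section_id, x$summary$mean_percent_positive,
              x$summary$sd_percent_positive, x$summary$n_rois))
  print(x$roi_scores)
  invisible(x)
}
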