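#' Parameters for the synthetic H-DAB tissue-field generator
#'
#' Describes one simulated brightfield field: hematoxylin-stained nuclei are
#' non-overlapping disks; a controllable fraction of cells carries DAB
#' chromogen in the nucleus or in a cytoplasmic ring. Optical densities are
#' composed additively (Beer-Lambert) from the H-DAB stain vectors, noise is
#' added in OD space, and the result is quantized to 8-bit RGB against a
#' white (255) background.
#'
#' Defaults define the generator's stated world: a 512 x 512 field holding
#' 200 nuclei of radius 5 +/- 1 px with an 8 px minimum inter-nucleus gap
#' (so detection annuli never touch a neighbor), hematoxylin OD 0.7 and DAB
#' OD 0.6 (both comfortably above the 0.3 calling thresholds), OD noise sd
#' 0.01, and fully nuclear DAB.
#'
#' @param n_cells Number of nuclei to place (>= 0).
#' @param true_positive_fraction Fraction of cells carrying DAB, in `[0, 1]`.
#' @param nucleus_radius_px Length-2 `(mean, sd)` of the nucleus radius in px.
#' @param field_size_px Length-2 `(height, width)` of the field in px.
#' @param hema_od_level Hematoxylin OD inside every nucleus (>= 0).
#' @param dab_od_level DAB OD in the stained compartment of positive cells.
#' @param background_noise_sd Gaussian noise sd added per channel in OD space.
#' @param cytoplasm_dab_fraction Fraction of positive cells whose DAB sits in
#'   a cytoplasmic ring only (no nuclear DAB).
#' @param cytoplasm_width_px Width of the cytoplasmic ring in px.
#' @param min_gap_px Minimum edge-to-edge gap between nuclei in px.
#' @param exact_assignment If `TRUE` (default) exactly
#'   `round(true_positive_fraction * n_cells)` cells are positive, making the
#'   image-level ground truth noiseless; `FALSE` draws i.i.d. Bernoulli flags.
#' @param max_tries Placement attempts per nucleus before giving up.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A list of class `ihc_sim_params`.
#' @export
ihc_sim_params <- function(n_cells = 200,
                           true_positive_fraction = 0.3,
                           nucleus_radius_px = c(5, 1),
                           field_size_px = c(512, 512),
                           hema_od_level = 0.7,
                           dab_od_level = 0.6,
                           background_noise_sd = 0.01,
                           cytoplasm_dab_fraction = 0,
                           cytoplasm_width_px = 3,
                           min_gap_px = 8,
                           exact_assignment = TRUE,
                           max_tries = 2000,
                           seed = 1L) {
  p <- list(n_cells = n_cells, true_positive_fraction = true_positive_fraction,
            nucleus_radius_px = nucleus_radius_px, field_size_px = field_size_px,
            hema_od_level = hema_od_level, dab_od_level = dab_od_level,
            background_noise_sd = background_noise_sd,
            cytoplasm_dab_fraction = cytoplasm_dab_fraction,
            cytoplasm_width_px = cytoplasm_width_px, min_gap_px = min_gap_px,
            exact_assignment = isTRUE(exact_assignment),
            max_tries = max_tries, seed = as.integer(seed))
  validate_ihc_sim_params(p)
  structure(p, class = "ihc_sim_params")
}

validate_ihc_sim_params <- function(p) {
  ok <- p$n_cells >= 0 &&
    p$true_positive_fraction >= 0 && p$true_positive_fraction <= 1 &&
    p$cytoplasm_dab_fraction >= 0 && p$cytoplasm_dab_fraction <= 1 &&
    p$hema_od_level >= 0 && p$dab_od_level >= 0 &&
    p$background_noise_sd >= 0 &&
    length(p$field_size_px) == 2 && all(p$field_size_px >= 1) &&
    length(p$nucleus_radius_px) == 2 && p$nucleus_radius_px[1] > 0
  if (!ok) rlang::abort("invalid `ihc_sim_params`: fractions must lie in [0,1] and sizes/levels must be nonnegative")
  invisible(p)
}

#' Simulate a stained H-DAB tissue field with known ground truth
#'
#' Places non-overlapping nuclei, assigns DAB to cells per
#' `true_positive_fraction` (nuclear, or cytoplasmic-ring for the
#' `cytoplasm_dab_fraction` share of positives), composes the optical
#' density image as `hema_conc * v_hema + dab_conc * v_dab + noise`, and
#' converts OD to 8-bit RGB through the Beer-Lambert inverse.
#'
#' @param params An [ihc_sim_params()] object.
#' @param vectors Stain vectors used for composition (default H-DAB).
#' @return A list with `image` (a [stained_image()]) and `ground_truth`
#'   (tibble: `cell_id`, `row`, `col`, `radius_px`, `dab_positive`,
#'   `dab_compartment` in `none|nucleus|cytoplasm`).
#' @examples
#' sim <- simulate_ihc_image(ihc_sim_params(n_cells = 20, seed = 1))
#' sum(sim$ground_truth$dab_positive)
#' @export
simulate_ihc_image <- function(params = ihc_sim_params(),
                               vectors = hdab_stain_vectors()) {
  validate_ihc_sim_params(params)
  p <- params
  h <- p$field_size_px[1]; w <- p$field_size_px[2]

  withr::with_seed(p$seed, {
    placement <- place_nuclei(p$n_cells, h, w, p$nucleus_radius_px,
                              p$min_gap_px, p$cytoplasm_width_px, p$max_tries)
    flags <- assign_positivity(p$n_cells, p$true_positive_fraction,
                               p$cytoplasm_dab_fraction, p$exact_assignment)
    hema_map <- matrix(0, h, w)
    dab_map <- matrix(0, h, w)
    if (p$n_cells > 0) {
      for (i in seq_len(p$n_cells)) {
        disk <- disk_pixels(placement$row[i], placement$col[i],
                            placement$radius[i], h, w)
        hema_map[disk] <- p$hema_od_level
        if (flags$compartment[i] == "nucleus") {
          dab_map[disk] <- p$dab_od_level
        } else if (flags$compartment[i] == "cytoplasm") {
          ring <- ring_pixels(placement$row[i], placement$col[i],
                              placement$radius[i],
                              placement$radius[i] + p$cytoplasm_width_px, h, w)
          dab_map[ring] <- p$dab_od_level
        }
      }
    }
    od <- array(0, dim = c(h, w, 3))
    for (c in 1:3) {
      od[, , c] <- hema_map * vectors$hema[c] + dab_map * vectors$dab[c]
      if (p$background_noise_sd > 0) {
        od[, , c] <- od[, , c] + stats::rnorm(h * w, 0, p$background_noise_sd)
      }
    }
    od[od < 0] <- 0
    rgb <- od_to_rgb(od)
  })

  gt <- tibble::tibble(
    cell_id = seq_len(p$n_cells),
    row = placement$row, col = placement$col, radius_px = placement$radius,
    dab_positive = flags$positive, dab_compartment = flags$compartment
  )
  list(image = stained_image(rgb), ground_truth = gt)
}

# rejection-sample non-overlapping disk centers; error after bounded retries
place_nuclei <- function(n, h, w, radius_px, min_gap, margin_extra, max_tries) {
  if (n == 0) {
    return(list(row = numeric(0), col = numeric(0), radius = numeric(0)))
  }
  radius <- pmax(2, stats::rnorm(n, radius_px[1], radius_px[2]))
  margin <- radius + margin_extra + 1
  if (any(2 * margin >= h) || any(2 * margin >= w)) {
    rlang::abort("field too small for the requested nucleus radii")
  }
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, margin[i], h - margin[i])
      c <- stats::runif(1, margin[i], w - margin[i])
      if (i == 1) { ok <- TRUE } else {
        j <- seq_len(i - 1)
        d2 <- (rows[j] - r)^2 + (cols[j] - c)^2
        ok <- all(d2 > (radius[j] + radius[i] + min_gap)^2)
      }
      if (ok) { rows[i] <- r; cols[i] <- c; placed <- TRUE; break }
    }
    if (!placed) {
      rlang::abort(sprintf(
        "could not place nucleus %d of %d after %d tries; enlarge the field or reduce n_cells",
        i, n, max_tries))
    }
  }
  list(row = rows, col = cols, radius = radius)
}

assign_positivity <- function(n, fraction, cyto_fraction, exact) {
  if (n == 0) {
    return(list(positive = logical(0), compartment = character(0)))
  }
  if (exact) {
    k <- round(fraction * n)
    positive <- rep(FALSE, n)
    if (k > 0) positive[sample.int(n, k)] <- TRUE
  } else {
    positive <- stats::runif(n) < fraction
  }
  compartment <- rep("none", n)
  pos_idx <- which(positive)
  if (length(pos_idx) > 0) {
    k_cyto <- round(cyto_fraction * length(pos_idx))
    cyto_idx <- if (k_cyto > 0) sample(pos_idx, k_cyto) else integer(0)
    compartment[pos_idx] <- "nucleus"
    compartment[cyto_idx] <- "cytoplasm"
  }
  list(positive = positive, compartment = compartment)
}

# linear indices of disk r <= radius around (row, col), clipped to the field
disk_pixels <- function(row, col, radius, h, w) {
  r0 <- max(1, floor(row - radius)); r1 <- min(h, ceiling(row + radius))
  c0 <- max(1, floor(col - radius)); c1 <- min(w, ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  (cc[inside[, 2]] - 1) * h + rr[inside[, 1]]
}

# linear indices of annulus r_in < d <= r_out
ring_pixels <- function(row, col, r_in, r_out, h, w) {
  r0 <- max(1, floor(row - r_out)); r1 <- min(h, ceiling(row + r_out))
  c0 <- max(1, floor(col - r_out)); c1 <- min(w, ceiling(col + r_out))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  inside <- which(d2 > r_in^2 & d2 <= r_out^2, arr.ind = TRUE)
  (cc[inside[, 2]] - 1) * h + rr[inside[, 1]]
}
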