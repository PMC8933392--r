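#' H-DAB stain vectors for color deconvolution
#'
#' Optical-density unit vectors for hematoxylin and DAB in RGB-OD space,
#' plus a residual vector completing an invertible basis. Defaults are the
#' standard published H-DAB pair; the residual is the normalized cross
#' product of the two stain vectors.
#'
#' @param hema,dab Numeric length-3 OD vectors (need not be unit length;
#'   they are normalized here).
#' @return An object of class `stain_vectors`: a list with unit vectors
#'   `hema`, `dab`, `residual` and the 3x3 stain `matrix` (stains in
#'   columns, RGB in rows).
#' @examples
#' sv <- hdab_stain_vectors()
#' colSums(sv$matrix^2) # all 1
#' @export
hdab_stain_vectors <- function(hema = c(0.650, 0.704, 0.286),
                               dab = c(0.269, 0.568, 0.778)) {
  stopifnot(length(hema) == 3, length(dab) == 3)
  unitize <- function(v) v / sqrt(sum(v^2))
  h <- unitize(hema)
  d <- unitize(dab)
  res <- unitize(c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  ))
  m <- cbind(hema = h, dab = d, residual = res)
  if (abs(det(m)) < 1e-8) {
    rlang::abort("stain vectors are collinear; deconvolution matrix is singular")
  }
  structure(list(hema = h, dab = d, residual = res, matrix = m),
            class = "stain_vectors")
}

#' Convert an RGB brightfield image to optical density
#'
#' Beer-Lambert conversion: `OD_c = -log10(max(pixel_c, 1) / background_c)`,
#' clipped below at zero. Stain amounts combine additively in OD space, so
#' this is the preprocessing step for color deconvolution.
#'
#' @param image A `stained_image` or an H x W x 3 numeric array with channel
#'   values in `[0, 255]`.
#' @param background_rgb Per-channel background (unstained) level, each > 0.
#' @return An H x W x 3 array of nonnegative optical densities.
#' @examples
#' px <- array(25, dim = c(1, 1, 3))
#' rgb_to_od(px, background_rgb = c(250, 250, 250)) # 1,1,1
#' @export
rgb_to_od <- function(image, background_rgb = c(255, 255, 255)) {
  rgb <- as_rgb_array(image)
  if (length(background_rgb) == 1) background_rgb <- rep(background_rgb, 3)
  if (length(background_rgb) != 3 || any(background_rgb <= 0)) {
    rlang::abort("`background_rgb` must be 3 positive per-channel values")
  }
  od <- rgb
  for (c in 1:3) {
    od[, , c] <- -log10(pmax(rgb[, , c], 1) / background_rgb[c])
  }
  od[od < 0] <- 0
  od
}

#' Convert an optical-density image back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()]: transmittance `10^-OD` times the background
#' level, rounded to 8-bit unless `quantize = FALSE`.
#'
#' @param od H x W x 3 array of optical densities.
#' @param background_rgb Per-channel background level.
#' @param quantize Round to integer 8-bit values (default `TRUE`).
#' @return H x W x 3 array of RGB values in `[0, 255]`.
#' @export
od_to_rgb <- function(od, background_rgb = c(255, 255, 255), quantize = TRUE) {
  if (length(background_rgb) == 1) background_rgb <- rep(background_rgb, 3)
  rgb <- od
  for (c in 1:3) {
    rgb[, , c] <- background_rgb[c] * 10^(-od[, , c])
  }
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  if (quantize) rgb <- round(rgb)
  rgb
}

#' Unmix an OD image into per-stain concentration maps
#'
#' Linear color deconvolution: per pixel, concentrations solve
#' `OD = M %*% conc` where `M` holds the stain OD vectors in columns.
#' Negative concentrations are clipped to zero after solving; on
#' nonnegative-concentration inputs the reconstruction
#' `M %*% conc` recovers the OD to numerical precision.
#'
#' @param od H x W x 3 optical-density array.
#' @param vectors A [hdab_stain_vectors()] object (or compatible list with a
#'   3x3 `matrix` element).
#' @param clip Clip negative concentrations to 0 (default `TRUE`).
#' @return A list of H x W matrices `hema`, `dab`, `residual`.
#' @export
deconvolve_stains <- function(od, vectors = hdab_stain_vectors(), clip = TRUE) {
  m <- vectors$matrix
  if (!is.matrix(m) || any(dim(m) != 3) ||
      !is.finite(rcond(m)) || rcond(m) < 1e-10) {
    rlang::abort("stain matrix is singular or ill-conditioned")
  }
  dims <- dim(od)
  flat <- matrix(od, ncol = 3)          # pixels x channels
  conc <- flat %*% t(solve(m))          # pixels x stains
  if (clip) conc[conc < 0] <- 0
  shape <- function(j) matrix(conc[, j], nrow = dims[1], ncol = dims[2])
  list(hema = shape(1), dab = shape(2), residual = shape(3))
}

#' @keywords internal
as_rgb_array <- function(image) {
  if (inherits(image, "stained_image")) image <- image$rgb
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    rlang::abort("expected an H x W x 3 RGB array or a `stained_image`")
  }
  if (any(image < 0 | image > 255, na.rm = TRUE)) {
    rlang::abort("RGB channel values must lie in [0, 255]")
  }
  image
}
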