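#' Construct a stained brightfield image object
#'
#' Thin container for one imaged field of view (ROI): an 8-bit RGB pixel
#' array plus identifiers used when aggregating ROIs into section scores.
#'
#' @param rgb H x W x 3 numeric array, channel values in `[0, 255]`.
#' @param microns_per_pixel Optional physical pixel size.
#' @param roi_id,section_id,sample_id Identifiers carried through scoring.
#' @return An object of class `stained_image`.
#' @export
stained_image <- function(rgb, microns_per_pixel = NULL,
                          roi_id = NA_character_, section_id = NA_character_,
                          sample_id = NA_character_) {
  rgb <- as_rgb_array(rgb)
  if (dim(rgb)[1] < 1 || dim(rgb)[2] < 1) {
    rlang::abort("image must have at least one pixel")
  }
  structure(
    list(rgb = rgb, microns_per_pixel = microns_per_pixel,
         roi_id = roi_id, section_id = section_id, sample_id = sample_id),
    class = "stained_image"
  )
}

#' @export
print.stained_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<stained_image> %d x %d px, roi=%s section=%s sample=%s\n",
              d[1], d[2], x$roi_id, x$section_id, x$sample_id))
  invisible(x)
}

#' Write a stained image as an 8-bit RGB PNG
#'
#' @param image A `stained_image` or RGB array.
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_stained_image <- function(image, path) {
  rgb <- as_rgb_array(image)
  png::writePNG(rgb / 255, target = path)
  invisible(path)
}

#' Read an 8-bit RGB PNG as a stained image
#'
#' @param path PNG file path.
#' @inheritParams stained_image
#' @return A `stained_image`.
#' @export
read_stained_image <- function(path, roi_id = NA_character_,
                               section_id = NA_character_,
                               sample_id = NA_character_) {
  if (!file.exists(path)) rlang::abort(paste0("image file not found: ", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  stained_image(round(a * 255), roi_id = roi_id,
                section_id = section_id, sample_id = sample_id)
}
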