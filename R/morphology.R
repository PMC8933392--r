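# Vectorized binary pixel operations used by cell detection. No installed R
# package provides these (EBImage-class functionality), so they are written
# here against logical matrices; all are pure and allocation-bounded.

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) == 0 || length(cs) == 0) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# binary erosion with a 3x3 square structuring element
erode3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat(mask, dr, dc, fill = FALSE)
  }
  out
}

# binary dilation with a 3x3 square structuring element
dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat(mask, dr, dc, fill = FALSE)
  }
  out
}

# morphological opening (erosion then dilation), 3x3 square
open3 <- function(mask) dilate3(erode3(mask))

# binary dilation with a Euclidean disk of the given radius (pixels)
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- ceiling(radius)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    if (dr * dr + dc * dc > radius * radius) next
    out <- out | shift_mat(mask, dr, dc, fill = FALSE)
  }
  out
}

# 8-connected component labeling by iterative minimum-label propagation.
# Returns an integer matrix: 0 = background, components numbered 1..k in
# raster order of their first pixel.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab_full <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab_full)
  lab_full[mask] <- seq_len(sum(mask))
  # propagate the minimum positive label across 8-neighborhoods until stable
  repeat {
    nb <- lab_full
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- shift_mat(lab_full, dr, dc, fill = 0L)
      take <- mask & sh > 0L & (nb == 0L | sh < nb)
      nb[take] <- sh[take]
    }
    if (all(nb == lab_full)) break
    lab_full <- nb
  }
  # renumber to consecutive 1..k
  ids <- sort(unique(lab_full[lab_full > 0L]))
  lab_full[lab_full > 0L] <- match(lab_full[lab_full > 0L], ids)
  lab_full
}
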