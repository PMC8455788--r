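# Binary morphology with the two structuring elements used throughout:
# cross3d = 3x3x3 with the 6 face neighbors + center (7 active cells),
# cross2d = 3x3 with the 4 edge neighbors + center (5 active cells, applied
# per z-plane). Outside the grid counts as background.

shift_mask <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  x1 <- max(1L, 1L + dx); x2 <- min(d[1], d[1] + dx)
  y1 <- max(1L, 1L + dy); y2 <- min(d[2], d[2] + dy)
  z1 <- max(1L, 1L + dz); z2 <- min(d[3], d[3] + dz)
  if (x1 > x2 || y1 > y2 || z1 > z2) return(out)
  out[x1:x2, y1:y2, z1:z2] <-
    m[(x1 - dx):(x2 - dx), (y1 - dy):(y2 - dy), (z1 - dz):(z2 - dz)]
  out
}

offsets6 <- cbind(
  dx = c(-1L, 1L, 0L, 0L, 0L, 0L),
  dy = c(0L, 0L, -1L, 1L, 0L, 0L),
  dz = c(0L, 0L, 0L, 0L, -1L, 1L)
)
offsets4_2d <- offsets6[1:4, , drop = FALSE]

binary_dilate <- function(m, offsets = offsets6) {
  out <- m
  for (k in seq_len(nrow(offsets))) {
    out <- out | shift_mask(m, offsets[k, 1], offsets[k, 2], offsets[k, 3])
  }
  out
}

binary_erode <- function(m, offsets = offsets6) {
  out <- m
  for (k in seq_len(nrow(offsets))) {
    out <- out & shift_mask(m, -offsets[k, 1], -offsets[k, 2], -offsets[k, 3])
  }
  out
}

# Mean over the center and its 6 face neighbors (edge-replicated); one light
# smoothing pass used when detecting watershed seeds.
smooth_mean6 <- function(x) {
  d <- dim(x)
  s <- x
  for (k in seq_len(nrow(offsets6))) {
    sh <- offsets6[k, ]
    y <- array(0, d)
    x1 <- max(1L, 1L + sh[1]); x2 <- min(d[1], d[1] + sh[1])
    y1 <- max(1L, 1L + sh[2]); y2 <- min(d[2], d[2] + sh[2])
    z1 <- max(1L, 1L + sh[3]); z2 <- min(d[3], d[3] + sh[3])
    y[x1:x2, y1:y2, z1:z2] <-
      x[(x1 - sh[1]):(x2 - sh[1]), (y1 - sh[2]):(y2 - sh[2]), (z1 - sh[3]):(z2 - sh[3])]
    s <- s + y
  }
  s / 7
}

# Bounding box of a logical array, padded and clipped to the grid.
mask_bbox <- function(m, pad = 1L) {
  d <- dim(m)
  px <- which(apply(m, 1, any))
  if (length(px) == 0L) return(NULL)
  py <- which(apply(m, 2, any))
  pz <- which(apply(m, 3, any))
  list(
    x = max(1L, min(px) - pad):min(d[1], max(px) + pad),
    y = max(1L, min(py) - pad):min(d[2], max(py) + pad),
    z = max(1L, min(pz) - pad):min(d[3], max(pz) + pad)
  )
}

# Apply fn(cropped logical mask) per positive label inside its padded
# bounding box; fn returns a logical mask on the crop. Results are painted
# into an integer array with the original label ids.
map_instances <- function(labels_arr, fn, pad = 1L) {
  out <- array(0L, dim(labels_arr))
  for (lab in sort(unique(labels_arr[labels_arr > 0L]))) {
    m <- labels_arr == lab
    bb <- mask_bbox(m, pad)
    sub <- fn(m[bb$x, bb$y, bb$z, drop = FALSE])
    if (any(sub)) {
      crop <- out[bb$x, bb$y, bb$z, drop = FALSE]
      crop[sub] <- lab
      out[bb$x, bb$y, bb$z] <- crop
    }
  }
  out
}

#' Morphological opening of each cyst instance
#'
#' Replaces every instance by its opening (erosion then dilation) with the
#' 6-connected 3x3x3 cross. Instances whose erosion is empty vanish
#' entirely. Opening is anti-extensive and idempotent, so each opened
#' instance is a subset of the original and instances never overlap; original
#' label ids are kept. Opening before [encode_erosion()] is what makes the
#' erosion codec exactly invertible (the decoder's one-voxel dilation of the
#' eroded core reproduces the opened instance).
#'
#' @param labels an `instance_map3d`.
#' @return an `instance_map3d` with each surviving instance opened.
#' @export
open_instances <- function(labels) {
  stopifnot(inherits(labels, "instance_map3d"))
  out <- map_instances(labels$data, function(m) {
    er <- binary_erode(m)
    if (!any(er)) return(er)
    binary_dilate(er)
  })
  instance_map3d(out, labels$spacing, labels$affine)
}
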