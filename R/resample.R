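# Separable resampling between the exam grid and the working grid. Output
# sample j (0-based) maps to input coordinate (j + 0.5) / scale - 0.5
# (cell-centered), so physical extent (shape x spacing) is preserved exactly
# when spacing is rescaled by n_in / n_out.

# Dense interpolation matrix (n_out x n_in); order 1 = linear, order 3 =
# cubic convolution (Keys kernel, a = -0.5); borders replicate.
interp_matrix <- function(n_in, n_out, order = 1L) {
  M <- matrix(0, n_out, n_in)
  scale <- n_out / n_in
  keys <- function(t) {
    a <- -0.5
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  for (j in seq_len(n_out)) {
    p <- (j - 0.5) / scale - 0.5  # 0-based input coordinate
    if (order == 1L) {
      i0 <- floor(p)
      w <- p - i0
      taps <- c(i0, i0 + 1)
      wts <- c(1 - w, w)
    } else {
      i0 <- floor(p)
      taps <- i0 + (-1):2
      wts <- keys(p - taps)
    }
    taps <- pmin(pmax(taps, 0), n_in - 1)  # replicate border
    for (k in seq_along(taps)) {
      M[j, taps[k] + 1] <- M[j, taps[k] + 1] + wts[k]
    }
  }
  M
}

# Apply matrix M (n_out x n_in) along one axis of a 3D array.
apply_along <- function(arr, M, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  y <- M %*% matrix(a, d[1], d[2] * d[3])
  dim(y) <- c(nrow(M), d[2], d[3])
  aperm(y, order(perm))
}

# Voxel-to-world affine after resampling one grid to another (cell-centered).
rescale_affine <- function(affine, factors) {
  S <- diag(c(1 / factors, 1))
  S[1:3, 4] <- 0.5 / factors - 0.5
  affine %*% S
}

#' Up-sample an exam to the working grid
#'
#' The MR volume is interpolated with cubic (order-3) convolution and the
#' label map label-by-label with trilinear (order-1) interpolation of each
#' instance's binary mask, thresholded at 0.5. Where two labels both exceed
#' the threshold, the larger interpolated value wins and ties go to the
#' smaller label, so instances can shrink or vanish but never appear. The
#' default target (in-plane 512, slices x3) is the working grid of the final
#' pipeline; smaller targets keep the same geometry at desk scale. Spacing is
#' rescaled so physical extent is preserved.
#'
#' @param mri a `volume3d` with a square in-plane grid.
#' @param labels an `instance_map3d` or `binary_mask3d` on the same grid.
#' @param inplane_target in-plane output size (>= input in-plane size).
#' @param z_factor integer slice multiplication factor.
#' @return list with elements `volume` and `labels` on the working grid.
#' @export
upsample_exam <- function(mri, labels, inplane_target = 512L, z_factor = 3L) {
  stopifnot(inherits(mri, "volume3d"))
  d <- dim(mri$data)
  if (d[1] != d[2]) stop("in-plane grid must be square", call. = FALSE)
  if (d[1] > inplane_target) {
    stop("in-plane size exceeds `inplane_target`", call. = FALSE)
  }
  check_same_grid(mri, labels, "mri and labels")
  out_shape <- c(inplane_target, inplane_target, d[3] * z_factor)
  factors <- out_shape / d
  new_spacing <- mri$spacing / factors
  new_affine <- rescale_affine(mri$affine, factors)

  Mx3 <- interp_matrix(d[1], out_shape[1], order = 3L)
  Mz3 <- interp_matrix(d[3], out_shape[3], order = 3L)
  vol <- apply_along(apply_along(apply_along(mri$data, Mx3, 1), Mx3, 2), Mz3, 3)
  vol_out <- volume3d(vol, new_spacing, new_affine)

  Mx1 <- interp_matrix(d[1], out_shape[1], order = 1L)
  Mz1 <- interp_matrix(d[3], out_shape[3], order = 1L)
  is_mask <- inherits(labels, "binary_mask3d")
  labs <- if (is_mask) 1L else instance_labels(labels)
  val <- array(0, out_shape)
  lab <- array(0L, out_shape)
  for (lb in labs) {
    m <- labels$data == lb
    bb <- mask_bbox(m, 2L)
    # output rows whose interpolation support intersects the padded bbox
    rx <- which(rowSums(abs(Mx1[, bb$x, drop = FALSE])) > 0 &
                rowSums(abs(Mx1[, -bb$x, drop = FALSE])) == 0)
    ry <- which(rowSums(abs(Mx1[, bb$y, drop = FALSE])) > 0 &
                rowSums(abs(Mx1[, -bb$y, drop = FALSE])) == 0)
    rz <- which(rowSums(abs(Mz1[, bb$z, drop = FALSE])) > 0 &
                rowSums(abs(Mz1[, -bb$z, drop = FALSE])) == 0)
    if (length(rx) == 0 || length(ry) == 0 || length(rz) == 0) next
    sub <- (m[bb$x, bb$y, bb$z, drop = FALSE]) * 1.0
    v <- apply_along(apply_along(apply_along(
      sub, Mx1[rx, bb$x, drop = FALSE], 1), Mx1[ry, bb$y, drop = FALSE], 2),
      Mz1[rz, bb$z, drop = FALSE], 3)
    win <- v > 0.5 & v > val[rx, ry, rz, drop = FALSE]
    if (any(win)) {
      vcrop <- val[rx, ry, rz, drop = FALSE]
      lcrop <- lab[rx, ry, rz, drop = FALSE]
      vcrop[win] <- v[win]
      lcrop[win] <- lb
      val[rx, ry, rz] <- vcrop
      lab[rx, ry, rz] <- lcrop
    }
  }
  labels_out <- if (is_mask) {
    binary_mask3d(1L * (lab > 0L), new_spacing, new_affine)
  } else {
    instance_map3d(lab, new_spacing, new_affine)
  }
  list(volume = vol_out, labels = labels_out)
}

#' Down-sample a decoded label map to the original grid
#'
#' Nearest-neighbor sampling at output voxel centers; each working-grid axis
#' must be an integer multiple of the original axis. Spacing (and physical
#' extent) is restored.
#'
#' @param labels an `instance_map3d` or `binary_mask3d` on the working grid.
#' @param original_shape integer `(X, Y, Z)` of the target grid.
#' @return a label map on the original grid.
#' @export
downsample_labels <- function(labels, original_shape) {
  stopifnot(inherits(labels, "volume3d"))
  d <- dim(labels$data)
  original_shape <- as.integer(original_shape)
  f <- d / original_shape
  if (any(f != round(f)) || any(f < 1)) {
    stop("working-grid shape must be an integer multiple of `original_shape`",
         call. = FALSE)
  }
  f <- as.integer(f)
  idx <- lapply(1:3, function(a) {
    (0:(original_shape[a] - 1L)) * f[a] + (f[a] %/% 2L) + 1L
  })
  out <- labels$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  new_spacing <- labels$spacing * f
  S <- diag(c(f, 1))
  S[1:3, 4] <- f %/% 2L
  new_affine <- labels$affine %*% S
  if (inherits(labels, "binary_mask3d")) {
    binary_mask3d(out, new_spacing, new_affine)
  } else {
    instance_map3d(out, new_spacing, new_affine)
  }
}
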