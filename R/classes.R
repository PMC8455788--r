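#' @useDynLib edgecore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm quantile sd lm coef cor
#' @importFrom utils write.csv read.csv
NULL

# Internal constructor shared by all grid-carrying objects. `data` is a 3D
# array indexed (x, y, z) with z the slice (coronal stacking) axis.
new_grid3d <- function(data, spacing, affine, class) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-dimensional array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(
    list(data = data, spacing = spacing, affine = affine),
    class = class
  )
}

#' Scalar 3D image volume
#'
#' A real-valued 3D grid (the MR intensity carrier) with voxel spacing in mm
#' and a rigid placement affine. Arrays are indexed `(x, y, z)` with `z` the
#' slice axis, so in-plane operations act on fixed-`z` planes.
#'
#' @param data numeric 3D array.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm, all strictly positive.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(c(spacing, 1))`.
#' @return An object of class `volume3d` with fields `data`, `spacing`,
#'   `affine`.
#' @examples
#' v <- volume3d(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1.5, 1.5, 4.5))
#' voxel_volume_ml(v)
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "double"
  if (any(!is.finite(data))) stop("volume values must all be finite", call. = FALSE)
  new_grid3d(data, spacing, affine, "volume3d")
}

#' Binary mask on a 3D grid
#'
#' Values are restricted to \{0, 1\}; used for the kidney segmentation mask
#' consumed alongside the MR volume.
#'
#' @inheritParams volume3d
#' @return An object of class `binary_mask3d` (also `volume3d`).
#' @export
binary_mask3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "integer"
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0L, 1L))) {
    stop("binary mask values must lie in {0, 1}", call. = FALSE)
  }
  new_grid3d(data, spacing, affine, c("binary_mask3d", "volume3d"))
}

#' Instance label map on a 3D grid
#'
#' Non-negative integers; 0 is background and each positive label is one cyst
#' instance. Labels need not be contiguous except directly after a relabeling
#' operation, which always emits `1..K`.
#'
#' @inheritParams volume3d
#' @return An object of class `instance_map3d` (also `volume3d`).
#' @export
instance_map3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.double(data) && any(data != round(data))) {
    stop("instance labels must be integer-valued", call. = FALSE)
  }
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("instance labels must be non-negative", call. = FALSE)
  new_grid3d(data, spacing, affine, c("instance_map3d", "volume3d"))
}

#' Three-class edge-core semantic map
#'
#' Voxel classes are fixed as 0 = background, 1 = edge, 2 = core; this coding
#' is used in files and in the predictor's class channels.
#'
#' @inheritParams volume3d
#' @return An object of class `semantic_map3d` (also `volume3d`).
#' @export
semantic_map3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  storage.mode(data) <- "integer"
  if (!all(unique(as.vector(data)) %in% 0:2)) {
    stop("semantic map values must lie in {0 = background, 1 = edge, 2 = core}",
         call. = FALSE)
  }
  new_grid3d(data, spacing, affine, c("semantic_map3d", "volume3d"))
}

#' Semantic class codes
#'
#' The fixed integer coding of the three semantic classes.
#' @export
EDGECORE_CLASSES <- c(background = 0L, edge = 1L, core = 2L)

#' Voxel volume in millilitres
#'
#' @param v any grid object (`volume3d` and subclasses).
#' @return `prod(spacing)` converted from mm^3 to mL (1000 mm^3 = 1 mL).
#' @export
voxel_volume_ml <- function(v) {
  prod(v$spacing) / 1000
}

#' Positive labels present in an instance map
#'
#' @param labels an `instance_map3d`.
#' @return sorted integer vector of distinct positive labels.
#' @export
instance_labels <- function(labels) {
  u <- sort(unique(as.vector(labels$data)))
  u[u > 0L]
}

# Stop unless two grid objects share shape (and optionally spacing).
check_same_grid <- function(a, b, what = "inputs", spacing = FALSE) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("%s must share the same grid shape", what), call. = FALSE)
  }
  if (spacing && !isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6))) {
    stop(sprintf("%s must share the same voxel spacing", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "instance_map3d")) {
    labs <- instance_labels(x)
    cat(sprintf("  %d instances, %d foreground voxels\n",
                length(labs), sum(x$data > 0L)))
  } else if (inherits(x, "binary_mask3d")) {
    cat(sprintf("  %d foreground voxels\n", sum(x$data == 1L)))
  } else if (inherits(x, "semantic_map3d")) {
    tab <- tabulate(as.vector(x$data) + 1L, nbins = 3L)
    cat(sprintf("  background %d | edge %d | core %d\n", tab[1], tab[2], tab[3]))
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
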