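# Semantic edge-core map -> instance map. Two decoders: the initial variant
# (plain 6-connected components on the core class) and the final variant
# (EDT -> seeded 3D watershed -> connected-component recovery -> one-voxel
# instance dilation -> downsample -> minimum-size filter).

label_components6 <- function(mask_arr) {
  .cc_label6(as.logical(mask_arr), as.integer(dim(mask_arr)))
}

#' Decode instances by connected components on cores (initial variant)
#'
#' Each 6-connected component of the core class becomes one instance,
#' labeled `1..K` in scan order (x fastest) of each component's first
#' voxel. Touching cores fuse; that limitation motivated the watershed-based
#' final decoder.
#'
#' @param sem a `semantic_map3d`.
#' @return an `instance_map3d` on the same grid.
#' @export
decode_initial <- function(sem) {
  stopifnot(inherits(sem, "semantic_map3d"))
  instance_map3d(label_components6(sem$data == 2L), sem$spacing, sem$affine)
}

#' Split a core mask into instances by watershed on the distance transform
#'
#' The Euclidean distance transform (distance to the nearest background
#' voxel, measured in units of the finest voxel dimension with per-axis
#' weights `spacing / min(spacing)`, so plain voxel units on an isotropic
#' grid) is computed inside the core mask; a watershed of the
#' negated distance map, restricted to the mask, splits cores that fuse
#' several convex cysts. Catchment seeds are the regional maxima, after
#' h-maxima suppression of depth `h` (default 1 voxel), of the distance map
#' lightly smoothed (two mean-filter passes over the 6-neighborhood) —
#' flooding itself uses the raw distances. The smoothing flattens the one-voxel digitization bumps that
#' anisotropic thick-slice grids leave on distance plateaus (which would
#' otherwise seed spurious basins), while genuine two-cyst necks, whose
#' depth exceeds the bump scale, keep distinct seeds. Cores whose smoothed
#' peak falls below `h` get no seed at all and are labeled whole by
#' [recover_lost_cores()]. Ridge voxels between basins carry label 0 at
#' this stage and are dealt with by the same recovery step.
#'
#' @param core a `binary_mask3d` of the core class on the working grid.
#' @param h h-maxima suppression depth in voxels.
#' @return an `instance_map3d`; the distance map used is attached as
#'   attribute `"edt"`.
#' @export
split_cores <- function(core, h = 1) {
  stopifnot(inherits(core, "binary_mask3d"))
  d <- as.integer(dim(core$data))
  fg <- core$data == 1L
  if (!any(fg)) {
    out <- instance_map3d(array(0L, d), core$spacing, core$affine)
    attr(out, "edt") <- array(0, d)
    return(out)
  }
  w <- core$spacing / min(core$spacing)
  edt <- sqrt(.edt_sq(as.logical(fg), d, w))
  sm <- smooth_mean6(smooth_mean6(edt))
  rec <- .reconstruct_dilate6(sm - h, sm, d)
  seed_mask <- fg & (sm - rec >= h - 1e-9)
  seeds <- .cc_label6(as.logical(seed_mask), d)
  ws <- .watershed_seeded(edt, seeds, as.logical(fg), d)
  out <- instance_map3d(ws, core$spacing, core$affine)
  attr(out, "edt") <- edt
  out
}

#' Recover core voxels lost by the watershed
#'
#' 6-connected components of the core voxels that the watershed left
#' unlabeled (ridge voxels and seeds-starved fragments) are labeled starting
#' from one plus the last watershed label and added back, so that afterwards
#' every core voxel carries exactly one positive label.
#'
#' @param core a `binary_mask3d` of the core class.
#' @param ws an `instance_map3d` with `ws > 0` contained in `core`.
#' @return an `instance_map3d` covering all of `core`.
#' @export
recover_lost_cores <- function(core, ws) {
  stopifnot(inherits(core, "binary_mask3d"), inherits(ws, "instance_map3d"))
  check_same_grid(core, ws, "core and watershed output")
  if (any(ws$data > 0L & core$data == 0L)) {
    stop("watershed labels must be contained in the core mask", call. = FALSE)
  }
  residue <- core$data == 1L & ws$data == 0L
  if (!any(residue)) return(ws)
  cc <- label_components6(residue)
  offset <- max(ws$data)
  out <- ws$data
  out[cc > 0L] <- cc[cc > 0L] + offset
  res <- instance_map3d(out, ws$spacing, ws$affine)
  attr(res, "edt") <- attr(ws, "edt")
  res
}

#' Dilate every instance by one voxel (6-connected)
#'
#' One round of 6-connected dilation: each unlabeled voxel adjacent to at
#' least one instance takes a label. When a voxel is adjacent to several
#' instances, the neighbor with the largest core distance-transform value
#' wins; exact ties go to the first competing neighbor in the fixed
#' spatial scan order, a label-independent rule, so dilation commutes with
#' relabeling. This is the step that
#' re-absorbs the one-erosion-deep inner edge, so on opened instances
#' dilation of the eroded core reproduces the instance exactly.
#'
#' @param labels an `instance_map3d`.
#' @param edt optional distance map of the pre-dilation foreground; computed
#'   from `labels > 0` when missing.
#' @return an `instance_map3d`.
#' @export
dilate_instances <- function(labels, edt = NULL) {
  stopifnot(inherits(labels, "instance_map3d"))
  d <- as.integer(dim(labels$data))
  if (is.null(edt)) edt <- attr(labels, "edt")
  if (is.null(edt)) {
    edt <- sqrt(.edt_sq(as.logical(labels$data > 0L), d,
                        labels$spacing / min(labels$spacing)))
  }
  out <- .dilate_labels_once(labels$data, as.numeric(edt), d)
  instance_map3d(out, labels$spacing, labels$affine)
}

#' Remove instances below a minimum voxel count
#'
#' Applied on the original (down-sampled) grid; MR noise produces spurious
#' bright specks, so instances smaller than `min_voxels` (default 4) are
#' dropped. Survivors are relabeled `1..K` preserving the ascending order of
#' their old labels.
#'
#' @param labels an `instance_map3d`.
#' @param min_voxels minimum instance size in voxels, at least 1.
#' @return an `instance_map3d` with contiguous labels.
#' @export
filter_small <- function(labels, min_voxels = 4L) {
  stopifnot(inherits(labels, "instance_map3d"))
  if (min_voxels < 1L) stop("`min_voxels` must be at least 1", call. = FALSE)
  mx <- max(labels$data)
  if (mx == 0L) return(labels)
  counts <- tabulate(labels$data[labels$data > 0L], nbins = mx)
  keep <- which(counts >= min_voxels)
  lut <- integer(mx + 1L)
  lut[keep + 1L] <- seq_along(keep)
  out <- array(lut[labels$data + 1L], dim(labels$data))
  instance_map3d(out, labels$spacing, labels$affine)
}

#' Decode instances from an edge-core map (final variant)
#'
#' Full final-variant post-processing on the working grid: watershed
#' splitting of the core class ([split_cores()]), recovery of unlabeled core
#' voxels ([recover_lost_cores()]), one-voxel instance dilation
#' ([dilate_instances()]), down-sampling to the original grid
#' ([downsample_labels()]), and the minimum-size filter ([filter_small()]).
#'
#' @param sem a `semantic_map3d` on the working (up-sampled) grid.
#' @param original_shape integer `(X, Y, Z)` of the original exam grid; each
#'   working-grid axis must be an integer multiple of it.
#' @param min_voxels minimum instance size on the original grid.
#' @param h watershed h-maxima depth, see [split_cores()].
#' @return an `instance_map3d` on the original grid.
#' @export
decode_final <- function(sem, original_shape, min_voxels = 4L, h = 1) {
  stopifnot(inherits(sem, "semantic_map3d"))
  core <- binary_mask3d((sem$data == 2L) * 1L, sem$spacing, sem$affine)
  ws <- split_cores(core, h = h)
  full <- recover_lost_cores(core, ws)
  dil <- dilate_instances(full, edt = attr(full, "edt"))
  down <- downsample_labels(dil, original_shape)
  filter_small(down, min_voxels)
}
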