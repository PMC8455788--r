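# Exam-level prediction: slice stacking, intensity normalization, the
# majority-voting ensemble, and the truth-replay predictor that makes the
# full pipeline testable without trained weights.

#' Normalize MR intensities within the kidney
#'
#' Per-volume rescale to `[0, 1]` by the 1st-99th intensity percentiles
#' inside the kidney mask (whole volume if the mask is empty), clamped.
#' Percentile scaling keeps the stacking invariant to field-strength
#' dependent intensity ranges.
#'
#' @param mri a `volume3d`.
#' @param kidney a `binary_mask3d` on the same grid.
#' @return a normalized `volume3d`.
#' @export
normalize_volume <- function(mri, kidney) {
  check_same_grid(mri, kidney, "mri and kidney")
  vals <- if (any(kidney$data == 1L)) mri$data[kidney$data == 1L] else mri$data
  q <- quantile(vals, c(0.01, 0.99), names = FALSE)
  x <- if (q[2] > q[1]) (mri$data - q[1]) / (q[2] - q[1]) else mri$data * 0
  volume3d(pmin(pmax(x, 0), 1), mri$spacing, mri$affine)
}

#' Build the 4-channel input stack for one slice
#'
#' Channels, in order: slice `z - 1`, slice `z`, slice `z + 1`, and the
#' kidney mask at `z`. Out-of-range neighbor slices are all-zero planes.
#' Slice indices are 1-based.
#'
#' @param mri a `volume3d` (normalized unless `normalize = TRUE`).
#' @param kidney a `binary_mask3d` on the same grid.
#' @param z slice index in `1..Z`.
#' @param normalize apply [normalize_volume()] first.
#' @return `(X, Y, 4)` numeric array.
#' @export
stack_slices <- function(mri, kidney, z, normalize = TRUE) {
  check_same_grid(mri, kidney, "mri and kidney")
  d <- dim(mri$data)
  if (z < 1L || z > d[3]) stop("slice index out of range", call. = FALSE)
  if (normalize) mri <- normalize_volume(mri, kidney)
  zero <- matrix(0, d[1], d[2])
  out <- array(0, c(d[1], d[2], 4L))
  out[, , 1] <- if (z > 1L) mri$data[, , z - 1L] else zero
  out[, , 2] <- mri$data[, , z]
  out[, , 3] <- if (z < d[3]) mri$data[, , z + 1L] else zero
  out[, , 4] <- kidney$data[, , z]
  out
}

#' Majority vote over member predictions
#'
#' Per voxel, the class chosen by the majority of members wins. Ties
#' (including a full three-way split) are resolved by the largest summed
#' probability when probability maps are supplied; remaining exact ties fall
#' back to class precedence core > edge > background. Hard-label inputs with
#' an unresolvable split and no probabilities raise an error.
#'
#' @param predictions list of member predictions on identical grids: either
#'   `semantic_map3d`/integer arrays of classes, or probability arrays whose
#'   last dimension is the 3 classes.
#' @return integer class array (or `semantic_map3d` when inputs were
#'   semantic maps).
#' @export
majority_vote <- function(predictions) {
  stopifnot(length(predictions) >= 1L)
  is_sem <- vapply(predictions, inherits, logical(1), "semantic_map3d")
  arrs <- lapply(predictions, function(p) if (inherits(p, "volume3d")) p$data else p)
  d1 <- dim(arrs[[1]])
  soft <- length(d1) >= 2L && d1[length(d1)] == 3L && is.double(arrs[[1]])
  if (soft) {
    hard <- lapply(arrs, function(a) {
      nd <- length(dim(a))
      pieces <- if (nd == 3L) list(a[, , 1], a[, , 2], a[, , 3])
                else list(a[, , , 1], a[, , , 2], a[, , , 3])
      # per-member argmax; exact ties resolved core > edge > background
      cls <- array(0L, dim(pieces[[1]]))
      cls[pieces[[2]] >= pieces[[1]]] <- 1L
      cls[pieces[[3]] >= pieces[[1]] & pieces[[3]] >= pieces[[2]]] <- 2L
      cls
    })
    psum <- Reduce(`+`, arrs)
  } else {
    hard <- arrs
    psum <- NULL
  }
  for (h in hard[-1]) {
    if (!identical(dim(h), dim(hard[[1]]))) {
      stop("member predictions must share the same grid", call. = FALSE)
    }
  }
  counts <- lapply(0:2, function(cls) Reduce(`+`, lapply(hard, function(h) h == cls)))
  n0 <- counts[[1]]; n1 <- counts[[2]]; n2 <- counts[[3]]
  top <- pmax(n0, pmax(n1, n2))
  tie <- ((n0 == top) + (n1 == top) + (n2 == top)) > 1L
  out <- array(0L, dim(hard[[1]]))
  out[n1 == top & !tie] <- 1L
  out[n2 == top & !tie] <- 2L
  if (any(tie)) {
    if (is.null(psum)) {
      stop("tied hard-label votes cannot be resolved without probabilities",
           call. = FALSE)
    }
    nd <- length(dim(psum))
    pieces <- if (nd == 3L) list(psum[, , 1], psum[, , 2], psum[, , 3])
              else list(psum[, , , 1], psum[, , , 2], psum[, , , 3])
    # among tied top classes, largest summed probability; exact ties ->
    # precedence core > edge > background
    for (cls in c(0L, 1L, 2L)) {
      eligible <- tie & (counts[[cls + 1L]] == top)
      better <- rep(FALSE, length(eligible))
      for (oth in c(0L, 1L, 2L)) {
        if (oth == cls) next
        comp <- if (oth > cls) pieces[[oth + 1L]] >= pieces[[cls + 1L]]
                else pieces[[oth + 1L]] > pieces[[cls + 1L]]
        better <- better | (as.vector(counts[[oth + 1L]] == top) & as.vector(comp))
      }
      sel <- as.vector(eligible) & !better
      out[sel] <- cls
    }
  }
  if (all(is_sem)) {
    p1 <- predictions[[1]]
    semantic_map3d(out, p1$spacing, p1$affine)
  } else {
    out
  }
}

#' Ordered ensemble of slice predictors
#'
#' @param members list of `slice_predictor`s (typically 3).
#' @return an `ensemble_predictor`.
#' @export
ensemble_predictor <- function(members) {
  if (length(members) < 1L) stop("at least one member is required", call. = FALSE)
  for (m in members) stopifnot(inherits(m, "slice_predictor"))
  structure(list(members = members), class = "ensemble_predictor")
}

#' Predict the edge-core map of a whole exam
#'
#' For each slice: build the 4-channel stack, let every member predict, and
#' majority-vote the class probabilities voxel-wise. Voxels outside the
#' kidney mask are forced to background.
#'
#' @param ens an [ensemble_predictor()] (a single `slice_predictor` is
#'   promoted to a one-member ensemble).
#' @param mri a `volume3d` on the working grid.
#' @param kidney a `binary_mask3d` on the same grid.
#' @return a `semantic_map3d`.
#' @export
predict_exam <- function(ens, mri, kidney) {
  if (inherits(ens, "slice_predictor")) ens <- ensemble_predictor(list(ens))
  stopifnot(inherits(ens, "ensemble_predictor"))
  check_same_grid(mri, kidney, "mri and kidney")
  d <- dim(mri$data)
  norm <- normalize_volume(mri, kidney)
  sem <- array(0L, d)
  for (z in seq_len(d[3])) {
    stack <- stack_slices(norm, kidney, z, normalize = FALSE)
    probs <- lapply(ens$members, predict_slice, stack = stack, z = z)
    sem[, , z] <- majority_vote(probs)
  }
  sem[kidney$data == 0L] <- 0L
  semantic_map3d(sem, mri$spacing, mri$affine)
}

#' Truth-replay ("oracle") slice predictor
#'
#' Returns the one-hot encoding of a known semantic map, slice by slice.
#' Used to exercise the whole pipeline (stacking, voting, decoding) without
#' any trained weights.
#'
#' @param sem a `semantic_map3d`.
#' @return a `slice_predictor`.
#' @export
oracle_predictor <- function(sem) {
  stopifnot(inherits(sem, "semantic_map3d"))
  slice_predictor(function(stack, z) {
    if (is.null(z)) stop("oracle predictor needs the slice index", call. = FALSE)
    sl <- sem$data[, , z]
    out <- array(0, c(dim(sl), 3L))
    for (cls in 0:2) out[, , cls + 1L] <- (sl == cls) * 1.0
    out
  })
}

#' Select the best ensemble members by validation score
#'
#' Scores every candidate by the mean of the edge-class and core-class
#' Jaccard indices of its hard predictions over the validation exams and
#' keeps the top `n_keep` (the cross-validation member selection rule:
#' train one model per fold, retain the best three).
#'
#' @param members list of `slice_predictor` candidates.
#' @param val_exams list of `list(mri, kidney, sem)` validation exams.
#' @param n_keep ensemble size.
#' @return an `ensemble_predictor` of the `n_keep` best members (best
#'   first); scores attached as attribute `"scores"`.
#' @export
select_members <- function(members, val_exams, n_keep = 3L) {
  stopifnot(length(members) >= n_keep, length(val_exams) >= 1L)
  scores <- vapply(members, function(m) {
    per_exam <- vapply(val_exams, function(ex) {
      pred <- predict_exam(m, ex$mri, ex$kidney)
      mean(c(jaccard_index((pred$data == 1L) * 1, (ex$sem$data == 1L) * 1),
             jaccard_index((pred$data == 2L) * 1, (ex$sem$data == 2L) * 1)))
    }, numeric(1))
    mean(per_exam)
  }, numeric(1))
  keep <- order(scores, decreasing = TRUE)[seq_len(n_keep)]
  ens <- ensemble_predictor(members[keep])
  attr(ens, "scores") <- scores
  ens
}
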