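#' Soft Jaccard index
#'
#' `J = (sum(p*r) + eps) / (sum(p) + sum(r) - sum(p*r) + eps)`. With binary
#' inputs this is intersection over union; with a soft prediction it is the
#' differentiable overlap used as `1 - J` during training (with `eps = 1`
#' smoothing so empty masks are well-behaved). With `eps = 0` an
#' empty-vs-empty pair scores 1 by convention.
#'
#' @param p prediction: array or grid object, values in `[0, 1]`.
#' @param r reference: binary array or grid object.
#' @param eps smoothing constant added to numerator and denominator.
#' @return value in `[0, 1]`.
#' @export
jaccard_index <- function(p, r, eps = 0) {
  pa <- if (inherits(p, "volume3d")) p$data else p
  ra <- if (inherits(r, "volume3d")) r$data else r
  if (!identical(dim(pa), dim(ra))) {
    stop("prediction and reference must share the same grid shape", call. = FALSE)
  }
  pa <- as.numeric(pa); ra <- as.numeric(ra)
  if (any(pa < 0 | pa > 1)) stop("prediction values must lie in [0, 1]", call. = FALSE)
  inter <- sum(pa * ra)
  denom <- sum(pa) + sum(ra) - inter
  if (eps == 0 && denom == 0) return(1)
  (inter + eps) / (denom + eps)
}

#' Voxel-wise similarity between two segmentations
#'
#' Both maps are binarized (label > 0) and compared voxel-wise: Dice,
#' Jaccard, precision, recall, and the absolute relative volume change
#' `ARVC = |V_p - V_r| / V_r` (reference volume in the denominator). An
#' empty-vs-empty pair scores 1 on all overlap metrics and 0 on ARVC.
#'
#' @param pred predicted `instance_map3d` (or mask).
#' @param ref reference `instance_map3d` (or mask) on the same grid.
#' @return a `similarity_report` list with fields `dice`, `jaccard`,
#'   `precision`, `recall`, `arvc`.
#' @export
similarity <- function(pred, ref) {
  check_same_grid(pred, ref, "pred and ref")
  p <- pred$data > 0L
  r <- ref$data > 0L
  np <- sum(p); nr <- sum(r); ni <- sum(p & r)
  if (np == 0 && nr == 0) {
    rep_ <- list(dice = 1, jaccard = 1, precision = 1, recall = 1, arvc = 0)
  } else {
    vv_p <- voxel_volume_ml(pred); vv_r <- voxel_volume_ml(ref)
    rep_ <- list(
      dice = 2 * ni / (np + nr),
      jaccard = ni / (np + nr - ni),
      precision = if (np == 0) 0 else ni / np,
      recall = if (nr == 0) 0 else ni / nr,
      arvc = if (nr == 0) Inf else abs(np * vv_p - nr * vv_r) / (nr * vv_r)
    )
  }
  structure(rep_, class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Dice %.3f | Jaccard %.3f | precision %.3f | recall %.3f | ARVC %.3f\n",
              x$dice, x$jaccard, x$precision, x$recall, x$arvc))
  invisible(x)
}

#' Cyst biomarkers from an instance map
#'
#' Total cyst volume (TCV, mL) is the sum of all labeled voxels times the
#' voxel volume; cyst count is the number of distinct positive labels; the
#' cystic index is `100 * TCV / TKV`, the percent of the kidney occupied by
#' cysts, with TKV measured from the kidney mask the same way.
#'
#' @param labels an `instance_map3d`.
#' @param kidney optional `binary_mask3d` on the same grid; without it the
#'   cystic index is `NA`.
#' @return a `cyst_stats` list with `tcv_ml`, `cyst_count`, `cystic_index`,
#'   `tkv_ml` and the per-cyst `table` (label, voxels, volume_ml).
#' @export
cyst_stats <- function(labels, kidney = NULL) {
  stopifnot(inherits(labels, "instance_map3d"))
  tab <- phantom_cyst_table(labels)
  tcv <- sum(tab$volume_ml)
  count <- nrow(tab)
  tkv <- NA_real_
  index <- NA_real_
  if (!is.null(kidney)) {
    check_same_grid(labels, kidney, "labels and kidney")
    tkv <- sum(kidney$data == 1L) * voxel_volume_ml(kidney)
    if (tkv == 0) {
      if (count > 0) {
        stop("cystic index undefined: empty kidney mask with non-empty cysts",
             call. = FALSE)
      }
      index <- 0
    } else {
      index <- 100 * tcv / tkv
    }
  }
  structure(list(tcv_ml = tcv, cyst_count = count, cystic_index = index,
                 tkv_ml = tkv, table = tab),
            class = "cyst_stats")
}

#' @export
print.cyst_stats <- function(x, ...) {
  cat(sprintf("TCV %.2f mL | %d cysts | cystic index %s\n",
              x$tcv_ml, x$cyst_count,
              if (is.na(x$cystic_index)) "NA" else sprintf("%.1f%%", x$cystic_index)))
  invisible(x)
}
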