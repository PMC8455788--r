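#' Read a NIfTI volume
#'
#' Reads a `.nii` or `.nii.gz` file and returns it as one of the package's
#' grid objects, with voxel spacing and affine taken from the header. Integer
#' label maps and masks on disk can be requested via `as`; the corresponding
#' value checks are applied on read.
#'
#' @param path path to a NIfTI-1 file (optionally gzip-compressed).
#' @param as one of `"volume"`, `"instance"`, `"mask"`, `"semantic"`.
#' @return a `volume3d`, `instance_map3d`, `binary_mask3d` or
#'   `semantic_map3d`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, as = c("volume", "instance", "mask", "semantic")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not readable as NIfTI: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- array(as.vector(img), dim = dim(img))  # drop niftiImage attributes
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))[1:4, 1:4]
  switch(as,
    volume = volume3d(arr, spacing, affine),
    instance = instance_map3d(arr, spacing, affine),
    mask = binary_mask3d(arr, spacing, affine),
    semantic = semantic_map3d(arr, spacing, affine)
  )
}

#' Write a volume or label map as NIfTI
#'
#' Intensity volumes are stored as 32-bit float; integer maps with an integer
#' type wide enough for the largest label (8-bit up to 255, 16-bit up to
#' 32767, 32-bit beyond). A `.nii.gz` suffix triggers gzip compression.
#'
#' @param v a grid object.
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  arr <- v$data
  if (is.integer(arr)) {
    mx <- max(arr, 0L)
    datatype <- if (mx <= 255L) "uint8" else if (mx <= 32767L) "int16" else "int32"
  } else {
    datatype <- "float"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- v$spacing
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
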