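# NIfTI slice-stack I/O for label masks, with voxel spacing taken from the
# header so Hausdorff distances come out in millimetres.

#' Read / write label masks as NIfTI stacks
#'
#' `write_mask_nifti()` stores an integer label array (2-D slice or 3-D
#' stack) with the given per-axis spacing in the header;
#' `read_mask_nifti()` returns the labels and the spacing, ready to feed
#' [evaluate_cases()].
#'
#' @param mask integer array of class labels (rows, cols\[, slices\]).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param spacing per-axis voxel size, recycled to the array dimensionality.
#' @return `read_mask_nifti()`: list with `mask` (integer array) and
#'   `spacing` (numeric); `write_mask_nifti()`: the path, invisibly.
#' @export
write_mask_nifti <- function(mask, path, spacing = 1) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input/output")
  }
  nd <- length(dim(mask))
  spacing <- rep_len(as.numeric(spacing), nd)
  img <- array(as.integer(mask), dim(mask))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI input/output")
  }
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)
  m <- array(as.integer(img), dim(img))
  list(mask = m, spacing = as.numeric(spacing)[seq_along(dim(m))])
}
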