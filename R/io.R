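#' Write a volume to NIfTI with spacing metadata
#'
#' @param voxels numeric 3D array
#' @param spacing mm triple
#' @param path output path (.nii or .nii.gz)
#' @export
write_volume <- function(voxels, spacing, path) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file
#' @return list with \code{voxels} (array) and \code{spacing} (mm)
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(voxels = as.array(img), spacing = RNifti::pixdim(img))
}

#' @useDynLib petac, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
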