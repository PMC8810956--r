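#' Read a 3D CT volume from a NIfTI-1 file
#'
#' Voxel values are taken as already being Hounsfield units. The sform/qform
#' affine is decomposed into spacing, origin and direction cosines; NIfTI
#' world space is RAS, matching the package convention.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), "D: ", path)
  }
  aff <- RNifti::xform(img)
  M <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("degenerate affine in ", path)
  direction <- sweep(M, 2, spacing, "/")
  ct_volume(voxels = array(as.numeric(img), dim = d),
            spacing = spacing, origin = aff[1:3, 4], direction = direction)
}

#' Write a CT volume to NIfTI-1
#'
#' Voxels are written as 64-bit floats so that a write/read round-trip is
#' lossless; the full affine is stored in both sform and qform.
#'
#' @param volume A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  aff <- volume_affine(volume)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
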