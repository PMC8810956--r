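#' CT volume in Hounsfield units with scanner geometry
#'
#' Container for a single 3D scalar CT volume. Voxel values are Hounsfield
#' units (rescale slope/intercept already applied by the readers). Geometry
#' follows the NIfTI/RAS world convention: the physical position of 0-based
#' voxel index `(i, j, k)` is `origin + direction %*% (spacing * c(i, j, k))`
#' millimetres in right-anterior-superior space. Grid axis 3 is the axial
#' (slice) axis; slices are stored 0-based, ascending.
#'
#' @param voxels 3D numeric array of Hounsfield units, indexed `[x, y, z]`
#'   where `x` is the in-plane column axis, `y` the row axis and `z` the
#'   slice axis.
#' @param spacing Numeric length-3 vector of strictly positive voxel sizes
#'   in millimetres, one per grid axis.
#' @param origin Numeric length-3 RAS position (mm) of voxel `(0, 0, 0)`.
#' @param direction 3x3 direction-cosine matrix mapping grid axes to RAS
#'   axes (columns are unit vectors; identity for a canonically oriented
#'   axial volume).
#' @return An object of class `ct_volume`.
#' @seealso [read_nifti()], [read_dicom_series()], [ras_to_voxel()]
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3D array (got ", length(dim(voxels)), " dims)")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 strictly positive millimetre values")
  }
  if (length(origin) != 3L) stop("'origin' must have length 3")
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L))) stop("'direction' must be a 3x3 matrix")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-4) {
    stop("'direction' must have orthonormal columns")
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         direction = direction),
    class = "ct_volume"
  )
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (RAS mm): %.2f %.2f %.2f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  HU range: [%.1f, %.1f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' 4x4 voxel-to-world affine of a CT volume
#'
#' @param volume A [ct_volume()].
#' @return 4x4 matrix mapping homogeneous 0-based voxel indices to RAS mm.
#' @export
volume_affine <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  A <- diag(4)
  A[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
  A[1:3, 4] <- volume$origin
  A
}

#' Convert 0-based voxel indices to RAS millimetre coordinates
#'
#' @param volume A [ct_volume()].
#' @param idx Numeric length-3 0-based voxel index `(x, y, z)`, or an n x 3
#'   matrix of indices.
#' @return RAS mm coordinates, same shape as `idx`.
#' @export
voxel_to_ras <- function(volume, idx) {
  stopifnot(inherits(volume, "ct_volume"))
  idx <- rbind(idx)
  if (ncol(idx) != 3L) stop("'idx' must have 3 columns")
  world <- t(volume$direction %*% (t(idx) * volume$spacing) + volume$origin)
  if (nrow(world) == 1L) drop(world) else world
}

#' Convert an RAS millimetre point to the nearest 0-based voxel index
#'
#' Applies the inverse of the volume affine and rounds to the nearest voxel.
#' Points outside the physical extent of the grid (beyond half a voxel past
#' the first/last voxel centre on any axis) are rejected.
#'
#' @param volume A [ct_volume()].
#' @param p_ras Numeric length-3 RAS point in millimetres (e.g. a 3D Slicer
#'   fiducial).
#' @return Integer length-3 0-based voxel index `(x, y, z)`.
#' @export
ras_to_voxel <- function(volume, p_ras) {
  stopifnot(inherits(volume, "ct_volume"))
  p_ras <- as.numeric(p_ras)
  if (length(p_ras) != 3L) stop("'p_ras' must have length 3")
  cont <- drop(crossprod(volume$direction, p_ras - volume$origin)) / volume$spacing
  d <- dim(volume)
  bad <- which(cont < -0.5 | cont > d - 0.5)
  if (length(bad)) {
    stop(sprintf(
      "RAS point (%.2f, %.2f, %.2f) lies outside the volume extent on axis %d (continuous index %.2f, grid size %d)",
      p_ras[1], p_ras[2], p_ras[3], bad[1], cont[bad[1]], d[bad[1]]))
  }
  idx <- as.integer(floor(cont + 0.5))
  pmin(pmax(idx, 0L), d - 1L)
}
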