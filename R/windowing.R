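#' CT display window
#'
#' A window level/width pair describing the linear map from Hounsfield
#' units to 8-bit gray levels used on clinical workstations: HU values in
#' `[WL - WW/2, WL + WW/2]` map linearly onto `[0, 255]` and values outside
#' are clamped.
#'
#' @param level Window level (WL), the HU value mapped to mid-gray.
#' @param width Window width (WW) in HU; must be positive.
#' @return An object of class `window_setting`.
#' @export
window_setting <- function(level, width) {
  level <- as.numeric(level); width <- as.numeric(width)
  if (!is.finite(width) || width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_setting")
}

#' @export
print.window_setting <- function(x, ...) {
  cat(sprintf("<window> WL = %g, WW = %g (HU %g..%g -> 0..255)\n",
              x$level, x$width, x$level - x$width / 2, x$level + x$width / 2))
  invisible(x)
}

#' The default three-window triple for post-ablation liver CT
#'
#' Liver window WL 60 / WW 400 (red channel), ablation window WL 80 / WW 60
#' (green channel) and tumor window WL 120 / WW 40 (blue channel). The
#' narrow tumor window saturates arterially enhancing nodules at the
#' ablation margin while the ablation window keeps the hypodense treated
#' zone visible.
#'
#' @return Named list of three [window_setting()]s (`liver`, `ablation`,
#'   `tumor`).
#' @export
default_window_settings <- function() {
  list(liver = window_setting(60, 400),
       ablation = window_setting(80, 60),
       tumor = window_setting(120, 40))
}

# round-half-up, isolated so tests can pin the rounding rule of the 8-bit
# conversion (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Apply a display window to a HU volume
#'
#' `out = clamp(round(255 * (HU - WL + WW/2) / WW), 0, 255)` with
#' round-half-up — the standard radiology display transform. Monotone
#' non-decreasing in HU.
#'
#' @param volume A [ct_volume()] or a numeric array/vector of HU values.
#' @param w A [window_setting()].
#' @return Integer array of the same shape with values in `[0, 255]`.
#' @export
apply_window <- function(volume, w) {
  stopifnot(inherits(w, "window_setting"))
  hu <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  if (!is.numeric(hu)) stop("'volume' must be numeric HU data or a ct_volume")
  scaled <- 255 * (hu - w$level + w$width / 2) / w$width
  out <- round_half_up(scaled)
  out[out < 0] <- 0
  out[out > 255] <- 255
  storage.mode(out) <- "integer"
  out
}

#' Compose the three-channel 8-bit volume consumed by the classifier
#'
#' Each channel is an independent re-windowing of the same arterial-phase
#' HU volume, so the channels are voxel-aligned by construction; no spatial
#' resampling takes place and the geometry is inherited unchanged.
#'
#' @param volume A [ct_volume()].
#' @param settings List of three [window_setting()]s in channel order
#'   (red, green, blue); defaults to [default_window_settings()].
#' @return An object of class `multichannel_volume` with fields `channels`
#'   (integer array `[x, y, z, channel]`, values 0..255), `spacing`,
#'   `origin`, `direction` and `window_settings`.
#' @export
compose_channels <- function(volume, settings = default_window_settings()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (length(settings) != 3L) stop("exactly three window settings required")
  d <- dim(volume)
  ch <- array(0L, dim = c(d, 3L))
  for (k in 1:3) ch[, , , k] <- apply_window(volume, settings[[k]])
  structure(
    list(channels = ch, spacing = volume$spacing, origin = volume$origin,
         direction = volume$direction, window_settings = settings),
    class = "multichannel_volume"
  )
}

#' @export
dim.multichannel_volume <- function(x) dim(x$channels)

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x)
  lv <- vapply(x$window_settings, function(w) sprintf("%g/%g", w$level, w$width), "")
  cat(sprintf("<multichannel_volume> %d x %d x %d, 3 channels (WL/WW: %s)\n",
              d[1], d[2], d[3], paste(lv, collapse = ", ")))
  invisible(x)
}

#' Write a multichannel volume as a 3-channel NIfTI for inspection
#'
#' @param mcv A [compose_channels()] result.
#' @param path Output `.nii`/`.nii.gz` path (stored as a 4D image with the
#'   channel on the fourth axis).
#' @return `path`, invisibly.
#' @export
write_multichannel_nifti <- function(mcv, path) {
  stopifnot(inherits(mcv, "multichannel_volume"))
  img <- RNifti::asNifti(mcv$channels)
  aff <- diag(4)
  aff[1:3, 1:3] <- mcv$direction %*% diag(mcv$spacing)
  aff[1:3, 4] <- mcv$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
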