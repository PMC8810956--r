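#' Candidate index: patch id -> centre coordinate
#'
#' The deployment-time dictionary mapping every candidate patch to its
#' (x, y, z) centre in source-volume voxel coordinates, built during patch
#' extraction so proposals can be placed back onto the whole scan.
#'
#' @param patches A `patch_set` (or list of patches with `id`, `case_id`
#'   and `center` fields).
#' @return Data frame of class `candidate_index` with columns `id`,
#'   `case_id`, `x`, `y`, `z` (0-based voxel indices), one row per patch.
#' @export
build_candidate_index <- function(patches) {
  ids <- vapply(patches, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate patch identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  idx <- data.frame(
    id = ids,
    case_id = vapply(patches, `[[`, "", "case_id"),
    x = vapply(patches, function(p) p$center[1], 0L),
    y = vapply(patches, function(p) p$center[2], 0L),
    z = vapply(patches, function(p) p$center[3], 0L),
    stringsAsFactors = FALSE
  )
  class(idx) <- c("candidate_index", "data.frame")
  idx
}

#' Bounding-box proposals from above-threshold patches
#'
#' Scores every candidate patch with the trained classifier and keeps
#' those at or above the operating threshold. Each proposal carries the
#' patch centre, its probability, the axial slice number, the 32x32
#' in-plane box centred on the patch centre and the z-range of the 8-slice
#' stack. Proposals are sorted by descending probability. No non-maximum
#' suppression is applied.
#'
#' @param model A `trained_model`.
#' @param index The [build_candidate_index()] of `patches`.
#' @param patches The candidate `patch_set`.
#' @param threshold Operating threshold from [select_threshold()].
#' @return Data frame of class `proposal_set`: columns `case_id, id, x, y,
#'   z, probability, slice_number, box_x0, box_x1, box_y0, box_y1,
#'   z_first, z_last` (all coordinates 0-based voxel indices, boxes
#'   inclusive).
#' @export
propose_regions <- function(model, index, patches, threshold) {
  stopifnot(inherits(model, "trained_model"))
  ids <- vapply(patches, `[[`, "", "id")
  missing_ids <- setdiff(ids, index$id)
  if (length(missing_ids)) {
    stop("patches missing from the candidate index: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  probs <- predict_proba(model, patches)
  keep <- which(probs >= threshold)
  rows <- match(ids[keep], index$id)
  out <- data.frame(
    case_id = index$case_id[rows],
    id = index$id[rows],
    x = index$x[rows], y = index$y[rows], z = index$z[rows],
    probability = as.numeric(probs[keep]),
    slice_number = index$z[rows],
    box_x0 = index$x[rows] - 16L, box_x1 = index$x[rows] + 15L,
    box_y0 = index$y[rows] - 16L, box_y1 = index$y[rows] + 15L,
    z_first = index$z[rows] - 4L, z_last = index$z[rows] + 3L,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$probability), ]
  rownames(out) <- NULL
  class(out) <- c("proposal_set", "data.frame")
  out
}

#' Write proposals as a plain CSV (case_id, x, y, z, probability)
#'
#' @param proposals A [propose_regions()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_proposals_csv <- function(proposals, path) {
  utils::write.csv(
    proposals[c("case_id", "x", "y", "z", "probability")], path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}

# draw a 1-pixel rectangle outline (inclusive bounds, 0-based) in red on
# an RGB raster [y, x, 3] in [0, 1]; bounds clipped for display only
.draw_box <- function(img, x0, x1, y0, y1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cx0 <- max(x0, 0L); cx1 <- min(x1, w - 1L)
  cy0 <- max(y0, 0L); cy1 <- min(y1, h - 1L)
  if (cx0 > cx1 || cy0 > cy1) return(img)
  paint <- function(img, yy, xx) {
    img[yy + 1L, xx + 1L, 1] <- 1
    img[yy + 1L, xx + 1L, 2] <- 0
    img[yy + 1L, xx + 1L, 3] <- 0
    img
  }
  if (y0 >= 0 && y0 < h) img <- paint(img, y0, cx0:cx1)
  if (y1 >= 0 && y1 < h) img <- paint(img, y1, cx0:cx1)
  if (x0 >= 0 && x0 < w) img <- paint(img, cy0:cy1, x0)
  if (x1 >= 0 && x1 < w) img <- paint(img, cy0:cy1, x1)
  img
}

#' Render per-slice prediction maps with proposal boxes
#'
#' Produces one RGB raster per axial slice of the composed three-channel
#' volume, with red rectangles drawn at every proposal box on the
#' proposal's slice and on the neighbouring slices of its 8-slice stack.
#' Slice numbers and probabilities accompany the rasters as an annotation
#' table (and appear in the written file names).
#'
#' @param mcv The case's [compose_channels()] volume.
#' @param proposals [propose_regions()] rows for this case (may be empty).
#' @param slices Which 0-based slice indices to render (default: all).
#' @param out_dir If given, writes `slice_<z>.png` files and an
#'   `annotations.csv` there.
#' @return Invisible list with `images` (named list of `[y, x, 3]` arrays
#'   in `[0, 1]`) and `annotations` (data frame `slice_number, case_id,
#'   probability, box_x0, box_x1, box_y0, box_y1`).
#' @export
render_prediction_map <- function(mcv, proposals, slices = NULL,
                                  out_dir = NULL) {
  stopifnot(inherits(mcv, "multichannel_volume"))
  d <- dim(mcv$channels)
  if (is.null(slices)) slices <- 0:(d[3] - 1L)
  images <- list()
  ann <- data.frame(slice_number = integer(0), case_id = character(0),
                    probability = numeric(0), box_x0 = integer(0),
                    box_x1 = integer(0), box_y0 = integer(0),
                    box_y1 = integer(0), stringsAsFactors = FALSE)
  for (z in slices) {
    # raster convention: rows = y, columns = x
    img <- array(0, dim = c(d[2], d[1], 3))
    for (ch in 1:3) img[, , ch] <- t(mcv$channels[, , z + 1L, ch]) / 255
    if (nrow(proposals)) {
      on_slice <- proposals[proposals$z_first <= z & proposals$z_last >= z, ]
      for (i in seq_len(nrow(on_slice))) {
        img <- .draw_box(img, on_slice$box_x0[i], on_slice$box_x1[i],
                         on_slice$box_y0[i], on_slice$box_y1[i])
        ann <- rbind(ann, data.frame(
          slice_number = z, case_id = on_slice$case_id[i],
          probability = on_slice$probability[i],
          box_x0 = on_slice$box_x0[i], box_x1 = on_slice$box_x1[i],
          box_y0 = on_slice$box_y0[i], box_y1 = on_slice$box_y1[i],
          stringsAsFactors = FALSE))
      }
    }
    images[[sprintf("slice_%03d", z)]] <- img
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(images)) {
      png::writePNG(images[[nm]], file.path(out_dir, paste0(nm, ".png")))
    }
    utils::write.csv(ann, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE)
  }
  invisible(list(images = images, annotations = ann))
}

#' Regular-grid candidate patches for annotation-free screening
#'
#' Whole-volume screening mode (an extension of the coordinate-dictionary
#' deployment, which scores only pre-extracted candidates): lays a regular
#' 3D grid of fully in-bounds 32x32x8 patch centres over the volume with
#' the given stride and extracts the patches.
#'
#' @param mcv A [compose_channels()] volume.
#' @param stride Integer length-3 stride (x, y, z) in voxels, >= 1.
#' @param case_id Case identifier for the generated patches.
#' @return List with `patches` (a `patch_set`, label `"negative"` as a
#'   placeholder — screening candidates are unlabelled) and `index` (their
#'   [build_candidate_index()]).
#' @export
grid_candidates <- function(mcv, stride = c(16L, 16L, 4L), case_id = "case") {
  stopifnot(inherits(mcv, "multichannel_volume"))
  stride <- as.integer(stride)
  if (length(stride) == 1L) stride <- rep(stride, 3L)
  if (any(stride < 1L)) stop("stride must be >= 1")
  d <- dim(mcv$channels)[1:3]
  rng <- .center_range(d)
  if (any(unlist(lapply(rng, diff)) < 0)) {
    stop("volume smaller than one 32x32x8 patch")
  }
  cx <- seq.int(rng$x[1], rng$x[2], by = stride[1])
  cy <- seq.int(rng$y[1], rng$y[2], by = stride[2])
  cz <- seq.int(rng$z[1], rng$z[2], by = stride[3])
  grid <- expand.grid(x = cx, y = cy, z = cz)
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    ctr <- as.integer(grid[i, ])
    .new_patch(.extract_patch_data(mcv, ctr), ctr, "negative", case_id,
               sprintf("%s_grid_%05d", case_id, i))
  })
  patches <- structure(patches, class = "patch_set")
  list(patches = patches, index = build_candidate_index(patches))
}

#' Number of grid candidates along each axis for given sizes
#'
#' Sliding-window arithmetic: `floor((extent - patch)/stride) + 1` centres
#' per axis, every footprint fully inside the volume.
#'
#' @param dim3 Volume voxel counts (x, y, z).
#' @param stride Stride per axis.
#' @return Integer triple of per-axis candidate counts.
#' @export
grid_candidate_counts <- function(dim3, stride) {
  patch <- c(PATCH_XY, PATCH_XY, PATCH_Z)
  as.integer((dim3 - patch) %/% stride + 1L)
}
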