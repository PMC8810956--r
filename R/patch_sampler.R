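# Patch geometry: 32 x 32 in-plane, 8 axial slices. For a 0-based centre
# (cx, cy, cz) the footprint is x in [cx-16, cx+15], y in [cy-16, cy+15]
# and the slice stack z in [cz-4, cz+3] (centre biased low for even sizes).
PATCH_XY <- 32L
PATCH_Z <- 8L
HALF_XY_LO <- 16L; HALF_XY_HI <- 15L
HALF_Z_LO <- 4L; HALF_Z_HI <- 3L

#' Patch sampling configuration
#'
#' Holds the rule-based sampling rates: 20 jittered positive patches per
#' lesion, 40 negative patches per case (twice the per-lesion positive
#' rate), and a 15-voxel exclusion sphere around each lesion centre inside
#' which no negative patch centre may fall. The jitter limit keeps the
#' lesion centre at least 4 voxels inside the 32-voxel patch footprint.
#'
#' @param patches_per_lesion Positive patches sampled per lesion.
#' @param negatives_per_case Negative patches sampled per case.
#' @param exclusion_radius Radius (voxels) of the sphere around each lesion
#'   centre that negative patch centres must lie strictly outside of.
#' @param jitter_limit Maximum absolute in-plane jitter (voxels) of
#'   positive patch centres about the lesion centre; at most 12.
#' @param seed Integer seed for the sampling RNG (`NULL` = current state).
#' @return An object of class `sampling_config`.
#' @export
sampling_config <- function(patches_per_lesion = 20L, negatives_per_case = 40L,
                            exclusion_radius = 15, jitter_limit = 12L,
                            seed = NULL) {
  patches_per_lesion <- as.integer(patches_per_lesion)
  negatives_per_case <- as.integer(negatives_per_case)
  jitter_limit <- as.integer(jitter_limit)
  if (patches_per_lesion < 1L) stop("patches_per_lesion must be >= 1")
  if (negatives_per_case < 0L) stop("negatives_per_case must be >= 0")
  if (exclusion_radius <= 0) stop("exclusion_radius must be > 0")
  if (jitter_limit < 0L || jitter_limit > HALF_XY_HI - 3L) {
    stop("jitter_limit must be in [0, ", HALF_XY_HI - 3L,
         "] so the lesion centre stays inside the patch footprint")
  }
  structure(list(patches_per_lesion = patches_per_lesion,
                 negatives_per_case = negatives_per_case,
                 exclusion_radius = exclusion_radius,
                 jitter_limit = jitter_limit, seed = seed),
            class = "sampling_config")
}

# uniform integer draw on [lo, hi] (safe for lo == hi, unlike sample(x, 1))
.sample_int_range <- function(lo, hi) {
  if (lo == hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# valid centre ranges (0-based, inclusive) for a fully in-bounds patch
.center_range <- function(dim3) {
  list(x = c(HALF_XY_LO, dim3[1] - 1L - HALF_XY_HI),
       y = c(HALF_XY_LO, dim3[2] - 1L - HALF_XY_HI),
       z = c(HALF_Z_LO, dim3[3] - 1L - HALF_Z_HI))
}

.new_patch <- function(data, center, label, case_id, id, augmented = FALSE) {
  structure(list(data = data, center = as.integer(center), label = label,
                 case_id = case_id, id = id, augmented = augmented),
            class = "ltp_patch")
}

#' @export
print.ltp_patch <- function(x, ...) {
  cat(sprintf("<patch %s> %s, centre (%d, %d, %d), case %s%s\n", x$id, x$label,
              x$center[1], x$center[2], x$center[3], x$case_id,
              if (x$augmented) ", augmented" else ""))
  invisible(x)
}

# cut one 32x32x8x3 patch out of a multichannel volume; stores 8-bit data
# as a raw array to keep large patch sets compact
.extract_patch_data <- function(mcv, center) {
  cx <- center[1]; cy <- center[2]; cz <- center[3]
  block <- mcv$channels[(cx - HALF_XY_LO + 1L):(cx + HALF_XY_HI + 1L),
                        (cy - HALF_XY_LO + 1L):(cy + HALF_XY_HI + 1L),
                        (cz - HALF_Z_LO + 1L):(cz + HALF_Z_HI + 1L), ,
                        drop = FALSE]
  array(as.raw(block), dim = dim(block))
}

#' Extract jittered positive patches around a lesion centre
#'
#' Samples `patches_per_lesion` patches whose in-plane centres are uniform
#' integer jitters of the lesion centre (|dx|, |dy| <= `jitter_limit`), so
#' every patch footprint contains the lesion's (x, y); all patches share
#' the 8-slice stack centred on the lesion's z. Jitter is in-plane only.
#'
#' @param mcv A [compose_channels()] result.
#' @param p 0-based voxel triple of the lesion centre.
#' @param cfg A [sampling_config()].
#' @param case_id Case identifier stored with each patch.
#' @return A `patch_set` (list of patches).
#' @export
extract_positive_patches <- function(mcv, p, cfg, case_id = "case") {
  stopifnot(inherits(mcv, "multichannel_volume"), inherits(cfg, "sampling_config"))
  p <- as.integer(p)
  d <- dim(mcv$channels)[1:3]
  rng <- .center_range(d)
  if (p[3] < rng$z[1] || p[3] > rng$z[2]) {
    stop("lesion in case '", case_id, "' at z = ", p[3],
         " is too close to the axial boundary for an 8-slice stack ",
         "(valid z: ", rng$z[1], "..", rng$z[2], "); refusing to pad")
  }
  j <- cfg$jitter_limit
  dx_lo <- max(-j, rng$x[1] - p[1]); dx_hi <- min(j, rng$x[2] - p[1])
  dy_lo <- max(-j, rng$y[1] - p[2]); dy_hi <- min(j, rng$y[2] - p[2])
  if (dx_lo > dx_hi || dy_lo > dy_hi) {
    stop("lesion in case '", case_id, "' at (", p[1], ", ", p[2],
         ") leaves no in-bounds patch centre")
  }
  draw <- function() {
    lapply(seq_len(cfg$patches_per_lesion), function(k) {
      ctr <- c(p[1] + .sample_int_range(dx_lo, dx_hi), p[2] + .sample_int_range(dy_lo, dy_hi),
               p[3])
      .new_patch(.extract_patch_data(mcv, ctr), ctr, "positive", case_id,
                 sprintf("%s_pos_%d_%d_%d_%02d", case_id, p[1], p[2], p[3], k))
    })
  }
  patches <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, draw()) else draw()
  structure(patches, class = "patch_set")
}

#' Extract exclusion-sphere negative patches from a lesion-bearing case
#'
#' Negative patch centres are drawn uniformly over all fully in-bounds
#' centres and accepted only if their Euclidean distance (voxel units) to
#' every lesion centre strictly exceeds `exclusion_radius`.
#'
#' @param mcv A [compose_channels()] result.
#' @param lesion_centers n x 3 matrix (or length-3 vector) of 0-based
#'   lesion centres.
#' @inheritParams extract_positive_patches
#' @param n Number of negatives to draw (default `cfg$negatives_per_case`).
#' @return A `patch_set`.
#' @export
extract_negative_patches_lesion_case <- function(mcv, lesion_centers, cfg,
                                                 case_id = "case",
                                                 n = cfg$negatives_per_case) {
  stopifnot(inherits(mcv, "multichannel_volume"), inherits(cfg, "sampling_config"))
  lesion_centers <- rbind(lesion_centers)
  d <- dim(mcv$channels)[1:3]
  rng <- .center_range(d)
  if (any(unlist(lapply(rng, diff)) < 0)) {
    stop("volume too small to host 32x32x8 patches")
  }
  r2 <- cfg$exclusion_radius^2
  draw <- function() {
    out <- vector("list", n)
    got <- 0L
    tries <- 0L
    max_tries <- max(1000L, 200L * n)
    while (got < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not place ", n, " negatives outside the r = ",
             cfg$exclusion_radius, " exclusion sphere(s) in case '", case_id,
             "' (unsatisfiable geometry?)")
      }
      ctr <- c(.sample_int_range(rng$x[1], rng$x[2]), .sample_int_range(rng$y[1], rng$y[2]),
               .sample_int_range(rng$z[1], rng$z[2]))
      d2 <- colSums((t(lesion_centers) - ctr)^2)
      if (length(d2) && min(d2) <= r2) next
      got <- got + 1L
      out[[got]] <- .new_patch(.extract_patch_data(mcv, ctr), ctr, "negative",
                               case_id, sprintf("%s_neg_%03d", case_id, got))
    }
    out
  }
  patches <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, draw()) else draw()
  structure(patches, class = "patch_set")
}

#' Extract random negative patches from a control (no-LTP) case
#'
#' Centres are uniform over all fully in-bounds patch centres, restricted
#' to the body (centre voxel above -500 HU in the source volume, when that
#' volume is supplied) so air-only patches are not sampled.
#'
#' @inheritParams extract_negative_patches_lesion_case
#' @param source_volume Optional [ct_volume()] the channels were derived
#'   from, used for the body-mask test.
#' @return A `patch_set`.
#' @export
extract_negative_patches_control <- function(mcv, cfg, case_id = "case",
                                             n = cfg$negatives_per_case,
                                             source_volume = NULL) {
  stopifnot(inherits(mcv, "multichannel_volume"), inherits(cfg, "sampling_config"))
  d <- dim(mcv$channels)[1:3]
  rng <- .center_range(d)
  if (any(unlist(lapply(rng, diff)) < 0)) {
    stop("volume too small to host 32x32x8 patches")
  }
  draw <- function() {
    out <- vector("list", n)
    got <- 0L
    tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > max(1000L, 200L * n)) {
        stop("could not place ", n, " in-body negatives in case '", case_id, "'")
      }
      ctr <- c(.sample_int_range(rng$x[1], rng$x[2]), .sample_int_range(rng$y[1], rng$y[2]),
               .sample_int_range(rng$z[1], rng$z[2]))
      if (!is.null(source_volume) &&
          source_volume$voxels[ctr[1] + 1L, ctr[2] + 1L, ctr[3] + 1L] <= -500) {
        next
      }
      got <- got + 1L
      out[[got]] <- .new_patch(.extract_patch_data(mcv, ctr), ctr, "negative",
                               case_id, sprintf("%s_neg_%03d", case_id, got))
    }
    out
  }
  patches <- if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, draw()) else draw()
  structure(patches, class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  lab <- vapply(x, `[[`, "", "label")
  cat(sprintf("<patch_set> %d patches (%d positive, %d negative)\n",
              length(x), sum(lab == "positive"), sum(lab == "negative")))
  invisible(x)
}

#' @export
c.patch_set <- function(...) {
  structure(NextMethod(), class = "patch_set")
}

#' Tabulate a patch set
#'
#' @param patches A `patch_set`.
#' @return Data frame with one row per patch: `id, case_id, x, y, z, label,
#'   augmented`.
#' @export
patch_index <- function(patches) {
  data.frame(
    id = vapply(patches, `[[`, "", "id"),
    case_id = vapply(patches, `[[`, "", "case_id"),
    x = vapply(patches, function(p) p$center[1], 0L),
    y = vapply(patches, function(p) p$center[2], 0L),
    z = vapply(patches, function(p) p$center[3], 0L),
    label = vapply(patches, `[[`, "", "label"),
    augmented = vapply(patches, `[[`, TRUE, "augmented"),
    stringsAsFactors = FALSE
  )
}

#' Deterministic in-plane patch transform
#'
#' Applies one affine transform (flip, rotation, shear, zoom, shift) about
#' the in-plane centre, identically to every axial slice and every
#' channel, with nearest-neighbour resampling; source coordinates falling
#' outside the footprint are clamped to the border (edge replication, so
#' no out-of-distribution fill values enter the patch). Shape and label
#' are unchanged.
#'
#' @param patch An `ltp_patch`.
#' @param flip Mirror the x axis.
#' @param rotate Rotation angle, degrees (counter-clockwise in (x, y)).
#' @param shear Shear angle, degrees (x displaced along y).
#' @param zoom Isotropic in-plane scale factor.
#' @param shift Integer length-2 in-plane translation (voxels).
#' @return The transformed patch, with `augmented = TRUE`.
#' @export
transform_patch <- function(patch, flip = FALSE, rotate = 0, shear = 0,
                            zoom = 1, shift = c(0L, 0L)) {
  stopifnot(inherits(patch, "ltp_patch"))
  th <- rotate * pi / 180
  sh <- tan(shear * pi / 180)
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*%
    matrix(c(1, 0, sh, 1), 2) %*%
    (zoom * diag(2)) %*%
    diag(c(if (flip) -1 else 1, 1))
  ctr <- (PATCH_XY - 1) / 2
  # inverse mapping: for each output pixel find its source pixel
  Ainv <- solve(A)
  g <- as.matrix(expand.grid(x = 0:(PATCH_XY - 1), y = 0:(PATCH_XY - 1)))
  src <- t(Ainv %*% t(sweep(g, 2, ctr + shift)) + ctr)
  sx <- as.integer(floor(src[, 1] + 0.5))
  sy <- as.integer(floor(src[, 2] + 0.5))
  si <- pmin(pmax(sx, 0L), PATCH_XY - 1L) + 1L
  sj <- pmin(pmax(sy, 0L), PATCH_XY - 1L) + 1L
  dat <- patch$data
  out <- array(as.raw(0L), dim = dim(dat))
  oi <- g[, 1] + 1L
  oj <- g[, 2] + 1L
  for (z in seq_len(PATCH_Z)) for (ch in 1:3) {
    plane <- dat[, , z, ch]
    newp <- matrix(as.raw(0L), PATCH_XY, PATCH_XY)
    newp[cbind(oi, oj)] <- plane[cbind(si, sj)]
    out[, , z, ch] <- newp
  }
  p2 <- patch
  p2$data <- out
  p2$augmented <- TRUE
  p2
}

#' Random axial-plane augmentation of a patch
#'
#' Each of flip, shift (<= 4 px), shear (<= 10 deg), zoom (0.9-1.1) and
#' rotation (<= 15 deg) is applied with probability 1/2, composed into a
#' single in-plane transform via [transform_patch()].
#'
#' @param patch An `ltp_patch`.
#' @param seed Optional integer seed.
#' @return The augmented patch (same shape and label, `augmented = TRUE`).
#' @export
augment_patch <- function(patch, seed = NULL) {
  draw <- function() {
    on <- stats::runif(5) < 0.5
    transform_patch(
      patch,
      flip = on[1],
      shift = if (on[2]) sample(-4:4, 2L, replace = TRUE) else c(0L, 0L),
      shear = if (on[3]) stats::runif(1, -10, 10) else 0,
      zoom = if (on[4]) stats::runif(1, 0.9, 1.1) else 1,
      rotate = if (on[5]) stats::runif(1, -15, 15) else 0
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Sample all patches for a phantom cohort
#'
#' Runs the full sampling rule over a [generate_cohort()] result: windows
#' every case into three channels, extracts `patches_per_lesion` positives
#' per lesion, exclusion-sphere negatives from LTP cases and random
#' negatives from control cases (`negatives_per_case` each). Patches carry
#' their case's split so downstream code can keep the patient-level split.
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg A [sampling_config()]; its `seed` controls per-case sampling.
#' @param settings Window settings for [compose_channels()].
#' @return List with `patches` (a `patch_set`) and `index` (the
#'   [patch_index()] data frame plus a `split` column).
#' @export
sample_cohort_patches <- function(cohort, cfg = sampling_config(),
                                  settings = default_window_settings()) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  seed0 <- if (is.null(cfg$seed)) 1L else cfg$seed
  case_seeds <- withr::with_seed(seed0, {
    sample.int(.Machine$integer.max, length(cohort$cases))
  })
  all <- list()
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    mcv <- compose_channels(case$volume, settings)
    ccfg <- cfg
    ccfg$seed <- case_seeds[i]
    if (case$group_label == "LTP") {
      for (l in seq_len(nrow(case$lesion_centers))) {
        lcfg <- ccfg
        lcfg$seed <- (case_seeds[i] + l) %% .Machine$integer.max
        all <- c(all, extract_positive_patches(mcv, case$lesion_centers[l, ],
                                               lcfg, case$case_id))
      }
      all <- c(all, extract_negative_patches_lesion_case(
        mcv, case$lesion_centers, ccfg, case$case_id))
    } else {
      all <- c(all, extract_negative_patches_control(
        mcv, ccfg, case$case_id, source_volume = case$volume))
    }
  }
  patches <- structure(all, class = "patch_set")
  idx <- patch_index(patches)
  idx$split <- cohort$manifest$split[match(idx$case_id, cohort$manifest$case_id)]
  list(patches = patches, index = idx)
}

#' Write / read a patch archive (RDS payload + CSV index)
#'
#' The archive is a versioned RDS file holding the patch list and the
#' split assignment, with a plain CSV index alongside for inspection.
#'
#' @param patches A `patch_set`.
#' @param index The matching index data frame (with `split`).
#' @param path Base path; `<path>.rds` and `<path>_index.csv` are written.
#' @return Base path, invisibly.
#' @export
write_patch_archive <- function(patches, index, path) {
  saveRDS(list(format_version = 1L, patches = unclass(patches),
               index = index), paste0(path, ".rds"))
  utils::write.csv(index, paste0(path, "_index.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_patch_archive
#' @export
read_patch_archive <- function(path) {
  ar <- readRDS(paste0(path, ".rds"))
  if (is.null(ar$format_version) || ar$format_version != 1L) {
    stop("unknown patch archive version")
  }
  list(patches = structure(ar$patches, class = "patch_set"), index = ar$index)
}
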