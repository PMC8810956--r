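#' Parameters of the synthetic post-ablation CT phantom
#'
#' Describes one arterial-phase phantom case: a liver-like parenchyma block
#' filling the volume, a hypodense spherical ablation zone, optional
#' arterially enhancing nodules (the LTP lesions) placed on the ablation
#' boundary, bright tubular vessels as distractors, and additive Gaussian
#' HU noise applied after structure placement.
#'
#' Defaults put the lesions at 120 HU — the centre of the tumor display
#' window — against 100 HU parenchyma, with a 45 HU ablation zone, so the
#' phantom honours the contrast ordering the imaging premise relies on:
#' `ablation_hu < liver_hu_mean < lesion_hu <= vessel_hu`.
#'
#' @param volume_shape Integer triple `(x, y, z)` of voxel counts.
#' @param spacing_mm Per-axis voxel size in mm (default 0.7 x 0.7 x 3.0,
#'   the thick-slice axial regime of clinical follow-up CT).
#' @param liver_hu_mean Parenchyma HU (arterial phase).
#' @param liver_hu_noise_sd SD of additive Gaussian HU noise.
#' @param ablation_center 0-based voxel triple; `NULL` = volume centre.
#' @param ablation_radius_mm Radius of the spherical ablation zone (mm).
#' @param ablation_hu HU of the ablation zone; must be below `liver_hu_mean`.
#' @param n_lesions Number of LTP nodules (0 gives a no-LTP case).
#' @param lesion_diameter_mm Lesion sphere diameter (mm).
#' @param lesion_hu Lesion HU; must exceed `liver_hu_mean`.
#' @param lesion_margin_jitter_mm Radial jitter of lesion centres about the
#'   ablation surface (mm); lesions sit on the ablative margin.
#' @param n_vessels Number of straight cylindrical vessels.
#' @param vessel_hu Vessel HU; at least `lesion_hu` (vessels are the
#'   brightest structures and the classic false-positive source).
#' @param vessel_radius_mm Vessel cylinder radius (mm).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(volume_shape = c(96L, 96L, 24L),
                           spacing_mm = c(0.7, 0.7, 3.0),
                           liver_hu_mean = 100,
                           liver_hu_noise_sd = 10,
                           ablation_center = NULL,
                           ablation_radius_mm = 10,
                           ablation_hu = 45,
                           n_lesions = 1L,
                           lesion_diameter_mm = 6,
                           lesion_hu = 120,
                           lesion_margin_jitter_mm = 2,
                           n_vessels = 2L,
                           vessel_hu = 150,
                           vessel_radius_mm = 1.5,
                           seed = NULL) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L)) {
    stop("'volume_shape' must be three voxel counts >= 8")
  }
  if (is.null(ablation_center)) ablation_center <- (volume_shape - 1L) %/% 2L
  ablation_center <- as.integer(ablation_center)
  if (!(ablation_hu < liver_hu_mean)) stop("ablation_hu must be below liver_hu_mean")
  if (!(lesion_hu > liver_hu_mean)) stop("lesion_hu must exceed liver_hu_mean")
  if (vessel_hu < lesion_hu) stop("vessel_hu must be >= lesion_hu")
  if (n_lesions < 0 || n_vessels < 0) stop("structure counts must be non-negative")
  p <- structure(
    list(volume_shape = volume_shape, spacing_mm = as.numeric(spacing_mm),
         liver_hu_mean = liver_hu_mean, liver_hu_noise_sd = liver_hu_noise_sd,
         ablation_center = ablation_center,
         ablation_radius_mm = ablation_radius_mm, ablation_hu = ablation_hu,
         n_lesions = as.integer(n_lesions),
         lesion_diameter_mm = lesion_diameter_mm, lesion_hu = lesion_hu,
         lesion_margin_jitter_mm = lesion_margin_jitter_mm,
         n_vessels = as.integer(n_vessels), vessel_hu = vessel_hu,
         vessel_radius_mm = vessel_radius_mm, seed = seed),
    class = "phantom_params"
  )
  # every lesion (margin sphere + its own radius) must fit inside the volume
  reach_mm <- ablation_radius_mm + lesion_margin_jitter_mm + lesion_diameter_mm / 2
  ctr_mm <- ablation_center * p$spacing_mm
  ext_mm <- (volume_shape - 1L) * p$spacing_mm
  if (any(ctr_mm - reach_mm < 0) || any(ctr_mm + reach_mm > ext_mm)) {
    stop("ablation zone plus lesion margin does not fit inside the volume ",
         "(reach ", reach_mm, " mm from centre ",
         paste(round(ctr_mm, 1), collapse = ","), " mm)")
  }
  p
}

# squared distance (mm^2) of every voxel to a point given in mm
.dist2_to_point <- function(shape, spacing, p_mm) {
  dx2 <- ((seq_len(shape[1]) - 1) * spacing[1] - p_mm[1])^2
  dy2 <- ((seq_len(shape[2]) - 1) * spacing[2] - p_mm[2])^2
  dz2 <- ((seq_len(shape[3]) - 1) * spacing[3] - p_mm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

#' Generate one synthetic post-ablation CT case
#'
#' Structures are painted in order liver block, ablation sphere, vessels,
#' lesions (so a lesion voxel always carries `lesion_hu` before noise), and
#' Gaussian noise is added last. Lesion centres are drawn uniformly on the
#' ablation sphere surface with radial jitter of
#' `lesion_margin_jitter_mm`, mimicking recurrent nodules at the ablative
#' margin. Deterministic for a fixed `params$seed`.
#'
#' @param params A [phantom_params()].
#' @param case_id Case identifier string.
#' @return An object of class `phantom_case`: list with `volume`
#'   ([ct_volume()]), `lesion_centers` (n x 3 integer matrix of 0-based
#'   voxel indices, 0 rows for a no-LTP case), `group_label`
#'   (`"LTP"`/`"no-LTP"`) and `case_id`.
#' @export
generate_case <- function(params, case_id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  gen <- function() .generate_case_impl(params, case_id)
  if (!is.null(params$seed)) withr::with_seed(params$seed, gen()) else gen()
}

.generate_case_impl <- function(params, case_id) {
  shp <- params$volume_shape
  sp <- params$spacing_mm
  ctr_mm <- params$ablation_center * sp
  vol <- array(params$liver_hu_mean, dim = shp)

  # ablation sphere
  D2 <- .dist2_to_point(shp, sp, ctr_mm)
  vol[D2 <= params$ablation_radius_mm^2] <- params$ablation_hu

  # vessels: straight cylinders crossing the block
  if (params$n_vessels > 0L) {
    ext_mm <- (shp - 1L) * sp
    X <- (seq_len(shp[1]) - 1) * sp[1]
    Y <- (seq_len(shp[2]) - 1) * sp[2]
    Z <- (seq_len(shp[3]) - 1) * sp[3]
    XA <- array(X, dim = shp)
    YA <- array(rep(Y, each = shp[1]), dim = shp)
    ZA <- array(rep(Z, each = shp[1] * shp[2]), dim = shp)
    for (v in seq_len(params$n_vessels)) {
      p0 <- stats::runif(3, 0.25, 0.75) * ext_mm
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      wx <- XA - p0[1]; wy <- YA - p0[2]; wz <- ZA - p0[3]
      t <- wx * d[1] + wy * d[2] + wz * d[3]
      r2 <- (wx - t * d[1])^2 + (wy - t * d[2])^2 + (wz - t * d[3])^2
      vol[r2 <= params$vessel_radius_mm^2] <- params$vessel_hu
    }
  }

  # lesions on the ablative margin
  centers <- matrix(integer(0), nrow = 0, ncol = 3)
  if (params$n_lesions > 0L) {
    for (l in seq_len(params$n_lesions)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- params$ablation_radius_mm +
        stats::runif(1, -params$lesion_margin_jitter_mm,
                     params$lesion_margin_jitter_mm)
      c_mm <- ctr_mm + r * u
      cvox <- as.integer(floor(c_mm / sp + 0.5))
      cvox <- pmin(pmax(cvox, 0L), shp - 1L)
      L2 <- .dist2_to_point(shp, sp, cvox * sp)
      vol[L2 <= (params$lesion_diameter_mm / 2)^2] <- params$lesion_hu
      centers <- rbind(centers, cvox)
    }
    rownames(centers) <- NULL
  }

  if (params$liver_hu_noise_sd > 0) {
    vol <- vol + stats::rnorm(length(vol), 0, params$liver_hu_noise_sd)
  }

  structure(
    list(volume = ct_volume(vol, spacing = sp),
         lesion_centers = centers,
         group_label = if (nrow(centers) > 0) "LTP" else "no-LTP",
         case_id = case_id),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s (%s), %d lesion(s)\n",
              x$case_id, x$group_label, nrow(x$lesion_centers)))
  invisible(x)
}

#' Generate a phantom cohort with a case-level train/validation/test split
#'
#' Emulates a clinical study cohort: `n_ltp` cases carry one or more
#' lesions (`n_lesions` in total), `n_noltp` cases carry none. Both case
#' groups and the lesion total are divided across the three splits by
#' explicit per-split counts, so patch bookkeeping downstream is exact.
#' The split is at case (patient) level — a case never contributes to two
#' splits. Within a split, lesions are assigned to that split's LTP cases
#' randomly with at least one lesion per case.
#'
#' Defaults reproduce the reference cohort layout: 34 LTP cases (49
#' lesions) and 40 controls, case splits 21/5/8 and 27/5/8, lesion split
#' 36/5/8.
#'
#' @param n_ltp,n_noltp Number of LTP / control cases.
#' @param n_lesions Total number of lesions across all LTP cases.
#' @param ltp_split,noltp_split,lesion_split Integer length-3 vectors
#'   (train, validation, test) summing to `n_ltp`, `n_noltp`, `n_lesions`.
#' @param params A [phantom_params()] used (with `n_lesions` overridden per
#'   case and a per-case seed) for every case.
#' @param seed Integer seed controlling both the assignment and the
#'   per-case volumes.
#' @return An object of class `phantom_cohort`: list with `cases` (list of
#'   [generate_case()] results), `manifest` (data frame `case_id, group,
#'   split, n_lesions`) and `splits = c("train", "validation", "test")`.
#' @export
generate_cohort <- function(n_ltp = 34L, n_noltp = 40L, n_lesions = 49L,
                            ltp_split = c(21L, 5L, 8L),
                            noltp_split = c(27L, 5L, 8L),
                            lesion_split = c(36L, 5L, 8L),
                            params = phantom_params(),
                            seed = 1L) {
  splits <- c("train", "validation", "test")
  n_ltp <- as.integer(n_ltp); n_noltp <- as.integer(n_noltp)
  n_lesions <- as.integer(n_lesions)
  ltp_split <- as.integer(ltp_split); noltp_split <- as.integer(noltp_split)
  lesion_split <- as.integer(lesion_split)
  if (n_ltp + n_noltp <= 0) stop("cohort must contain at least one case")
  if (length(ltp_split) != 3L || length(noltp_split) != 3L ||
      length(lesion_split) != 3L) {
    stop("split vectors must have length 3 (train, validation, test)")
  }
  if (sum(ltp_split) != n_ltp) stop("ltp_split must sum to n_ltp")
  if (sum(noltp_split) != n_noltp) stop("noltp_split must sum to n_noltp")
  if (sum(lesion_split) != n_lesions) stop("lesion_split must sum to n_lesions")
  if (any(ltp_split < 0) || any(noltp_split < 0) || any(lesion_split < 0)) {
    stop("impossible split: negative count")
  }
  if (any(lesion_split < ltp_split)) {
    stop("impossible split: fewer lesions than LTP cases in some split ",
         "(every LTP case needs at least one lesion)")
  }
  if (any(lesion_split > 0 & ltp_split == 0)) {
    stop("impossible split: lesions assigned to a split with no LTP cases")
  }

  withr::with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max, n_ltp + n_noltp)
    # lesions per LTP case, respecting per-split lesion totals
    lesions_per_case <- integer(0)
    for (s in 1:3) {
      k <- ltp_split[s]
      if (k == 0) next
      extra <- lesion_split[s] - k
      cnt <- rep(1L, k)
      if (extra > 0) {
        add <- table(factor(sample.int(k, extra, replace = TRUE), levels = 1:k))
        cnt <- cnt + as.integer(add)
      }
      lesions_per_case <- c(lesions_per_case, cnt)
    }
    cases <- vector("list", n_ltp + n_noltp)
    manifest <- data.frame(case_id = character(0), group = character(0),
                           split = character(0), n_lesions = integer(0),
                           stringsAsFactors = FALSE)
    i <- 0L
    for (s in 1:3) for (j in seq_len(ltp_split[s])) {
      i <- i + 1L
      id <- sprintf("ltp_%03d", i)
      p <- params
      p$n_lesions <- lesions_per_case[i]
      p$seed <- case_seeds[i]
      cases[[i]] <- generate_case(p, case_id = id)
      manifest <- rbind(manifest, data.frame(
        case_id = id, group = "LTP", split = splits[s],
        n_lesions = lesions_per_case[i], stringsAsFactors = FALSE))
    }
    for (s in 1:3) for (j in seq_len(noltp_split[s])) {
      i <- i + 1L
      id <- sprintf("ctl_%03d", i - n_ltp)
      p <- params
      p$n_lesions <- 0L
      p$seed <- case_seeds[i]
      cases[[i]] <- generate_case(p, case_id = id)
      manifest <- rbind(manifest, data.frame(
        case_id = id, group = "no-LTP", split = splits[s], n_lesions = 0L,
        stringsAsFactors = FALSE))
    }
    structure(list(cases = cases, manifest = manifest, splits = splits),
              class = "phantom_cohort")
  })
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort>", nrow(x$manifest), "cases\n")
  print(table(x$manifest$group, x$manifest$split))
  invisible(x)
}

#' Write a phantom case to disk (NIfTI + FCSV + CSV annotations)
#'
#' @param case A [generate_case()] result.
#' @param dir Output directory (created if absent).
#' @return Invisible list of the written paths.
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nii <- file.path(dir, paste0(case$case_id, ".nii.gz"))
  write_nifti(case$volume, nii)
  csv <- file.path(dir, paste0(case$case_id, "_lesions.csv"))
  n <- nrow(case$lesion_centers)
  tab <- data.frame(case_id = rep(case$case_id, n),
                    x = case$lesion_centers[, 1], y = case$lesion_centers[, 2],
                    z = case$lesion_centers[, 3])
  write_lesion_table(tab, csv)
  fcsv <- file.path(dir, paste0(case$case_id, ".fcsv"))
  ras <- voxel_to_ras(case$volume, case$lesion_centers)
  ras <- rbind(ras)
  pts <- data.frame(label = sprintf("%s_L%d", case$case_id, seq_len(n)),
                    r = ras[seq_len(n), 1], a = ras[seq_len(n), 2],
                    s = ras[seq_len(n), 3], stringsAsFactors = FALSE)
  write_fiducials(pts, fcsv)
  invisible(list(nifti = nii, lesions_csv = csv, fcsv = fcsv))
}

#' Write a cohort manifest CSV (case_id, group, split)
#'
#' @param cohort A [generate_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
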