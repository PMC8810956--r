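test_that("a case without lesions is a no-LTP case", {
  p <- phantom_params(n_lesions = 0, seed = 5)
  case <- generate_case(p, "ctl")
  expect_identical(case$group_label, "no-LTP")
  expect_equal(nrow(case$lesion_centers), 0L)
  p2 <- phantom_params(n_lesions = 2, seed = 5)
  case2 <- generate_case(p2)
  expect_identical(case2$group_label, "LTP")
  expect_equal(nrow(case2$lesion_centers), 2L)
})

test_that("lesion centre voxels carry the lesion HU before noise", {
  p <- phantom_params(seed = 9, liver_hu_noise_sd = 0, n_lesions = 3,
                      lesion_hu = 120)
  case <- generate_case(p)
  for (l in seq_len(nrow(case$lesion_centers))) {
    ctr <- case$lesion_centers[l, ] + 1L
    hu <- case$volume$voxels[ctr[1], ctr[2], ctr[3]]
    expect_equal(hu, 120)
    # inside the tumor window span WL 120 / WW 40 -> [100, 140]
    expect_gte(hu, 100)
    expect_lte(hu, 140)
  }
})

test_that("generation is seed-deterministic and seed-sensitive", {
  p <- phantom_params(seed = 77)
  a <- generate_case(p)
  b <- generate_case(p)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$lesion_centers, b$lesion_centers)
  p2 <- phantom_params(seed = 78)
  c <- generate_case(p2)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("structure contrast ordering holds at centres before noise", {
  p <- phantom_params(seed = 3, liver_hu_noise_sd = 0)
  case <- generate_case(p)
  vox <- case$volume$voxels
  abl <- p$ablation_center + 1L
  expect_lt(vox[abl[1], abl[2], abl[3]], p$liver_hu_mean)   # ablation dark
  corner <- vox[3, 3, 3]                                    # far from all structures
  expect_equal(corner, p$liver_hu_mean)
  les <- case$lesion_centers[1, ] + 1L
  expect_gt(vox[les[1], les[2], les[3]], p$liver_hu_mean)
  expect_true(p$ablation_hu < p$liver_hu_mean &&
                p$liver_hu_mean < p$lesion_hu &&
                p$lesion_hu <= p$vessel_hu)
})

test_that("out-of-bounds structures are rejected at parameter time", {
  expect_error(phantom_params(volume_shape = c(32, 32, 8),
                              ablation_radius_mm = 20),
               "does not fit")
  expect_error(phantom_params(ablation_hu = 150), "below liver_hu_mean")
  expect_error(phantom_params(lesion_hu = 50), "exceed liver_hu_mean")
})

test_that("cohort splits conserve cases and lesions at case level", {
  coh <- generate_cohort(n_ltp = 6, n_noltp = 5, n_lesions = 9,
                         ltp_split = c(3, 1, 2), noltp_split = c(2, 2, 1),
                         lesion_split = c(5, 1, 3),
                         params = phantom_params(), seed = 4)
  m <- coh$manifest
  expect_equal(nrow(m), 11L)
  expect_equal(sum(m$group == "LTP"), 6L)
  expect_equal(as.vector(table(m$split[m$group == "LTP"])[
    c("train", "validation", "test")]), c(3L, 1L, 2L))
  # lesion totals per split match the requested split
  lesions <- tapply(m$n_lesions, m$split, sum)
  expect_equal(as.vector(lesions[c("train", "validation", "test")]),
               c(5L, 1L, 3L))
  # no case in two splits; every case generated with its manifest lesions
  expect_false(anyDuplicated(m$case_id) > 0)
  for (i in seq_len(nrow(m))) {
    expect_equal(nrow(coh$cases[[i]]$lesion_centers), m$n_lesions[i])
  }
})

test_that("degenerate and impossible cohort splits are handled", {
  one <- generate_cohort(n_ltp = 1, n_noltp = 0, n_lesions = 1,
                         ltp_split = c(1, 0, 0), noltp_split = c(0, 0, 0),
                         lesion_split = c(1, 0, 0), seed = 2)
  expect_equal(one$manifest$split, "train")
  expect_error(
    generate_cohort(n_ltp = 2, n_noltp = 0, n_lesions = 2,
                    ltp_split = c(1, 1, 0), noltp_split = c(0, 0, 0),
                    lesion_split = c(2, 0, 0), seed = 2),
    "impossible split")
  expect_error(
    generate_cohort(n_ltp = 0, n_noltp = 1, n_lesions = 1,
                    ltp_split = c(0, 0, 0), noltp_split = c(1, 0, 0),
                    lesion_split = c(1, 0, 0), seed = 2),
    "impossible split")
})

test_that("cohort assignment is reproducible for a fixed seed", {
  a <- generate_cohort(n_ltp = 3, n_noltp = 2, n_lesions = 4,
                       ltp_split = c(2, 1, 0), noltp_split = c(1, 1, 0),
                       lesion_split = c(3, 1, 0), seed = 31)
  b <- generate_cohort(n_ltp = 3, n_noltp = 2, n_lesions = 4,
                       ltp_split = c(2, 1, 0), noltp_split = c(1, 1, 0),
                       lesion_split = c(3, 1, 0), seed = 31)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[1]]$volume$voxels, b$cases[[1]]$volume$voxels)
})

test_that("phantom cases round-trip through the on-disk formats", {
  case <- quiet_phantom(seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_phantom_case(case, dir)
  vol <- read_nifti(paths$nifti)
  expect_equal(vol$voxels, case$volume$voxels)
  expect_equal(vol$spacing, case$volume$spacing, tolerance = 1e-6)
  tab <- read_lesion_table(paths$lesions_csv)
  expect_equal(as.integer(tab$x), as.integer(case$lesion_centers[, 1]))
  fid <- read_fiducials(paths$fcsv)
  expect_equal(nrow(fid), nrow(case$lesion_centers))
  # fiducial RAS coordinates map back to the annotated voxel
  back <- ras_to_voxel(vol, c(fid$r[1], fid$a[1], fid$s[1]))
  expect_equal(back, as.integer(case$lesion_centers[1, ]))
})
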