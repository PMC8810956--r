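test_that("NIfTI round-trip is lossless for voxels and geometry", {
  vol <- ct_volume(array(rnorm(10 * 12 * 6, 50, 20), dim = c(10, 12, 6)),
                   spacing = c(0.7, 0.8, 3.0), origin = c(-12.5, 4, 7))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  back <- read_nifti(f)
  expect_equal(back$voxels, vol$voxels)
  # the NIfTI-1 header stores the affine in float32: compare at single
  # precision; voxel data round-trips exactly (written as doubles)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$direction, vol$direction, tolerance = 1e-6)
})

test_that("non-3D NIfTI images are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, dim = c(4, 4, 2, 3)))
  RNifti::writeNifti(img, f)
  expect_error(read_nifti(f), "3D")
})

test_that("RAS points convert to the nearest voxel index", {
  vol <- ct_volume(array(0, dim = c(20, 20, 10)),
                   spacing = c(0.7, 0.7, 3.0), origin = c(5, -3, 11))
  expect_equal(ras_to_voxel(vol, c(5, -3, 11)), c(0L, 0L, 0L))
  expect_equal(ras_to_voxel(vol, c(5 + 7.0, -3, 11)), c(10L, 0L, 0L))
  expect_equal(ras_to_voxel(vol, c(5, -3 + 1.05, 11 + 4.6)), c(0L, 2L, 2L))
  expect_error(ras_to_voxel(vol, c(5 - 1.4, -3, 11)), "outside")
  expect_error(ras_to_voxel(vol, c(5, -3, 11 + 10 * 3)), "outside")
})

test_that("voxel -> RAS -> voxel is the identity on voxel centres", {
  vol <- ct_volume(array(0, dim = c(15, 9, 7)), spacing = c(0.7, 1.1, 2.5),
                   origin = c(-4, 2, 30))
  set.seed(8)
  for (i in 1:25) {
    idx <- c(sample(0:14, 1), sample(0:8, 1), sample(0:6, 1))
    expect_equal(ras_to_voxel(vol, voxel_to_ras(vol, idx)), as.integer(idx))
  }
})

test_that("DICOM series read applies rescale and sorts by position", {
  skip_if_not(python_available(), "python/pydicom not available")
  hu <- array(0L, dim = c(6, 5, 4))
  hu[2, 3, 1] <- 60L   # stored 1084 with slope 1 / intercept -1024
  hu[4, 2, 3] <- -200L
  dir <- withr::local_tempdir()
  write_dicom_series_py(hu, dir, origin_lps = c(10, 20, -30))
  vol <- read_dicom_series(dir)
  expect_equal(dim(vol), c(6L, 5L, 4L))
  expect_equal(vol$voxels[2, 3, 1], 60)
  expect_equal(vol$voxels[4, 2, 3], -200)
  expect_equal(vol$spacing, c(0.7, 0.7, 3.0))
  # LPS origin (10, 20, -30) converts to RAS (-10, -20, -30)
  expect_equal(vol$origin, c(-10, -20, -30))

  # same series written slice-reversed on disk parses identically
  dir2 <- withr::local_tempdir()
  write_dicom_series_py(hu, dir2, origin_lps = c(10, 20, -30),
                        reverse_on_disk = TRUE)
  vol2 <- read_dicom_series(dir2)
  expect_equal(vol2$voxels, vol$voxels)
  expect_equal(vol2$origin, vol$origin)
})

test_that("DICOM reader rejects mixed series and missing rescale", {
  skip_if_not(python_available(), "python/pydicom not available")
  hu <- array(0L, dim = c(4, 4, 2))
  dir <- withr::local_tempdir()
  write_dicom_series_py(hu, dir, series_uid = "1.2.3.1")
  # interleave a second series in the same directory
  sub <- withr::local_tempdir()
  write_dicom_series_py(hu, sub, series_uid = "1.2.3.2",
                        origin_lps = c(0, 0, 100))
  for (f in list.files(sub, full.names = TRUE)) {
    file.copy(f, file.path(dir, paste0("b_", basename(f))))
  }
  expect_error(read_dicom_series(dir), "series")

  dir3 <- withr::local_tempdir()
  write_dicom_series_py(hu, dir3, omit_rescale = TRUE)
  expect_error(read_dicom_series(dir3), "Rescale")
})

test_that("DICOM and NIfTI readers agree on the same phantom", {
  skip_if_not(python_available(), "python/pydicom not available")
  case <- quiet_phantom(seed = 21)
  hu <- round(case$volume$voxels)
  sub <- hu[31:62, 31:62, 7:12]  # keep the fixture series small
  # DICOM identity orientation (row->L, column->P) is direction
  # diag(-1,-1,1) in RAS; write the NIfTI with the same geometry
  vol_int <- ct_volume(sub, spacing = case$volume$spacing,
                       origin = c(-1, -2, 3),
                       direction = diag(c(-1, -1, 1)))
  ndir <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol_int, ndir)
  ddir <- withr::local_tempdir()
  # NIfTI origin is RAS; the DICOM tag wants LPS
  write_dicom_series_py(sub, ddir, spacing = case$volume$spacing,
                        origin_lps = c(1, 2, 3))
  a <- read_nifti(ndir)
  b <- read_dicom_series(ddir)
  expect_equal(a$voxels, b$voxels)
  expect_equal(a$spacing, b$spacing, tolerance = 1e-6)
  expect_equal(a$origin, b$origin, tolerance = 1e-6)
  expect_equal(a$direction, b$direction, tolerance = 1e-6)
})

test_that("FCSV fiducials parse with coordinate-system handling", {
  f <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c(
    "# Markups fiducial file version = 4.11",
    "# CoordinateSystem = RAS",
    "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
    "F1,10.5,-4.25,33,0,0,0,1,1,1,0,lesion_a,,",
    "F2,-2,6,9,0,0,0,1,1,1,0,lesion_b,,",
    "F3,0,0,1,0,0,0,1,1,1,0,lesion_c,,"), f)
  fid <- read_fiducials(f)
  expect_equal(nrow(fid), 3L)
  expect_equal(fid$r[1], 10.5)
  expect_equal(fid$label, c("lesion_a", "lesion_b", "lesion_c"))

  # comment-only file: empty, not an error
  f2 <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c("# Markups fiducial file version = 4.11",
               "# CoordinateSystem = RAS"), f2)
  expect_equal(nrow(read_fiducials(f2)), 0L)

  # LPS-flagged file is sign-converted to RAS
  f3 <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c("# CoordinateSystem = LPS",
               "F1,10,-4,33,0,0,0,1,1,1,0,p,,"), f3)
  fid3 <- read_fiducials(f3)
  expect_equal(c(fid3$r, fid3$a, fid3$s), c(-10, 4, 33))

  # malformed rows are reported with their line number
  f4 <- withr::local_tempfile(fileext = ".fcsv")
  writeLines(c("# CoordinateSystem = RAS",
               "F1,1,2,3,0,0,0,1,1,1,0,p,,",
               "F2,not_a_number,2,3,0,0,0,1,1,1,0,q,,"), f4)
  expect_error(read_fiducials(f4), "line 3")
})
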