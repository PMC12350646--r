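test_that("voxel_grid and binary_mask enforce their invariants", {
  expect_error(voxel_grid(array(0, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(voxel_grid(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  skewed <- diag(3); skewed[1, 2] <- 0.1
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(1, 1, 1), axes = skewed),
               "orthonormal")
  flipped <- diag(c(1, 1, -1))
  expect_error(voxel_grid(array(0, c(2, 2, 2)), c(1, 1, 1), axes = flipped),
               "right-handed")
  expect_error(binary_mask(array(2L, c(2, 2, 2)), c(1, 1, 1)), "0 or 1")
})

test_that("NIfTI round trip preserves values exactly and geometry to 1e-6", {
  set.seed(11)
  g <- voxel_grid(array(rnorm(5 * 6 * 7) * 100, c(5, 6, 7)),
                  spacing = c(0.125, 0.125, 0.160), origin = c(-3, 2, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(g, f)
  g2 <- read_volume(f)
  expect_identical(g2$values, g$values)
  expect_lt(max(abs(g2$spacing - g$spacing)), 1e-6)
  expect_lt(max(abs(g2$origin - g$origin)), 1e-6)
  expect_lt(max(abs(g2$axes - g$axes)), 1e-6)
})

test_that("mask round trip through NIfTI is voxel-identical", {
  gm <- fixture_geom(8, 0.5)
  m <- ball_mask(gm, radius = 1.5)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(m, f)
  m2 <- read_mask(f, label = m$label)
  expect_identical(m2$voxels, m$voxels)
  empty <- mask_from(gm, array(FALSE, gm$dim))
  f2 <- tempfile(fileext = ".nii")
  write_volume(empty, f2)
  expect_identical(read_mask(f2)$voxels, empty$voxels)
})

test_that("sheared NIfTI affines are rejected", {
  aff <- rbind(cbind(diag(3) + matrix(c(0, 0, 0, 0.1, 0, 0, 0, 0, 0), 3),
                     c(0, 0, 0)), c(0, 0, 0, 1))
  img <- RNifti::asNifti(array(0, c(3, 3, 3)))
  # sform only: a quaternion-based qform cannot represent shear
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(read_volume(f), "shear")
})

test_that("DICOM series round-trips and is independent of listing order", {
  set.seed(3)
  vals <- array(sample(0:4000, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  dir1 <- file.path(tempdir(), "dcm_plain")
  write_dicom_stack(dir1, vals, spacing = c(0.5, 0.5, 0.5),
                    origin = c(-10, -8, 3))
  g <- read_dicom_series(dir1)
  expect_identical(g$values, array(as.double(vals), dim(vals)))
  expect_equal(g$spacing, c(0.5, 0.5, 0.5))
  expect_equal(g$origin, c(-10, -8, 3))
  # shuffled file names: listing order disagrees with slice position
  dir2 <- file.path(tempdir(), "dcm_shuffled")
  write_dicom_stack(dir2, vals, spacing = c(0.5, 0.5, 0.5),
                    origin = c(-10, -8, 3),
                    filenames = c("d.dcm", "a.dcm", "c.dcm", "b.dcm"))
  g2 <- read_dicom_series(dir2)
  expect_identical(g2$values, g$values)
  expect_identical(g2$origin, g$origin)
})

test_that("broken DICOM stacks are rejected with named conflicts", {
  set.seed(4)
  vals <- array(sample(0:100, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  # one slice with altered pixel spacing
  dir1 <- file.path(tempdir(), "dcm_badspacing")
  dir.create(dir1, showWarnings = FALSE)
  write_dicom_stack(dir1, vals, c(0.5, 0.5, 0.5), c(0, 0, 0))
  write_dicom_slice(file.path(dir1, "slice_002.dcm"),
                    as.vector(vals[, , 2]), 4L, 4L, c(0.6, 0.6),
                    c(0, 0, 0.5), "1.2.826.0.1.999999.1", 2L)
  expect_error(read_dicom_series(dir1), "Pixel Spacing")
  # mixed series UIDs
  dir2 <- file.path(tempdir(), "dcm_mixeduid")
  write_dicom_stack(dir2, vals, c(0.5, 0.5, 0.5), c(0, 0, 0))
  write_dicom_slice(file.path(dir2, "slice_003.dcm"),
                    as.vector(vals[, , 3]), 4L, 4L, c(0.5, 0.5),
                    c(0, 0, 1), "1.2.826.0.1.999999.2", 3L)
  expect_error(read_dicom_series(dir2), "Series Instance UID")
  # non-uniform slice gap beyond 1e-3 mm
  dir3 <- file.path(tempdir(), "dcm_gap")
  write_dicom_stack(dir3, vals, c(0.5, 0.5, 0.5), c(0, 0, 0),
                    gaps = c(0.5, 0.508))
  expect_error(read_dicom_series(dir3), "slice spacing")
})

test_that("STL export volume matches voxel volume on convex solids", {
  cube <- binary_mask(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
  f <- tempfile(fileext = ".stl")
  export_stl(cube, f)
  stl <- read_stl_volume(f)
  expect_lt(abs(stl$volume - 1000) / 1000, 0.05)

  gm <- fixture_geom(24, 0.5)
  sphere <- ball_mask(gm, radius = 4)
  f2 <- tempfile(fileext = ".stl")
  export_stl(sphere, f2)
  stl2 <- read_stl_volume(f2)
  expect_lt(abs(stl2$volume - measure_volume(sphere)) /
              measure_volume(sphere), 0.05)

  single <- binary_mask(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)),
                        spacing = c(1, 1, 1))
  f3 <- tempfile(fileext = ".stl")
  export_stl(single, f3)
  stl3 <- read_stl_volume(f3)
  expect_gt(stl3$volume, 0)
  expect_gt(stl3$triangles, 3)

  empty <- binary_mask(array(0L, c(3, 3, 3)), spacing = c(1, 1, 1))
  expect_error(export_stl(empty, tempfile(fileext = ".stl")), "empty")
})

test_that("report CSV/JSON writing round-trips and enforces uniqueness", {
  r1 <- case_report("a", 1000, 2000, 1000, 500, 200, 100, 50)
  r2 <- case_report("b", 1505.2, 1982.7, 850.8, 867.6, 131.7, 56.5, 57.1)
  f <- tempfile(fileext = ".csv")
  write_report(list(r1, r2), f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2L)
  expect_equal(ncol(df), 9L)
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  back <- read_report(f)
  expect_lt(abs(back[[2]]$v_cleft_mm3 - 1505.2), 1e-3)
  expect_lt(abs(back[[1]]$v_resorption_mm3 - 1000), 1e-3)
  expect_error(write_report(list(r1, r1), tempfile(fileext = ".csv")),
               "duplicate")
  expect_error(write_report(list(), tempfile(fileext = ".csv")), "no case")
})
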