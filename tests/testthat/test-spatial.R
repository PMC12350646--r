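test_that("rigid transforms compose, invert and serialize consistently", {
  set.seed(41)
  t1 <- cleftvol:::rotation_about(c(1, 2, -1), 23, c(5, 0, 2))
  t1$translation <- t1$translation + c(1, -2, 0.5)
  t1 <- rigid_transform(t1$rotation, t1$translation)
  t2 <- cleftvol:::rotation_about(c(0, 1, 1), -40, c(-3, 2, 0))
  pts <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(compose_transform(t1, t2), pts),
               apply_transform(t1, apply_transform(t2, pts)),
               tolerance = 1e-12)
  ident <- compose_transform(t1, invert_transform(t1))
  expect_lt(rotation_angle_deg(ident), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)
  back <- transform_from_matrix(transform_to_matrix(t1))
  expect_equal(back$rotation, t1$rotation)
  expect_equal(back$translation, t1$translation)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("reslice_to_plane is the identity for aligned grids and pads FOV", {
  g <- fixture_geom(24, 0.5)
  w <- world_arrays(g)
  vals <- exp(-(w[[1]]^2 + w[[2]]^2 + w[[3]]^2) / 12) * 1000
  grid <- voxel_grid(vals, g$spacing, g$origin)
  aligned <- reslice_to_plane(grid, plane(c(0, 0, 0), c(0, 0, 1)))
  expect_identical(aligned$values, grid$values)
  # antipodal normal: also no-op (minimal rotation)
  flipped <- reslice_to_plane(grid, plane(c(0, 0, 0), c(0, 0, -1)))
  expect_identical(flipped$values, grid$values)

  # 30 degree tilt: all foreground stays inside the output FOV
  tilt <- plane(c(0, 0, 0), c(sin(pi / 6), 0, cos(pi / 6)))
  res <- reslice_to_plane(grid, tilt)
  expect_equal(res$axes[, 3], tilt$normal, tolerance = 1e-12)
  # the interpolated mass is preserved (nothing cropped)
  expect_lt(abs(sum(res$values) - sum(grid$values)) / sum(grid$values),
            0.02)
  fg <- which(res$values > 500)
  ai <- arrayInd(fg, dim(res$values)) - 1L
  rng <- apply(ai, 2, range)
  expect_true(all(rng[1, ] > 0) && all(rng[2, ] < dim(res$values) - 1))
})

test_that("double reslicing reproduces a smooth grid within tolerance", {
  g <- fixture_geom(40, 0.5)
  w <- world_arrays(g)
  vals <- exp(-(w[[1]]^2 + w[[2]]^2 + w[[3]]^2) / 30) * 1000
  grid <- voxel_grid(vals, g$spacing, g$origin)
  tilt <- plane(c(0, 0, 0), c(sin(10 * pi / 180), 0, cos(10 * pi / 180)))
  fwd <- reslice_to_plane(grid, tilt)
  back <- reslice_to_plane(fwd, plane(c(0, 0, 0), c(0, 0, 1)))
  res <- cleftvol:::cpp_resample_lin(
    as.double(back$values), dim(back$values), back$spacing, back$origin,
    back$axes, g$dim, g$spacing, g$origin, diag(3), c(diag(3)), c(0, 0, 0),
    NA_real_)
  ok <- !is.na(res)
  expect_lt(mean(abs(res[ok] - grid$values[ok])) / 1000, 0.02)
})

test_that("mirroring reflects voxels exactly and is an involution", {
  g <- fixture_geom(20, 0.5)
  sag <- plane(c(0, 0, 0), c(1, 0, 0))
  ball <- ball_mask(g, centre = c(0, 1, -1), radius = 3)
  expect_equal(dice_coefficient(mirror_mask(ball, sag), ball), 1)

  # single voxel at +1.0 mm lands at -1.0 mm (closed-form reflection);
  # lattice chosen so that +/-1.0 are voxel centres
  g1 <- list(dim = c(20L, 20L, 20L), spacing = rep(0.5, 3),
             origin = c(-5, -5, -5), axes = diag(3))
  w1 <- world_arrays(g1)
  single <- mask_from(g1, abs(w1[[1]] - 1) < 0.2 &
                        abs(w1[[2]] - 0.5) < 0.2 &
                        abs(w1[[3]] - 0.5) < 0.2)
  expect_equal(sum(single$voxels), 1L)
  mirrored <- mirror_mask(single, sag)
  idx <- arrayInd(which(mirrored$voxels == 1L), g1$dim) - 1L
  wpt <- cleftvol:::index_to_world(g1, idx)
  expect_equal(as.double(wpt), c(-1, 0.5, 0.5), tolerance = 1e-9)

  # exact involution on a lattice-aligned plane, for an asymmetric mask
  blob <- mask_from(g, blob_mask(fixture_geom(20, 0.5)))
  twice <- mirror_mask(mirror_mask(blob, sag), sag)
  expect_identical(twice$voxels, blob$voxels)
})

test_that("double mirroring across arbitrary planes keeps Dice >= 0.98", {
  set.seed(42)
  m <- big_ellipsoid_mask()
  for (i in 1:3) {
    pl <- plane(runif(3, -2, 2), rnorm(3))
    twice <- mirror_mask(mirror_mask(m, pl), pl)
    expect_gte(dice_coefficient(twice, m), 0.98)
  }
})

test_that("resample_mask preserves volume under rigid motion", {
  g <- fixture_geom(32, 0.5)
  ball <- ball_mask(g, radius = 5)  # 20 voxels across
  ident <- resample_mask(ball, rigid_transform(), g)
  expect_identical(ident$voxels, ball$voxels)

  # exact lattice shift: one voxel along axis 1
  shift <- rigid_transform(diag(3), c(0.5, 0, 0))
  shifted <- resample_mask(ball, shift, g)
  expect_equal(sum(shifted$voxels), sum(ball$voxels))
  expect_identical(shifted$voxels[2:32, , ], ball$voxels[1:31, , ])

  set.seed(43)
  for (i in 1:5) {
    tf <- compose_transform(
      rigid_transform(diag(3), runif(3, -2, 2)),
      cleftvol:::rotation_about(rnorm(3), runif(1, -20, 20), c(0, 0, 0)))
    moved <- resample_mask(ball, tf, g)
    expect_lt(abs(measure_volume(moved) - measure_volume(ball)) /
                measure_volume(ball), 0.02)
  }
})

test_that("register_rigid recovers planted transforms on a blob model", {
  g <- fixture_geom(64, 0.5)
  fixed <- mask_from(g, blob_mask(g))
  com <- cleftvol:::mask_centroid(fixed)

  # moving identical to fixed: identity transform, Dice 1
  self <- register_rigid(fixed, fixed)
  expect_equal(self$overlap, 1)
  expect_lt(rotation_angle_deg(self$transform), 0.05)
  expect_lt(max(abs(self$transform$translation)), 0.05)

  # pure translation (anatomy re-rasterized at the moved pose)
  tf_t <- rigid_transform(diag(3), c(2, -1, 0.5))
  mv_t <- mask_from(g, blob_mask(g, tf_t))
  reg_t <- register_rigid(mv_t, fixed)
  err_t <- compose_transform(reg_t$transform, tf_t)
  expect_lt(max(abs(apply_transform(err_t, com) - com)),
            0.5 * max(g$spacing))
  expect_gte(reg_t$overlap, 0.95)

  # 5 degree rotation about the axial axis
  tf_r <- cleftvol:::rotation_about(c(0, 0, 1), 5, com)
  mv_r <- mask_from(g, blob_mask(g, tf_r))
  reg_r <- register_rigid(mv_r, fixed)
  err_r <- compose_transform(reg_r$transform, tf_r)
  expect_lt(rotation_angle_deg(err_r), 1)
  expect_gte(reg_r$overlap, 0.95)

  # bit-identical determinism
  reg_r2 <- register_rigid(mv_r, fixed)
  expect_identical(reg_r$transform, reg_r2$transform)
  expect_identical(reg_r$overlap, reg_r2$overlap)

  empty <- mask_from(g, array(FALSE, g$dim))
  expect_error(register_rigid(empty, fixed), "empty")
  expect_error(register_rigid(fixed, empty), "empty")
})
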