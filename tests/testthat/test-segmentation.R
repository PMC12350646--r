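test_that("dual thresholding merges bone and teeth windows inclusively", {
  gm <- fixture_geom(12, 1)
  spec <- threshold_spec(bone_low = 200, bone_high = 600, teeth_low = 700,
                         teeth_high = 1200, closing_radius_mm = 0)
  zeros <- voxel_grid(array(0, gm$dim), gm$spacing, gm$origin)
  expect_equal(sum(segment_dual_threshold(zeros, spec)$voxels), 0L)

  # two-blob phantom: bone blob at 300, tooth blob at 900
  w <- world_arrays(gm)
  bone_blob <- (w[[1]] + 2)^2 + w[[2]]^2 + w[[3]]^2 <= 6
  tooth_blob <- (w[[1]] - 3)^2 + w[[2]]^2 + w[[3]]^2 <= 4
  vals <- array(0, gm$dim)
  vals[bone_blob] <- 300
  vals[tooth_blob] <- 900
  g <- voxel_grid(vals, gm$spacing, gm$origin)
  seg <- segment_dual_threshold(g, spec)
  # brute-force voxelwise oracle
  expected <- array(0L, gm$dim)
  for (i in seq_along(vals))
    expected[i] <- as.integer((vals[i] >= 200 && vals[i] <= 600) ||
                                (vals[i] >= 700 && vals[i] <= 1200))
  expect_identical(seg$voxels, expected)
  expect_equal(sum(seg$voxels), sum(bone_blob) + sum(tooth_blob))

  # inclusive bounds on both ends of both windows
  for (v in c(200, 600, 700, 1200)) {
    g1 <- voxel_grid(array(v, c(2, 2, 2)), c(1, 1, 1))
    expect_equal(sum(segment_dual_threshold(g1, spec)$voxels), 8L)
  }
  g2 <- voxel_grid(array(199.999, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(sum(segment_dual_threshold(g2, spec)$voxels), 0L)
})

test_that("widening a threshold window never removes voxels", {
  set.seed(21)
  gm <- fixture_geom(10, 1)
  for (i in 1:8) {
    vals <- array(runif(prod(gm$dim), 0, 1500), gm$dim)
    g <- voxel_grid(vals, gm$spacing, gm$origin)
    narrow <- threshold_spec(300, 500, 800, 1000, closing_radius_mm = 0,
                             fill_internal = FALSE)
    wide <- threshold_spec(250, 600, 700, 1100, closing_radius_mm = 0,
                           fill_internal = FALSE)
    a <- segment_dual_threshold(g, narrow)$voxels
    b <- segment_dual_threshold(g, wide)$voxels
    expect_true(all(b[a == 1L] == 1L))
  }
})

test_that("the Euclidean distance transform matches brute force", {
  set.seed(24)
  for (trial in 1:15) {
    d <- sample(3:10, 3, replace = TRUE)
    sp <- sample(c(0.125, 0.25, 0.5, 1), 3, replace = TRUE)
    vox <- array(as.integer(runif(prod(d)) < 0.2), d)
    if (sum(vox) == 0) vox[1] <- 1L
    d2 <- cleftvol:::cpp_edt_sq(vox, d, sp)
    idx <- which(vox == 1L)
    pts <- t(t(arrayInd(idx, d) - 1L) * sp)
    bf <- vapply(seq_len(prod(d)), function(i) {
      ci <- (arrayInd(i, d) - 1L) * sp
      min(colSums((t(pts) - as.double(ci))^2))
    }, 0)
    expect_equal(as.double(d2), bf, tolerance = 1e-12)
  }
})

test_that("fill_gaps closes thin cracks, is extensive and idempotent", {
  gm <- fixture_geom(20, 1)
  # hollow box with a single-voxel crack in its 1-voxel cortical wall
  outer <- box_mask(gm, c(-5, -5, -5), c(5, 5, 5))
  inner <- box_mask(gm, c(-4, -4, -4), c(4, 4, 4))
  wall <- mask_subtract(outer, inner)
  w <- world_arrays(gm)
  cracked <- wall
  idx <- which(w[[1]] > 4 & w[[1]] < 5 & w[[2]] > 0 & w[[2]] < 1 &
                 w[[3]] > 0 & w[[3]] < 1)
  expect_equal(length(idx), 1L)
  cracked$voxels[idx] <- 0L
  expect_gt(sum(wall$voxels), sum(cracked$voxels))

  # radius 0 is the identity
  expect_identical(fill_gaps(cracked, 0)$voxels, cracked$voxels)

  # 1.5 voxels: above the voxel diagonal, so the ball cannot thread the
  # crack mouth and the wall closes
  closed <- fill_gaps(cracked, 1.5)
  # crack bridged: the interior cavity is sealed off from the border again
  reach <- cleftvol:::cpp_border_background(closed$voxels,
                                            dim(closed$voxels))
  centre_idx <- which(w[[1]] > 0 & w[[1]] < 1 & w[[2]] > 0 & w[[2]] < 1 &
                        w[[3]] > 0 & w[[3]] < 1)
  expect_equal(length(centre_idx), 1L)
  expect_true(all(reach[centre_idx] == 0L))
  # extensive
  expect_true(all(closed$voxels[cracked$voxels == 1L] == 1L))
  # idempotent
  expect_identical(fill_gaps(closed, 1.5)$voxels, closed$voxels)

  # closing a convex solid leaves it unchanged
  cube <- box_mask(gm, c(-4, -4, -4), c(4, 4, 4))
  expect_identical(fill_gaps(cube, 1.5)$voxels, cube$voxels)
})

test_that("fill_internal fills enclosed cavities but not open concavities", {
  gm <- fixture_geom(24, 0.5)
  ball <- ball_mask(gm, radius = 4)
  core <- ball_mask(gm, radius = 2.5)
  shell <- mask_subtract(ball, core)
  filled <- fill_internal(shell)
  expect_identical(filled$voxels, ball$voxels)
  expect_equal(sum(filled$voxels), sum(shell$voxels) + sum(core$voxels))

  # an open notch (connected to the outside) must not be filled
  cup <- box_mask(gm, c(-3, -3, -3), c(3, 3, 3))
  notch <- box_mask(gm, c(-1, -1, 0), c(1, 1, 3.5))
  cup <- mask_subtract(cup, notch)
  expect_identical(fill_internal(cup)$voxels, cup$voxels)

  empty <- mask_from(gm, array(FALSE, gm$dim))
  expect_equal(sum(fill_internal(empty)$voxels), 0L)
})

test_that("segment_case recovers the phantom bone model", {
  ph <- generate_phantom(small_phantom_spec(seed = 31))
  seg <- segment_case(ph$v0_grid, ph$config$thresholds)
  truth <- ph$truth$true_bone_volume_v0
  expect_lt(abs(measure_volume(seg) - truth) / truth, 0.02)

  # with noise disabled the recovery is voxel-exact
  ph0 <- generate_phantom(small_phantom_spec(seed = 32, noise_sd = 0,
                                             misalign_max_t_mm = 0,
                                             misalign_max_rot_deg = 0))
  seg0 <- segment_case(ph0$v0_grid, ph0$config$thresholds)
  expect_identical(seg0$voxels, ph0$clean_masks$v0$voxels)
  seg2 <- segment_case(ph0$v2_grid, ph0$config$thresholds)
  expect_identical(seg2$voxels, ph0$clean_masks$v2$voxels)

  # all-air grid segments to an empty model
  air <- voxel_grid(array(0, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(sum(segment_case(air, threshold_spec())$voxels), 0L)
})

test_that("cancellous fill can be disabled to retain cavities", {
  gm <- fixture_geom(24, 0.5)
  ball <- ball_mask(gm, radius = 4)
  core <- ball_mask(gm, radius = 2.5)
  shell <- mask_subtract(ball, core)
  vals <- array(0, gm$dim)
  vals[shell$voxels == 1L] <- 400
  g <- voxel_grid(vals, gm$spacing, gm$origin)
  spec_off <- threshold_spec(closing_radius_mm = 0, fill_internal = FALSE)
  expect_identical(segment_case(g, spec_off)$voxels, shell$voxels)
  spec_on <- threshold_spec(closing_radius_mm = 0, fill_internal = TRUE)
  expect_identical(segment_case(g, spec_on)$voxels, ball$voxels)
})
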