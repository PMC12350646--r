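# Shared fixtures: all geometry is built in code at test time.

# Axis-aligned lattice centred on the world origin.
fixture_geom <- function(dim, spacing) {
  dim <- as.integer(rep(dim, length.out = 3))
  spacing <- rep(spacing, length.out = 3)
  list(dim = dim, spacing = spacing, origin = -(dim - 1) / 2 * spacing,
       axes = diag(3))
}

world_arrays <- function(g) cleftvol:::world_coord_arrays(g)

mask_from <- function(g, logical_arr, label = "") {
  binary_mask(array(as.integer(logical_arr), g$dim), g$spacing, g$origin,
              label = label)
}

ball_mask <- function(g, centre = c(0, 0, 0), radius = 4) {
  w <- world_arrays(g)
  mask_from(g, (w[[1]] - centre[1])^2 + (w[[2]] - centre[2])^2 +
              (w[[3]] - centre[3])^2 <= radius^2)
}

box_mask <- function(g, lower, upper) {
  w <- world_arrays(g)
  mask_from(g, w[[1]] >= lower[1] & w[[1]] <= upper[1] &
              w[[2]] >= lower[2] & w[[2]] <= upper[2] &
              w[[3]] >= lower[3] & w[[3]] <= upper[3])
}

random_mask <- function(dim = 16, p = 0.5) {
  d <- as.integer(rep(dim, length.out = 3))
  binary_mask(array(as.integer(stats::runif(prod(d)) < p), d), c(1, 1, 1))
}

# Asymmetric three-ellipsoid solid: enough voxels and asymmetry to pin a
# rigid pose; rasterized analytically at an arbitrary pose.
blob_mask <- function(g, pose = NULL) {
  w <- world_arrays(g)
  if (is.null(pose)) {
    x <- w[[1]]; y <- w[[2]]; z <- w[[3]]
  } else {
    inv <- invert_transform(pose)
    r <- inv$rotation; tv <- inv$translation
    x <- r[1, 1] * w[[1]] + r[1, 2] * w[[2]] + r[1, 3] * w[[3]] + tv[1]
    y <- r[2, 1] * w[[1]] + r[2, 2] * w[[2]] + r[2, 3] * w[[3]] + tv[2]
    z <- r[3, 1] * w[[1]] + r[3, 2] * w[[2]] + r[3, 3] * w[[3]] + tv[3]
  }
  b <- (x^2 / 100 + y^2 / 49 + z^2 / 144) <= 1
  b <- b | (((x - 6)^2 + (y - 4)^2 / 4 + (z + 7)^2) <= 16)
  b | (((x + 7)^2 / 2 + (y + 3)^2 + (z - 6)^2) <= 9)
}

# Coarser phantom for fast module-level tests (same anatomy, 40 mm FOV).
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(96L, 96L, 96L),
               spacing_mm = rep(5 / 12, 3), ...)
}

# Large smooth ellipsoid: double nearest-neighbour mirroring flips a
# fraction of surface voxels, so the involution Dice bound needs a
# model-scale solid (low surface-to-volume), like a real maxilla model.
big_ellipsoid_mask <- function() {
  g <- fixture_geom(96, 0.5)
  w <- world_arrays(g)
  mask_from(g, w[[1]]^2 / 400 + w[[2]]^2 / 256 + w[[3]]^2 / 324 <= 1)
}

# Read a binary STL and compute the enclosed volume by the divergence
# theorem (independent of the marching-tetrahedra exporter).
read_stl_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  vol <- 0
  for (i in seq_len(n)) {
    dat <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    p0 <- dat[4:6]; p1 <- dat[7:9]; p2 <- dat[10:12]
    vol <- vol + sum(p0 * c(p1[2] * p2[3] - p1[3] * p2[2],
                            p1[3] * p2[1] - p1[1] * p2[3],
                            p1[1] * p2[2] - p1[2] * p2[1])) / 6
  }
  list(triangles = n, volume = vol)
}

# Cached end-to-end phantom suites shared by the acceptance tests.
.suite_cache <- new.env(parent = emptyenv())

phantom_suite <- function(clean = FALSE, seeds = 1:20) {
  key <- paste0(if (clean) "clean" else "noisy", "_",
                paste(range(seeds), collapse = "-"))
  if (!is.null(.suite_cache[[key]])) return(.suite_cache[[key]])
  runs <- lapply(seeds, function(s) {
    sp <- if (clean)
      phantom_spec(seed = s, noise_sd = 0, misalign_max_t_mm = 0,
                   misalign_max_rot_deg = 0)
    else phantom_spec(seed = s)
    ph <- generate_phantom(sp)
    rep <- analyze_case(ph$v0_grid, ph$v1_grid, ph$v2_grid,
                        thresholds = ph$config$thresholds,
                        occlusal = ph$config$occlusal_plane,
                        sagittal = ph$config$sagittal_plane,
                        trim = ph$config$trim_box,
                        smoothing_radius_mm = ph$config$smoothing_radius_mm,
                        case_id = sprintf("seed%02d", s))
    # drop the intermediate masks: caching 20 cases of full-resolution
    # volumes would exhaust memory
    attr(rep, "details") <- NULL
    list(report = rep,
         truth = ph$truth[c("true_bone_volume_v0", "true_cleft_volume",
                            "true_graft_volume", "true_integrated_volume",
                            "true_missing_volume")])
  })
  .suite_cache[[key]] <- runs
  runs
}

suite_errors_pct <- function(runs) {
  t(vapply(runs, function(r) {
    tr <- r$truth
    truth <- c(cleft = tr$true_cleft_volume, graft = tr$true_graft_volume,
               integrated = tr$true_integrated_volume,
               resorption = tr$true_graft_volume -
                 tr$true_integrated_volume,
               missing = tr$true_missing_volume)
    meas <- c(r$report$v_cleft_mm3, r$report$v_graft_mm3,
              r$report$v_integrated_mm3, r$report$v_resorption_mm3,
              r$report$v_missing_mm3)
    100 * abs(meas - truth) / truth
  }, numeric(5)))
}
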