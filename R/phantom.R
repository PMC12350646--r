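#' Specification of the synthetic maxilla phantom
#'
#' The phantom emulates the clinical triple-timepoint CBCT situation on a
#' desk-scale lattice: a horseshoe-shaped maxillary arch symmetric about
#' the mid-sagittal plane, a unilateral through-and-through cleft wedge on
#' the right side (V0), a graft overfilling the cleft (V1), partial
#' marginal resorption of the graft at follow-up (V2), high-intensity
#' tooth spheres, soft-tissue background, rigid inter-timepoint
#' misalignment and additive Gaussian noise. All randomness (misalignment
#' draws, noise fields) is fixed by `seed`.
#'
#' Intensities are generator units (CBCT grey values are device specific):
#' air 0, soft tissue 80, bone 400, graft 450, teeth 1000 by default, so
#' the standard windows bone `[200, 700]` / teeth `[700, 2000]` segment the
#' phantom cleanly.
#'
#' @param grid_shape Voxels per axis (default 160^3).
#' @param spacing_mm Voxel spacing (default 0.25 mm isotropic, coarser than
#'   clinical CBCT so a full validation suite runs in minutes).
#' @param arch_outer_radius_mm,arch_thickness_mm,arch_height_mm,arch_span_deg,arch_center_y_mm
#'   Arch geometry: outer radius, radial thickness, vertical height, total
#'   angular span, and the y offset of the arch centre.
#' @param cleft_angle_deg Angular position of the cleft centre (degrees
#'   from the anterior midline, positive to the patient's right / +x).
#' @param cleft_width_mm Arc width of the cleft at mid-radius; 0 gives a
#'   symmetric (cleft-free) phantom.
#' @param cleft_depth_mm Radial depth of the wedge from the outer surface.
#' @param overfill_factor Graft volume as a multiple of the cleft volume
#'   (>= 0; > 1 means overfilled, the clinical norm).
#' @param graft_width_scale Angular widening of the graft wedge relative
#'   to the cleft (overfill spills sideways over the bone).
#' @param resorption_fraction Fraction of the graft volume lost at V2, in
#'   `[0, 1]`; resorption proceeds inward from the graft's free surface.
#' @param misalign_max_t_mm,misalign_max_rot_deg Per-axis translation and
#'   rotation bounds of the rigid misalignment applied to V1 and V2.
#' @param tooth_count Even number of tooth spheres (symmetric pairs).
#' @param tooth_radius_mm Tooth sphere radius.
#' @param noise_sd Gaussian noise SD in grey units (0 disables).
#' @param intensities Named vector `air, soft, bone, graft, teeth`.
#' @param seed Integer seed fixing all randomness.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(160L, 160L, 160L),
                         spacing_mm = c(0.25, 0.25, 0.25),
                         arch_outer_radius_mm = 15, arch_thickness_mm = 6,
                         arch_height_mm = 18, arch_span_deg = 220,
                         arch_center_y_mm = 4, cleft_angle_deg = 30,
                         cleft_width_mm = 9, cleft_depth_mm = 6,
                         overfill_factor = 1.36, graft_width_scale = 1.25,
                         resorption_fraction = 0.57, misalign_max_t_mm = 3,
                         misalign_max_rot_deg = 5, tooth_count = 6L,
                         tooth_radius_mm = 2.2, noise_sd = 25,
                         intensities = c(air = 0, soft = 80, bone = 400,
                                         graft = 450, teeth = 1000),
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.double(spacing_mm),
               arch_outer_radius_mm = arch_outer_radius_mm,
               arch_thickness_mm = arch_thickness_mm,
               arch_height_mm = arch_height_mm,
               arch_span_deg = arch_span_deg,
               arch_center_y_mm = arch_center_y_mm,
               cleft_angle_deg = cleft_angle_deg,
               cleft_width_mm = cleft_width_mm,
               cleft_depth_mm = cleft_depth_mm,
               overfill_factor = overfill_factor,
               graft_width_scale = graft_width_scale,
               resorption_fraction = resorption_fraction,
               misalign_max_t_mm = misalign_max_t_mm,
               misalign_max_rot_deg = misalign_max_rot_deg,
               tooth_count = as.integer(tooth_count),
               tooth_radius_mm = tooth_radius_mm, noise_sd = noise_sd,
               intensities = intensities, seed = as.integer(seed))
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("grid_shape must be three values >= 8")
    if (any(spacing_mm <= 0)) stop("spacing must be positive")
    lens <- c(arch_outer_radius_mm, arch_thickness_mm, arch_height_mm,
              tooth_radius_mm)
    if (any(lens <= 0)) stop("phantom lengths must be positive")
    if (arch_thickness_mm >= arch_outer_radius_mm)
      stop("arch thickness must be smaller than the outer radius")
    if (cleft_width_mm < 0 || cleft_depth_mm <= 0)
      stop("cleft dimensions must be nonnegative (width) / positive (depth)")
    if (overfill_factor < 0) stop("overfill_factor must be >= 0")
    if (resorption_fraction < 0 || resorption_fraction > 1)
      stop("resorption_fraction must lie in [0, 1]")
    if (misalign_max_t_mm < 0 || misalign_max_rot_deg < 0)
      stop("misalignment bounds must be >= 0")
    if (tooth_count %% 2L != 0L) stop("tooth_count must be even")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
  })
  # the (possibly widened) wedge must stay inside the arch span and clear
  # of the mid-sagittal plane
  geo <- phantom_geometry(spec)
  half_deg <- geo$graft_halfang * 180 / pi
  if (spec$cleft_width_mm > 0) {
    if (spec$cleft_angle_deg + half_deg > spec$arch_span_deg / 2)
      stop("cleft wedge extends outside the arch span")
    if (spec$cleft_angle_deg - half_deg < 2)
      stop("cleft wedge crosses the mid-sagittal region")
  }
  structure(spec, class = "phantom_spec")
}

# Derived continuous geometry shared by rasterization and analytic truth.
phantom_geometry <- function(spec) {
  r_out <- spec$arch_outer_radius_mm
  r_in <- r_out - spec$arch_thickness_mm
  r_mid <- r_out - spec$arch_thickness_mm / 2
  halfang <- (spec$cleft_width_mm / 2) / r_mid  # radians
  r_floor <- max(r_in, r_out - spec$cleft_depth_mm)
  a_cleft <- halfang * (r_out^2 - r_floor^2)    # wedge cross-section area
  cleft_vol <- a_cleft * spec$arch_height_mm
  o <- spec$overfill_factor
  lambda <- spec$graft_width_scale
  if (spec$cleft_width_mm == 0 || o == 0) {
    graft <- list(halfang = halfang, r_lo = r_floor, r_hi = r_floor,
                  vol = 0)
  } else if (o >= 1) {
    # widen sideways and extend radially outward to hit o * cleft volume
    r_hi <- sqrt(r_out^2 + (o - 1) * (r_out^2 - r_floor^2) / lambda)
    graft <- list(halfang = halfang * lambda, r_lo = r_floor, r_hi = r_hi,
                  vol = o * cleft_vol)
  } else {
    # underfill: same angle, reduced radial depth
    r_lo <- sqrt(r_out^2 - o * (r_out^2 - r_floor^2))
    graft <- list(halfang = halfang, r_lo = r_lo, r_hi = r_out,
                  vol = o * cleft_vol)
  }
  npair <- spec$tooth_count %/% 2L
  tooth_angles <- if (npair == 0L) numeric(0)
  else if (npair == 1L) 60 else seq(60, 104, length.out = npair)
  list(r_out = r_out, r_in = r_in, r_mid = r_mid, halfang = halfang,
       r_floor = r_floor, cleft_vol = cleft_vol,
       graft_halfang = graft$halfang, graft_r_lo = graft$r_lo,
       graft_r_hi = graft$r_hi, graft_vol = graft$vol,
       tooth_angles = tooth_angles)
}

# Membership arrays for every phantom shape on a lattice, optionally
# through a rigid map (anatomy coordinates y = R x + t). The heavy
# per-voxel evaluation is a single C++ pass returning bit codes.
phantom_shapes <- function(spec, geom, map = NULL) {
  geo <- phantom_geometry(spec)
  if (is.null(map)) {
    mr <- diag(3)
    mt <- c(0, 0, 0)
  } else {
    mr <- map$rotation
    mt <- map$translation
  }
  nt <- length(geo$tooth_angles) * 2L
  teeth <- matrix(numeric(0), 3, 0)
  if (nt > 0) {
    a <- c(-geo$tooth_angles, geo$tooth_angles) * pi / 180
    teeth <- rbind(geo$r_mid * sin(a),
                   spec$arch_center_y_mm - geo$r_mid * cos(a),
                   rep(spec$arch_height_mm / 2, nt))
  }
  code <- cpp_phantom_shapes(
    geom$dim, geom$spacing, geom$origin, c(mr), mt,
    spec$arch_center_y_mm, geo$r_in, geo$r_out,
    spec$arch_span_deg * pi / 360, spec$arch_height_mm / 2,
    spec$cleft_angle_deg * pi / 180, geo$halfang, geo$r_floor,
    geo$graft_halfang, geo$graft_r_lo, geo$graft_r_hi,
    spec$cleft_width_mm > 0, geo$graft_vol > 0, teeth,
    spec$tooth_radius_mm, geo$r_out + 3.5, spec$arch_height_mm / 2 + 5)
  d <- geom$dim
  list(bone = array(bitwAnd(code, 1L) > 0L, d),
       cleft = array(bitwAnd(code, 2L) > 0L, d),
       graft = array(bitwAnd(code, 4L) > 0L, d),
       teeth = array(bitwAnd(code, 8L) > 0L, d),
       head = array(bitwAnd(code, 16L) > 0L, d))
}

#' Generate a triple-timepoint phantom case with exact ground truth
#'
#' Rasterizes the phantom of a [phantom_spec()] on the V0 lattice, derives
#' the clean (noise-free, aligned) masks of the three timepoints, computes
#' the ground-truth volumes by exact voxel counting on those masks, and
#' paints the three grey CBCT-like volumes — V1 and V2 rigidly misaligned
#' by seeded random transforms, all three with Gaussian noise. The
#' resorbed graft at V2 is the deepest-from-the-free-surface fraction of
#' the graft (distance-transform order statistics), so the requested
#' retained volume is hit to within one voxel.
#'
#' @param spec A [phantom_spec()].
#' @param dir If non-NULL, NIfTI volumes, a ready-to-run case config
#'   (`case.yaml`) and a truth manifest (`truth.json`) are written there.
#' @return List with `v0_grid`, `v1_grid`, `v2_grid` ([voxel_grid()]s),
#'   `truth` (a `phantom_truth`), `clean_masks` (V0/V1/V2
#'   [binary_mask()]s before misalignment and noise), and `config` (the
#'   case configuration used by [run_case()]/[analyze_case()]).
#' @export
generate_phantom <- function(spec = phantom_spec(), dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  geo <- phantom_geometry(spec)
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  origin <- -(d - 1) / 2 * sp  # lattice centred on the world origin
  geom <- list(dim = d, spacing = sp, origin = origin, axes = diag(3))
  vv <- prod(sp)

  # --- clean masks on the V0 lattice ---------------------------------------
  # The cleft wedge and the graft body get rounded edges (morphological
  # opening at the smoothing radius): real bone defects have no razor
  # edges, and opening-invariant solids make the pipeline's contour
  # smoothing idempotent on the phantom instead of a corner-shaving bias.
  sh <- phantom_shapes(spec, geom)
  rs <- phantom_smoothing_radius()
  open_mask <- function(m) {
    e <- morpho_ball(array(as.integer(m), d), d, sp, rs, "erode")
    morpho_ball(e, d, sp, rs, "dilate") == 1L
  }
  wedge <- open_mask(sh$cleft)
  v0_clean <- (sh$bone | (sh$cleft & !wedge)) | sh$teeth
  cleft_clean <- wedge & !v0_clean
  graft_only <- open_mask(sh$graft & !v0_clean)
  v1_clean <- v0_clean | graft_only

  # resorption proceeds inward from the exposed outer (buccal) margin:
  # the eroding front is the free space outside the arch mid-radius
  wc <- world_coord_arrays(geom)
  geo_r <- sqrt(wc[[1]]^2 + (wc[[2]] - spec$arch_center_y_mm)^2)
  resorb_source <- !v1_clean & geo_r > geo$r_mid
  e_mask <- resorb_graft(graft_only, resorb_source, abs(wc[[3]]), d, sp,
                         spec$resorption_fraction)
  rm(wc, geo_r)
  v2_clean <- v0_clean | e_mask

  truth_vols <- c(
    true_bone_volume_v0 = sum(v0_clean) * vv,
    true_cleft_volume = sum(cleft_clean) * vv,
    true_graft_volume = sum(graft_only) * vv,
    true_integrated_volume = sum(e_mask) * vv,
    true_missing_volume = sum(cleft_clean & !e_mask) * vv)

  # --- misalignment draws (V1, V2), rotation about the arch centre ---------
  centre <- c(0, spec$arch_center_y_mm, 0)
  draw_misalign <- function() {
    tr <- runif(3, -spec$misalign_max_t_mm, spec$misalign_max_t_mm)
    ax <- rnorm(3)
    ang <- runif(1, -spec$misalign_max_rot_deg, spec$misalign_max_rot_deg)
    if (spec$misalign_max_rot_deg == 0 || sqrt(sum(ax^2)) < 1e-9) {
      rot <- rigid_transform()
    } else {
      rot <- rotation_about(ax, ang, centre)
    }
    if (spec$misalign_max_t_mm == 0) tr <- c(0, 0, 0)
    compose_transform(rigid_transform(diag(3), tr), rot)
  }
  m1 <- draw_misalign()  # maps V1 world -> V0 anatomy world
  m2 <- draw_misalign()

  # --- grey volumes ---------------------------------------------------------
  ints <- spec$intensities
  identity_map <- function(map) {
    is.null(map) || (max(abs(map$rotation - diag(3))) < 1e-12 &&
                       max(abs(map$translation)) < 1e-12)
  }
  paint <- function(map, graft_region) {
    if (identity_map(map)) {
      map <- NULL
      s <- sh  # reuse the identity-frame shapes
    } else {
      s <- phantom_shapes(spec, geom, map)
    }
    vals <- array(ints[["air"]], d)
    vals[s$head] <- ints[["soft"]]
    greg <- if (is.null(graft_region)) {
      NULL
    } else {  # voxel set defined on the V0 lattice, carried through map
      if (is.null(map)) {
        graft_region
      } else {
        array(cpp_resample_nn(array(as.integer(graft_region), d), d, sp,
                              origin, diag(3), d, sp, origin, diag(3),
                              c(map$rotation), map$translation) == 1L, d)
      }
    }
    if (!is.null(greg)) vals[greg] <- ints[["graft"]]
    vals[s$bone] <- ints[["bone"]]
    vals[s$teeth] <- ints[["teeth"]]
    if (spec$noise_sd > 0)
      vals <- vals + array(rnorm(prod(d), 0, spec$noise_sd), d)
    voxel_grid(vals, spacing = sp, origin = origin)
  }
  v0_grid <- paint(NULL, NULL)
  v1_grid <- paint(m1, graft_only)
  v2_grid <- paint(m2, e_mask)

  # --- annotations ----------------------------------------------------------
  sagittal <- plane(c(0, 0, 0), c(1, 0, 0))
  occlusal <- plane(c(0, 0, 0), c(0, 0, 1))
  tb <- phantom_trim_box(spec, cleft_clean | graft_only, geom)

  truth <- structure(c(as.list(truth_vols), list(
    transform_v1_to_v0 = m1, transform_v2_to_v0 = m2, sagittal = sagittal,
    occlusal = occlusal, trim_box = tb, truth_basis = "voxel",
    spec = spec)), class = "phantom_truth")
  validate_phantom_truth(truth, vv)

  config <- list(case_id = sprintf("phantom_seed%03d", spec$seed),
                 volumes = list(v0 = "v0.nii.gz", v1 = "v1.nii.gz",
                                v2 = "v2.nii.gz"),
                 thresholds = phantom_threshold_spec(),
                 occlusal_plane = occlusal, sagittal_plane = sagittal,
                 trim_box = tb,
                 smoothing_radius_mm = phantom_smoothing_radius(),
                 registration_control = list())

  out <- list(v0_grid = v0_grid, v1_grid = v1_grid, v2_grid = v2_grid,
              truth = truth,
              clean_masks = list(
                v0 = binary_mask(array(as.integer(v0_clean), d), sp, origin,
                                 label = "V0"),
                v1 = binary_mask(array(as.integer(v1_clean), d), sp, origin,
                                 label = "V1"),
                v2 = binary_mask(array(as.integer(v2_clean), d), sp, origin,
                                 label = "V2"),
                cleft = binary_mask(array(as.integer(cleft_clean), d), sp,
                                    origin, label = "cleft"),
                graft = binary_mask(array(as.integer(graft_only), d), sp,
                                    origin, label = "graft"),
                integrated = binary_mask(array(as.integer(e_mask), d), sp,
                                         origin, label = "integrated")),
              config = config)
  if (!is.null(dir)) write_phantom_case(out, dir)
  out
}

# Contour-smoothing radius used both to round the phantom's edges and in
# the emitted case config: the two must agree for smoothing idempotence.
phantom_smoothing_radius <- function() 0.3

# Thresholds matched to the generator's intensity levels. The phantom
# paints crisp boundaries (no partial-volume blur), so the emitted config
# disables gap closing: there are no sub-voxel gaps to close and a nonzero
# radius would fillet concave junctions, i.e. alter the anatomy.
phantom_threshold_spec <- function() {
  threshold_spec(bone_low = 200, bone_high = 700, teeth_low = 700,
                 teeth_high = 2000, closing_radius_mm = 0,
                 fill_internal = TRUE)
}

# Deepest-from-the-resorbing-front selection of the retained graft.
# Depth is the Euclidean distance to `source` (the exposed free surface),
# so the bone-graft interface does not count as a resorbing margin and the
# surviving graft remains a coherent wall-adjacent body.
resorb_graft <- function(graft_only, source, absz, d, sp, fraction) {
  n_g <- sum(graft_only)
  if (n_g == 0) return(graft_only & FALSE)
  keep_n <- round((1 - fraction) * n_g)
  achieved <- keep_n / n_g
  if (abs(achieved - (1 - fraction)) > 0.02)
    stop(sprintf(paste0("cannot realize resorption fraction %.3f on a ",
                        "%d-voxel graft within 2%% tolerance"),
                 fraction, n_g))
  if (keep_n == 0) return(graft_only & FALSE)
  d2 <- cpp_edt_sq(array(as.integer(source), d), d, sp)
  idx <- which(graft_only)
  # keep the deepest voxels; ties on the discrete iso-depth shells are
  # broken by |z| (the top/bottom margins resorb first) so the surviving
  # body has a geometrically coherent, smooth boundary
  ord <- order(d2[idx], -absz[idx], idx, decreasing = TRUE)
  keep <- array(FALSE, d)
  keep[idx[ord[seq_len(keep_n)]]] <- TRUE
  keep
}

# Axis-aligned box around the cleft + graft region with a 1.5 mm margin;
# for a cleft-free phantom a nominal box on the would-be cleft side.
phantom_trim_box <- function(spec, region, geom) {
  margin <- 1.5
  if (any(region)) {
    idx <- which(region)
    ai <- arrayInd(idx, geom$dim) - 1L
    wpts <- index_to_world(geom, ai)
    lo <- apply(wpts, 2, min) - margin
    hi <- apply(wpts, 2, max) + margin
  } else {
    geo <- phantom_geometry(spec)
    phic <- spec$cleft_angle_deg * pi / 180
    cx <- geo$r_mid * sin(phic)
    cy <- spec$arch_center_y_mm - geo$r_mid * cos(phic)
    lo <- c(cx - 4, cy - 4, -spec$arch_height_mm / 2 - 1)
    hi <- c(cx + 4, cy + 4, spec$arch_height_mm / 2 + 1)
  }
  lo[1] <- max(lo[1], 0.25)  # never reach across the mid-sagittal plane
  trim_box(lo, hi)
}

validate_phantom_truth <- function(truth, voxel_vol) {
  with(truth, {
    vols <- c(true_bone_volume_v0, true_cleft_volume, true_graft_volume,
              true_integrated_volume, true_missing_volume)
    stopifnot(all(vols >= 0))
    f <- spec$resorption_fraction
    if (abs(true_integrated_volume - (1 - f) * true_graft_volume) >
        voxel_vol + 1e-9)
      stop("resorption calibration violated the one-voxel tolerance")
  })
  invisible(truth)
}

#' Write a generated phantom case to disk
#'
#' Emits `v0/v1/v2.nii.gz`, a ready-to-run `case.yaml` and a
#' `truth.json` manifest into `dir`.
#'
#' @param phantom The list returned by [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(phantom$v0_grid, file.path(dir, "v0.nii.gz"))
  write_volume(phantom$v1_grid, file.path(dir, "v1.nii.gz"))
  write_volume(phantom$v2_grid, file.path(dir, "v2.nii.gz"))
  write_case_config(phantom$config, file.path(dir, "case.yaml"))
  tr <- phantom$truth
  ser <- list(
    volumes_mm3 = list(
      true_bone_volume_v0 = tr$true_bone_volume_v0,
      true_cleft_volume = tr$true_cleft_volume,
      true_graft_volume = tr$true_graft_volume,
      true_integrated_volume = tr$true_integrated_volume,
      true_missing_volume = tr$true_missing_volume),
    transform_v1_to_v0 = transform_to_matrix(tr$transform_v1_to_v0),
    transform_v2_to_v0 = transform_to_matrix(tr$transform_v2_to_v0),
    sagittal = unclass(tr$sagittal), occlusal = unclass(tr$occlusal),
    trim_box = unclass(tr$trim_box), truth_basis = tr$truth_basis,
    seed = tr$spec$seed)
  jsonlite::write_json(ser, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Generate a synthetic cohort with planted effects
#'
#' Samples per-case phantom parameters — cleft width (hence cleft volume),
#' overfill factor and resorption fraction — from uniform template ranges,
#' optionally planting a target Pearson correlation between the filling
#' rate and the cleft volume (the filling rate equals 100 x overfill by
#' construction, so the plant acts on the overfill draw). By default only
#' the per-case manifest with analytic (continuous-geometry) truth volumes
#' is produced, which is what cohort-statistics validation needs; with
#' `rasterize = TRUE` every case is generated in full via
#' [generate_phantom()] and the manifest carries exact voxel-count truth.
#'
#' @param n Number of cases (>= 2).
#' @param template A [phantom_spec()] supplying all non-varied parameters.
#' @param seed Integer seed for all draws.
#' @param ranges List of `c(lo, hi)` uniform ranges for `cleft_width_mm`,
#'   `overfill_factor`, `resorption_fraction` (lo == hi gives a
#'   zero-variance cohort).
#' @param planted_filling_cleft_r Target correlation between filling rate
#'   and cleft volume, or `NULL` for independent draws.
#' @param rasterize Generate full image volumes per case.
#' @param dir Output directory (required when `rasterize = TRUE` with
#'   file output; each case goes to `dir/case_###`).
#' @return A `phantom_cohort`: list with `manifest` (data frame of per-case
#'   parameters and truth volumes), `truth_basis`, and (if rasterized)
#'   `cases` (the per-case [generate_phantom()] outputs).
#' @export
generate_cohort <- function(n, template = phantom_spec(), seed = 1L,
                            ranges = list(cleft_width_mm = c(4.5, 7.5),
                                          overfill_factor = c(1.05, 1.75),
                                          resorption_fraction = c(0.35, 0.78)),
                            planted_filling_cleft_r = -0.55,
                            rasterize = FALSE, dir = NULL) {
  if (n < 2) stop("cohorts need n >= 2 cases")
  for (nm in c("cleft_width_mm", "overfill_factor", "resorption_fraction")) {
    rg <- ranges[[nm]]
    if (is.null(rg) || length(rg) != 2L || any(!is.finite(rg)) ||
        rg[1] > rg[2])
      stop("invalid range for ", nm)
  }
  if (!is.null(planted_filling_cleft_r) &&
      abs(planted_filling_cleft_r) > 1)
    stop("planted correlation must lie in [-1, 1]")
  set.seed(as.integer(seed))
  widths <- runif(n, ranges$cleft_width_mm[1], ranges$cleft_width_mm[2])
  resorp <- runif(n, ranges$resorption_fraction[1],
                  ranges$resorption_fraction[2])
  case_seeds <- sample.int(100000000L, n)

  cleft_vols <- vapply(widths, function(wd) {
    sp <- template
    sp$cleft_width_mm <- wd
    phantom_geometry(sp)$cleft_vol
  }, 0)

  o_rg <- ranges$overfill_factor
  mu_o <- mean(o_rg)
  sd_o <- diff(o_rg) / 4
  eps <- rnorm(n)
  if (is.null(planted_filling_cleft_r) || sd_o == 0) {
    overfill <- runif(n, o_rg[1], o_rg[2])
  } else {
    r <- planted_filling_cleft_r
    z <- if (sd(cleft_vols) > 0) as.numeric(scale(cleft_vols)) else
      rep(0, n)
    overfill <- mu_o + sd_o * (r * z + sqrt(1 - r^2) * eps)
    overfill <- pmin(pmax(overfill, max(0.02, o_rg[1] - 2 * sd_o)),
                     o_rg[2] + 2 * sd_o)
  }

  specs <- lapply(seq_len(n), function(i) {
    sp <- unclass(template)
    sp$cleft_width_mm <- widths[i]
    sp$overfill_factor <- overfill[i]
    sp$resorption_fraction <- resorp[i]
    sp$seed <- case_seeds[i]
    do.call(phantom_spec, sp)
  })

  cases <- NULL
  if (rasterize) {
    cases <- lapply(seq_len(n), function(i) {
      case_dir <- if (!is.null(dir))
        file.path(dir, sprintf("case_%03d", i)) else NULL
      generate_phantom(specs[[i]], dir = case_dir)
    })
    truth_rows <- lapply(cases, function(cs) {
      tr <- cs$truth
      c(true_cleft_volume = tr$true_cleft_volume,
        true_graft_volume = tr$true_graft_volume,
        true_integrated_volume = tr$true_integrated_volume,
        true_missing_volume = tr$true_missing_volume)
    })
    basis <- "voxel"
  } else {
    truth_rows <- lapply(specs, function(sp) {
      geo <- phantom_geometry(sp)
      vg <- geo$graft_vol
      vi <- (1 - sp$resorption_fraction) * vg
      c(true_cleft_volume = geo$cleft_vol, true_graft_volume = vg,
        true_integrated_volume = vi,
        true_missing_volume = max(0, geo$cleft_vol - vi))
    })
    basis <- "analytic"
  }
  tm <- do.call(rbind, truth_rows)
  manifest <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n)), seed = case_seeds,
    cleft_width_mm = widths, overfill_factor = overfill,
    resorption_fraction = resorp, tm, truth_basis = basis,
    row.names = NULL)
  if (!is.null(dir) && !rasterize) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, truth_basis = basis, cases = cases),
            class = "phantom_cohort")
}

#' Case reports from a cohort's ground truth
#'
#' Converts a [generate_cohort()] manifest into [case_report()]s (rates via
#' [compute_rates()]), e.g. to validate cohort statistics against planted
#' effects without running the imaging pipeline.
#'
#' @param cohort A `phantom_cohort`.
#' @return A list of [case_report()]s.
#' @export
cohort_truth_reports <- function(cohort) {
  mf <- cohort$manifest
  lapply(seq_len(nrow(mf)), function(i) {
    rates <- compute_rates(mf$true_cleft_volume[i], mf$true_graft_volume[i],
                           mf$true_integrated_volume[i])
    case_report(mf$case_id[i], mf$true_cleft_volume[i],
                mf$true_graft_volume[i], mf$true_integrated_volume[i],
                mf$true_missing_volume[i], rates$filling_rate_pct,
                rates$restoration_pct, rates$resorption_pct)
  })
}
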