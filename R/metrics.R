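#' Bundle the registered inputs of one case
#'
#' All three timepoint models must already live on the V0 lattice (the
#' pipeline registers V1 and V2 onto V0 so that every Boolean identity is
#' exact on one shared grid).
#'
#' @param v0,v1,v2 Segmented [binary_mask()] models on the V0 geometry
#'   (pre-operative, post-operative, ~6-month follow-up).
#' @param sagittal Mid-sagittal [plane()] (median palatine suture).
#' @param trim [trim_box()] enclosing the cleft/graft region.
#' @param smoothing_radius_mm Opening radius applied to subtraction-derived
#'   masks (default 0.3 mm).
#' @param registration_control Passed to [register_rigid()] for the mirror
#'   registrations.
#' @return A `case_inputs` object.
#' @export
case_inputs <- function(v0, v1, v2, sagittal, trim,
                        smoothing_radius_mm = 0.3,
                        registration_control = list()) {
  stopifnot(inherits(v0, "binary_mask"), inherits(v1, "binary_mask"),
            inherits(v2, "binary_mask"), inherits(sagittal, "plane"),
            inherits(trim, "trim_box"), smoothing_radius_mm >= 0)
  stop_if_geometry_mismatch(v0, v1, "V0 and V1")
  stop_if_geometry_mismatch(v0, v2, "V0 and V2")
  structure(list(v0 = v0, v1 = v1, v2 = v2, sagittal = sagittal,
                 trim = trim, smoothing_radius_mm = smoothing_radius_mm,
                 registration_control = registration_control),
            class = "case_inputs")
}

# shared post-processing of subtraction-derived masks
postprocess_mask <- function(mask, inputs) {
  mask <- trim_to_box(mask, inputs$trim)
  smooth_boundary(mask, inputs$smoothing_radius_mm)
}

#' Cleft volume from the mirrored contralateral reference
#'
#' Mirrors the pre-operative model across the mid-sagittal plane (the
#' mirror only sets the initial spatial position), refines the alignment by
#' Dice-maximizing rigid registration, subtracts the original model from
#' the registered mirror, trims to the anatomical region and smooths the
#' transition contours.
#'
#' @param inputs A [case_inputs()].
#' @return List with `mask` (the cleft [binary_mask()]), `volume_mm3`, and
#'   `registration` (the mirror [register_rigid()] result).
#' @export
compute_cleft_volume <- function(inputs) {
  mirrored <- mirror_mask(inputs$v0, inputs$sagittal)
  reg <- register_rigid(mirrored, inputs$v0,
                        control = inputs$registration_control)
  aligned <- resample_mask(mirrored, reg$transform, grid_geometry(inputs$v0))
  cleft <- postprocess_mask(mask_subtract(aligned, inputs$v0), inputs)
  cleft$label <- "cleft"
  list(mask = cleft, volume_mm3 = measure_volume(cleft), registration = reg)
}

#' Graft volume (V1 minus V0)
#'
#' @param inputs A [case_inputs()].
#' @return List with `mask` (graft [binary_mask()]) and `volume_mm3`.
#' @export
compute_graft_volume <- function(inputs) {
  graft <- postprocess_mask(mask_subtract(inputs$v1, inputs$v0), inputs)
  graft$label <- "graft"
  list(mask = graft, volume_mm3 = measure_volume(graft))
}

#' Integrated and resorbed graft volume at follow-up
#'
#' The integrated bone is the part of the original graft envelope still
#' occupied by mineralized tissue at follow-up (`V2` intersected with the
#' graft mask); resorption is the exact complement within the graft.
#'
#' @param inputs A [case_inputs()].
#' @param graft_mask The graft [binary_mask()] from [compute_graft_volume()].
#' @return List with `mask` (integrated-bone [binary_mask()]),
#'   `v_integrated_mm3` and `v_resorption_mm3` (their sum is the graft
#'   volume, exactly).
#' @export
compute_integration <- function(inputs, graft_mask) {
  stop_if_geometry_mismatch(inputs$v0, graft_mask, "graft mask and V0")
  integ <- mask_intersect(inputs$v2, graft_mask)
  integ$label <- "integrated"
  vi <- measure_volume(integ)
  list(mask = integ, v_integrated_mm3 = vi,
       v_resorption_mm3 = measure_volume(graft_mask) - vi)
}

#' Residual volumetric deficit at follow-up (mirror reference)
#'
#' Mirrors the follow-up model, registers it onto itself (contralateral
#' reference), and subtracts: what the healthy side still has and the cleft
#' side lacks.
#'
#' @param inputs A [case_inputs()].
#' @return List with `mask`, `volume_mm3` and `registration`.
#' @export
compute_missing_volume <- function(inputs) {
  mirrored <- mirror_mask(inputs$v2, inputs$sagittal)
  reg <- register_rigid(mirrored, inputs$v2,
                        control = inputs$registration_control)
  aligned <- resample_mask(mirrored, reg$transform, grid_geometry(inputs$v2))
  missing <- postprocess_mask(mask_subtract(aligned, inputs$v2), inputs)
  missing$label <- "missing"
  list(mask = missing, volume_mm3 = measure_volume(missing),
       registration = reg)
}

#' Clinical rates from the measured volumes
#'
#' Filling rate = 100 * V_graft / V_cleft (>100% means overfilled);
#' alveolar cleft restoration = 100 * V_integrated / V_cleft;
#' bone graft resorption = 100 * (V_graft - V_integrated) / V_graft.
#'
#' @param v_cleft,v_graft,v_integrated Volumes in mm^3; the two
#'   denominators must be strictly positive.
#' @return Named list `filling_rate_pct`, `restoration_pct`,
#'   `resorption_pct`.
#' @export
compute_rates <- function(v_cleft, v_graft, v_integrated) {
  if (!is.finite(v_cleft) || v_cleft <= 0)
    stop("degenerate cleft volume (", v_cleft, " mm^3): rates undefined")
  if (!is.finite(v_graft) || v_graft <= 0)
    stop("degenerate graft volume (", v_graft, " mm^3): rates undefined")
  if (v_integrated < 0 || v_integrated > v_graft + 1e-9)
    stop("v_integrated must lie in [0, v_graft]")
  list(filling_rate_pct = 100 * v_graft / v_cleft,
       restoration_pct = 100 * v_integrated / v_cleft,
       resorption_pct = 100 * (v_graft - v_integrated) / v_graft)
}

#' Full volumetric analysis of one case from grey volumes
#'
#' Runs the complete workflow on in-memory grids: segmentation of the
#' three timepoints, occlusal re-slicing of V0 (the reference frame),
#' Dice-maximizing rigid registration of V1 and V2 onto V0, the four
#' volume constructions and the clinical rates.
#'
#' @param v0_grid,v1_grid,v2_grid Grey [voxel_grid()]s of the three
#'   timepoints.
#' @param thresholds A [threshold_spec()].
#' @param occlusal,sagittal [plane()]s (occlusal for re-slicing,
#'   mid-sagittal for mirroring).
#' @param trim A [trim_box()].
#' @param smoothing_radius_mm Opening radius for subtraction masks.
#' @param case_id Case identifier for the report.
#' @param save_dir If non-NULL, intermediate masks are written there as
#'   NIfTI for audit.
#' @param registration_control Passed to [register_rigid()].
#' @return A [case_report()]; the intermediate masks and registrations are
#'   attached as attribute `"details"`.
#' @export
analyze_case <- function(v0_grid, v1_grid, v2_grid,
                         thresholds = threshold_spec(),
                         occlusal = plane(c(0, 0, 0), c(0, 0, 1)),
                         sagittal = plane(c(0, 0, 0), c(1, 0, 0)),
                         trim, smoothing_radius_mm = 0.3, case_id = "case",
                         save_dir = NULL, registration_control = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  v0r <- stage("reslice", reslice_to_plane(v0_grid, occlusal))
  v0 <- stage("segment-V0", segment_case(v0r, thresholds, label = "V0"))
  v1n <- stage("segment-V1", segment_case(v1_grid, thresholds, label = "V1"))
  v2n <- stage("segment-V2", segment_case(v2_grid, thresholds, label = "V2"))
  reg1 <- stage("register-V1", register_rigid(v1n, v0,
                                              control = registration_control))
  reg2 <- stage("register-V2", register_rigid(v2n, v0,
                                              control = registration_control))
  v1 <- resample_mask(v1n, reg1$transform, grid_geometry(v0))
  v1$label <- "V1"
  v2 <- resample_mask(v2n, reg2$transform, grid_geometry(v0))
  v2$label <- "V2"

  inputs <- case_inputs(v0, v1, v2, sagittal, trim, smoothing_radius_mm,
                        registration_control)
  cleft <- stage("cleft-volume", compute_cleft_volume(inputs))
  graft <- stage("graft-volume", compute_graft_volume(inputs))
  integ <- stage("integration", compute_integration(inputs, graft$mask))
  missing <- stage("missing-volume", compute_missing_volume(inputs))
  rates <- stage("rates", compute_rates(cleft$volume_mm3, graft$volume_mm3,
                                        integ$v_integrated_mm3))

  report <- case_report(case_id, cleft$volume_mm3, graft$volume_mm3,
                        integ$v_integrated_mm3, missing$volume_mm3,
                        rates$filling_rate_pct, rates$restoration_pct,
                        rates$resorption_pct)
  details <- list(v0 = v0, v1 = v1, v2 = v2, cleft = cleft$mask,
                  graft = graft$mask, integrated = integ$mask,
                  missing = missing$mask,
                  registrations = list(v1 = reg1, v2 = reg2,
                                       mirror_v0 = cleft$registration,
                                       mirror_v2 = missing$registration))
  if (!is.null(save_dir)) {
    dir.create(save_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("v0", "v1", "v2", "cleft", "graft", "integrated",
                 "missing"))
      write_volume(details[[nm]],
                   file.path(save_dir, paste0(case_id, "_", nm, ".nii.gz")))
  }
  attr(report, "details") <- details
  report
}

#' Run one case from a configuration file
#'
#' Reads the case configuration (YAML or JSON; see [read_case_config()]),
#' loads the three volumes (NIfTI file or DICOM directory per timepoint)
#' and calls [analyze_case()].
#'
#' @param config Path to a config file, or the list returned by
#'   [read_case_config()].
#' @param save_intermediates Write intermediate masks next to the config.
#' @return A [case_report()].
#' @export
run_case <- function(config, save_intermediates = FALSE) {
  if (is.character(config)) config <- read_case_config(config)
  load_tp <- function(tp) {
    path <- config$volumes[[tp]]
    if (is.null(path)) stop("config lists no volume for timepoint ", tp)
    if (!file.exists(path) && !dir.exists(path))
      stop("volume for timepoint ", tp, " not found: ", path)
    if (dir.exists(path)) read_dicom_series(path) else read_volume(path)
  }
  v0g <- load_tp("v0")
  v1g <- load_tp("v1")
  v2g <- load_tp("v2")
  save_dir <- if (isTRUE(save_intermediates)) config$output_dir %||%
    file.path(dirname(config$volumes$v0), "intermediates") else NULL
  analyze_case(v0g, v1g, v2g, thresholds = config$thresholds,
               occlusal = config$occlusal_plane,
               sagittal = config$sagittal_plane, trim = config$trim_box,
               smoothing_radius_mm = config$smoothing_radius_mm %||% 0.3,
               case_id = config$case_id %||% "case", save_dir = save_dir,
               registration_control = config$registration_control %||%
                 list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort summary: means, SDs and the planning correlations
#'
#' Per-metric mean and sample standard deviation (n-1 denominator) over a
#' cohort of case reports, plus Pearson correlations (two-sided p from the
#' t distribution with n-2 df) for the three clinically reported pairs:
#' filling rate vs cleft volume, filling rate vs resorption rate, and
#' filling rate vs restoration rate.
#'
#' @param reports List of [case_report()]s, n >= 2.
#' @return A `cohort_summary`: list with `n`, `stats` (data frame of
#'   metric/mean/sd) and `correlations` (data frame of pair/r/p). With
#'   zero-variance input the correlations are `NaN` and a warning is
#'   raised.
#' @export
summarize_cohort <- function(reports) {
  df <- reports_to_frame(reports)
  n <- nrow(df)
  if (n < 2L) stop("cohort summaries need at least 2 cases")
  metrics <- setdiff(report_fields, "case_id")
  stats_df <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(df[[m]]), 0),
    sd = vapply(metrics, function(m) sd(df[[m]]), 0),
    row.names = NULL)

  pearson <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance: correlation undefined")
      return(c(r = NaN, p = NaN))
    }
    r <- stats::cor(x, y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
  }
  pairs <- list(
    filling_vs_cleft = c("filling_rate_pct", "v_cleft_mm3"),
    filling_vs_resorption = c("filling_rate_pct", "resorption_pct"),
    filling_vs_restoration = c("filling_rate_pct", "restoration_pct"))
  cors <- t(vapply(pairs, function(p) pearson(df[[p[1]]], df[[p[2]]]),
                   c(r = 0, p = 0)))
  structure(list(n = n, stats = stats_df,
                 correlations = data.frame(pair = names(pairs),
                                           r = cors[, "r"], p = cors[, "p"],
                                           row.names = NULL)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  print(transform(x$stats, mean = signif(mean, 5), sd = signif(sd, 5)))
  print(transform(x$correlations, r = signif(r, 3), p = signif(p, 3)))
  invisible(x)
}
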