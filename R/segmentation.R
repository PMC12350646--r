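#' Threshold specification for bone and teeth segmentation
#'
#' CBCT grey values are device specific (not Hounsfield calibrated), so the
#' two intensity windows are mandatory configuration. Bone and teeth are
#' segmented separately and merged; gaps in the cortical shell are closed
#' with a ball of physical radius `closing_radius_mm`, and enclosed
#' cancellous space can be filled to obtain a dense model.
#'
#' @param bone_low,bone_high Inclusive grey-intensity window for bone.
#' @param teeth_low,teeth_high Inclusive grey-intensity window for teeth.
#' @param closing_radius_mm Ball radius (mm) for morphological gap closing;
#'   0 disables. Default 0.5 mm, a few voxels at clinical CBCT resolution.
#' @param fill_internal Logical: fill enclosed internal cavities
#'   (cancellous space) after closing.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(bone_low = 200, bone_high = 700, teeth_low = 700,
                           teeth_high = 2000, closing_radius_mm = 0.5,
                           fill_internal = TRUE) {
  if (!(bone_low < bone_high) || !(teeth_low < teeth_high))
    stop("each threshold window needs low < high")
  if (closing_radius_mm < 0) stop("closing_radius_mm must be >= 0")
  structure(list(bone_low = bone_low, bone_high = bone_high,
                 teeth_low = teeth_low, teeth_high = teeth_high,
                 closing_radius_mm = closing_radius_mm,
                 fill_internal = isTRUE(fill_internal)),
            class = "threshold_spec")
}

#' An oriented plane in world space
#'
#' Used for the occlusal plane (head-orientation normalization) and the
#' mid-sagittal / median-palatine-suture plane (mirroring reference).
#'
#' @param point A world point (mm) on the plane.
#' @param normal Plane normal; normalized internally, must be non-zero.
#' @return A `plane` object with `|normal| = 1`.
#' @export
plane <- function(point, normal) {
  point <- as.double(point)
  normal <- as.double(normal)
  if (length(point) != 3L || length(normal) != 3L)
    stop("point and normal must be length-3")
  nl <- sqrt(sum(normal^2))
  if (!is.finite(nl) || nl < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / nl), class = "plane")
}

#' Dual-threshold segmentation of bone and teeth
#'
#' Marks every voxel whose grey value falls in the bone window or the teeth
#' window (both bounds inclusive) and merges the two masks.
#'
#' @param grid A [voxel_grid()].
#' @param spec A [threshold_spec()].
#' @return A [binary_mask()] on the grid's geometry.
#' @export
segment_dual_threshold <- function(grid, spec) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(spec, "threshold_spec"))
  v <- grid$values
  sel <- (v >= spec$bone_low & v <= spec$bone_high) |
    (v >= spec$teeth_low & v <= spec$teeth_high)
  binary_mask(array(as.integer(sel), dim(v)), spacing = grid$spacing,
              origin = grid$origin, axes = grid$axes, label = "threshold")
}

#' Close gaps in a segmented model
#'
#' Morphological closing with a Euclidean ball of the given physical radius
#' (implemented by exact anisotropic distance transforms, so anisotropic
#' voxels are respected). Extensive: the output contains the input.
#'
#' @param mask A [binary_mask()].
#' @param closing_radius_mm Ball radius in mm; 0 returns the mask unchanged.
#' @return A [binary_mask()].
#' @export
fill_gaps <- function(mask, closing_radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), closing_radius_mm >= 0)
  if (closing_radius_mm == 0) return(mask)
  pad <- ceiling(closing_radius_mm / min(mask$spacing)) + 1L
  vox <- pad_array(mask$voxels, pad)
  d <- dim(vox)
  dil <- morpho_ball(vox, d, mask$spacing, closing_radius_mm, "dilate")
  clo <- morpho_ball(dil, d, mask$spacing, closing_radius_mm, "erode")
  out <- unpad_array(clo, pad, dim(mask$voxels))
  out[mask$voxels == 1L] <- 1L  # guard extensivity against border effects
  binary_mask(out, spacing = mask$spacing, origin = mask$origin,
              axes = mask$axes, label = mask$label)
}

#' Fill enclosed internal cavities (dense-model fill)
#'
#' Replaces the semi-automatic cancellous fill of interactive workflows
#' with a deterministic rule: every background component not 6-connected
#' to the array border becomes foreground. Extensive and idempotent.
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] whose only background is border-connected.
#' @export
fill_internal <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  d <- dim(mask$voxels)
  reach <- cpp_border_background(mask$voxels, d)
  out <- array(1L, d)
  out[reach == 1L] <- 0L
  binary_mask(out, spacing = mask$spacing, origin = mask$origin,
              axes = mask$axes, label = mask$label)
}

#' Segment a CBCT grid into a dense bone-plus-teeth model
#'
#' The standard recipe: dual thresholding, gap closing, then (optionally)
#' internal cavity filling, in that order.
#'
#' @param grid A [voxel_grid()].
#' @param spec A [threshold_spec()].
#' @param label Role tag for the resulting mask.
#' @return A dense [binary_mask()].
#' @export
segment_case <- function(grid, spec = threshold_spec(), label = "") {
  m <- segment_dual_threshold(grid, spec)
  m <- fill_gaps(m, spec$closing_radius_mm)
  if (spec$fill_internal) m <- fill_internal(m)
  m$label <- label
  m
}

# --- morphology internals ---------------------------------------------------

# Euclidean-ball operation via exact squared distance transform.
# dilate: keep voxels within r of the foreground; erode: keep foreground
# voxels strictly deeper than r from the background.
morpho_ball <- function(vox, d, spacing, radius_mm, op) {
  r2 <- radius_mm^2 + 1e-9
  if (op == "dilate") {
    d2 <- cpp_edt_sq(vox, d, spacing)
    array(as.integer(d2 <= r2), d)
  } else {
    inv <- array(1L - vox, d)
    d2 <- cpp_edt_sq(inv, d, spacing)
    array(as.integer(vox == 1L & d2 > r2), d)
  }
}

pad_array <- function(vox, pad) {
  d <- dim(vox)
  out <- array(0L, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- vox
  out
}

unpad_array <- function(vox, pad, d) {
  vox[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]),
      drop = FALSE]
}
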