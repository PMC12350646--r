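#' Axis-aligned trim box in world coordinates
#'
#' A deterministic surrogate for landmark-guided manual trimming: voxels
#' whose centres fall outside the box are discarded.
#'
#' @param lower,upper World-mm corners with `lower < upper` per axis.
#' @return A `trim_box` object.
#' @export
trim_box <- function(lower, upper) {
  lower <- as.double(lower)
  upper <- as.double(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("box corners must be length-3")
  if (any(!is.finite(c(lower, upper))) || any(lower >= upper))
    stop("trim box needs lower < upper on every axis")
  structure(list(lower = lower, upper = upper), class = "trim_box")
}

#' Boolean voxel algebra on a shared lattice
#'
#' `mask_subtract(a, b)` is voxelwise `a AND NOT b`; `mask_intersect(a, b)`
#' is voxelwise `a AND b`. Both require identical grid geometry — resample
#' first ([resample_mask()]) if the models live on different lattices.
#'
#' @param a,b [binary_mask()] objects with identical geometry.
#' @return A [binary_mask()] on the shared geometry.
#' @export
mask_subtract <- function(a, b) {
  stop_if_geometry_mismatch(a, b, "masks")
  binary_mask(array(as.integer(a$voxels == 1L & b$voxels == 0L),
                    dim(a$voxels)),
              spacing = a$spacing, origin = a$origin, axes = a$axes,
              label = a$label)
}

#' @rdname mask_subtract
#' @export
mask_intersect <- function(a, b) {
  stop_if_geometry_mismatch(a, b, "masks")
  binary_mask(array(as.integer(a$voxels == 1L & b$voxels == 1L),
                    dim(a$voxels)),
              spacing = a$spacing, origin = a$origin, axes = a$axes,
              label = a$label)
}

#' Trim a mask to an anatomical region of interest
#'
#' Keeps only voxels whose centres lie inside the box (inclusive bounds).
#'
#' @param mask A [binary_mask()].
#' @param box A [trim_box()] in world mm.
#' @return A [binary_mask()]; a warning is raised if the box misses the
#'   grid's field of view entirely (the result is then empty).
#' @export
trim_to_box <- function(mask, box) {
  stopifnot(inherits(mask, "binary_mask"), inherits(box, "trim_box"))
  d <- dim(mask$voxels)
  if (max(abs(mask$axes - diag(3))) < 1e-9) {
    # axis-aligned lattice: the inside test separates per axis
    keep <- lapply(1:3, function(a) {
      x <- mask$origin[a] + (seq_len(d[a]) - 1) * mask$spacing[a]
      x >= box$lower[a] & x <= box$upper[a]
    })
    out <- array(0L, d)
    if (any(keep[[1]]) && any(keep[[2]]) && any(keep[[3]])) {
      out[keep[[1]], keep[[2]], keep[[3]]] <-
        mask$voxels[keep[[1]], keep[[2]], keep[[3]]]
    } else {
      warning("trim box is disjoint from the grid field of view")
    }
  } else {
    w <- world_coord_arrays(mask)
    inside <- (w[[1]] >= box$lower[1] & w[[1]] <= box$upper[1]) &
      (w[[2]] >= box$lower[2] & w[[2]] <= box$upper[2]) &
      (w[[3]] >= box$lower[3] & w[[3]] <= box$upper[3])
    if (!any(inside))
      warning("trim box is disjoint from the grid field of view")
    out <- mask$voxels
    out[!inside] <- 0L
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin,
              axes = mask$axes, label = mask$label)
}

#' Smooth a mask boundary by morphological opening
#'
#' Removes protrusions thinner than twice the given radius with a
#' Euclidean-ball opening — the deterministic counterpart of manually
#' smoothing contours around the cleft transition. Anti-extensive
#' (output is contained in input) and idempotent.
#'
#' @param mask A [binary_mask()].
#' @param radius_mm Ball radius in mm; 0 returns the mask unchanged.
#' @return A [binary_mask()].
#' @export
smooth_boundary <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "binary_mask"), radius_mm >= 0)
  if (radius_mm == 0) return(mask)
  d <- dim(mask$voxels)
  ero <- morpho_ball(mask$voxels, d, mask$spacing, radius_mm, "erode")
  opn <- morpho_ball(ero, d, mask$spacing, radius_mm, "dilate")
  opn[mask$voxels == 0L] <- 0L  # guard anti-extensivity at the border
  binary_mask(opn, spacing = mask$spacing, origin = mask$origin,
              axes = mask$axes, label = mask$label)
}

#' Volume of a mask in cubic millimetres
#'
#' Foreground voxel count times the voxel volume (product of spacings).
#'
#' @param mask A [binary_mask()].
#' @return Volume in mm^3 (always >= 0).
#' @export
measure_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$voxels) * prod(mask$spacing)
}
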