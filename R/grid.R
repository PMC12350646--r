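#' Voxel grids and binary masks
#'
#' `voxel_grid()` wraps a grey-level CBCT volume together with its physical
#' geometry; `binary_mask()` wraps a segmented model on the same kind of
#' lattice. World coordinates follow the LPS convention in millimetres,
#' voxel indices are 0-based, and a voxel's value is located at its centre:
#' `world = origin + axes %*% (index * spacing)`.
#'
#' @param values 3-D numeric array of grey intensities (arbitrary CBCT units).
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the centre of
#'   voxel (0,0,0).
#' @param axes 3x3 direction matrix with orthonormal columns and
#'   determinant +1.
#' @return An object of class `voxel_grid` or `binary_mask`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' m <- binary_mask(array(1L, c(4, 4, 4)), spacing = c(0.5, 0.5, 0.5))
#' measure_volume(m)
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0), axes = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(is.finite(values)))
    stop("grid values must all be finite")
  geom <- validate_geometry(spacing, origin, axes)
  structure(list(values = values, spacing = geom$spacing,
                 origin = geom$origin, axes = geom$axes),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param voxels 3-D array of 0/1 foreground indicators.
#' @param label Free-text role tag (e.g. "V0", "graft").
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0), axes = diag(3),
                        label = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels) || !all(voxels == 0L | voxels == 1L))
    stop("mask voxels must be 0 or 1")
  geom <- validate_geometry(spacing, origin, axes)
  structure(list(voxels = voxels, spacing = geom$spacing,
                 origin = geom$origin, axes = geom$axes,
                 label = as.character(label)),
            class = "binary_mask")
}

validate_geometry <- function(spacing, origin, axes, tol = 1e-6) {
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  axes <- matrix(as.double(axes), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values")
  if (max(abs(crossprod(axes) - diag(3))) > tol)
    stop("axes must be orthonormal")
  if (det(axes) < 0)
    stop("axes must be right-handed (determinant +1)")
  list(spacing = spacing, origin = origin, axes = axes)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask%s> %s voxels, %d foreground, %.2f mm^3\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels), measure_volume(x)))
  invisible(x)
}

# --- geometry helpers (internal) -------------------------------------------

grid_dim <- function(x) dim(if (inherits(x, "binary_mask")) x$voxels else x$values)

grid_geometry <- function(x) {
  list(dim = grid_dim(x), spacing = x$spacing, origin = x$origin,
       axes = x$axes)
}

geometry_equal <- function(a, b, tol = 1e-6) {
  ga <- grid_geometry_of(a)
  gb <- grid_geometry_of(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol &&
    max(abs(ga$axes - gb$axes)) <= tol
}

grid_geometry_of <- function(x) {
  if (inherits(x, c("voxel_grid", "binary_mask"))) grid_geometry(x) else x
}

stop_if_geometry_mismatch <- function(a, b, what = "operands") {
  if (!geometry_equal(a, b))
    stop(sprintf("%s must share identical grid geometry", what))
  invisible(TRUE)
}

# World coordinates (mm) of 0-based voxel indices given as an N x 3 matrix.
index_to_world <- function(geom, idx) {
  geom <- grid_geometry_of(geom)
  idx <- matrix(as.double(idx), ncol = 3)
  sweep(idx %*% diag(geom$spacing) %*% t(geom$axes), 2, geom$origin, "+")
}

# Continuous 0-based voxel indices of world points (N x 3).
world_to_index <- function(geom, pts) {
  geom <- grid_geometry_of(geom)
  pts <- matrix(as.double(pts), ncol = 3)
  sweep(sweep(pts, 2, geom$origin, "-") %*% geom$axes, 2, geom$spacing, "/")
}

# Full 3-D arrays of the world coordinate along each world axis.
world_coord_arrays <- function(geom) {
  geom <- grid_geometry_of(geom)
  d <- geom$dim
  i <- (seq_len(d[1]) - 1) * geom$spacing[1]
  j <- (seq_len(d[2]) - 1) * geom$spacing[2]
  k <- (seq_len(d[3]) - 1) * geom$spacing[3]
  ax <- geom$axes
  lapply(1:3, function(a) {
    geom$origin[a] +
      outer(outer(ax[a, 1] * i, ax[a, 2] * j, "+"), ax[a, 3] * k, "+")
  })
}

# World coordinates of all foreground voxel centres, 3 x N (for registration).
mask_world_points <- function(mask) {
  idx <- which(mask$voxels == 1L)
  if (length(idx) == 0L) return(matrix(numeric(0), 3, 0))
  ai <- arrayInd(idx, dim(mask$voxels)) - 1L
  t(index_to_world(mask, ai))
}

# World centroid of a mask's foreground.
mask_centroid <- function(mask) {
  idx <- which(mask$voxels == 1L)
  if (length(idx) == 0L) stop("mask is empty")
  ai <- arrayInd(idx, dim(mask$voxels)) - 1L
  colMeans(index_to_world(mask, ai))
}

#' Dice overlap coefficient of two masks on a shared lattice
#'
#' @param a,b `binary_mask` objects with identical geometry.
#' @return 2|A∩B| / (|A|+|B|) in `[0, 1]`; `NaN` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stop_if_geometry_mismatch(a, b, "masks")
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  2 * sum(a$voxels == 1L & b$voxels == 1L) / (na + nb)
}

# Box-filter pyramid level: non-overlapping block means (fractional
# occupancy in [0, 1]). Strided subsampling would alias the jagged
# boundaries of rasterized masks and bias the registration objective.
block_mean_level <- function(mask, factor) {
  d <- dim(mask$voxels)
  if (any(d %/% factor < 1L)) return(NULL)
  m <- array(cpp_block_mean(mask$voxels, d, as.integer(factor)),
             d %/% factor)
  # block centre = mean of member voxel centres
  list(values = m, spacing = mask$spacing * factor,
       origin = mask$origin +
         as.double(mask$axes %*% ((factor - 1) / 2 * mask$spacing)),
       axes = mask$axes, dim = dim(m))
}
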