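#' Rigid transforms in world space
#'
#' A 6-DOF map `x -> rotation %*% x + translation` (world mm) used for
#' inter-timepoint alignment and for mirror registration. Composition and
#' inversion are closed; rotations must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.double(rotation), 3, 3)
  translation <- as.double(translation)
  if (length(translation) != 3L || any(!is.finite(translation)) ||
      any(!is.finite(rotation)))
    stop("non-finite transform parameters")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0) stop("rotation must have determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b Transforms; `compose_transform(a, b)` applies `b` first.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.double(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.double(rt %*% tf$translation))
}

#' @rdname rigid_transform
#' @param pts An N x 3 matrix of world points (or a length-3 vector).
#' @export
apply_transform <- function(tf, pts) {
  vec <- is.null(dim(pts))
  pts <- matrix(as.double(pts), ncol = 3)
  out <- sweep(pts %*% t(tf$rotation), 2, tf$translation, "+")
  if (vec) as.double(out) else out
}

#' @rdname rigid_transform
#' @export
transform_to_matrix <- function(tf) {
  rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
}

#' @rdname rigid_transform
#' @param m A 4x4 homogeneous matrix.
#' @export
transform_from_matrix <- function(m) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Rotation angle of a rigid transform, in degrees
#'
#' @param tf A [rigid_transform()] (or a 3x3 rotation matrix).
#' @return The rotation angle about the screw axis, in `[0, 180]` degrees.
#' @export
rotation_angle_deg <- function(tf) {
  r <- if (inherits(tf, "rigid_transform")) tf$rotation else tf
  acos(pmin(1, pmax(-1, (sum(diag(r)) - 1) / 2))) * 180 / pi
}

# Intrinsic ZYX Euler rotation, angles in degrees.
euler_zyx <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  rz %*% ry %*% rx
}

# Rotation about an axis through a centre point.
rotation_about <- function(axis, angle_deg, centre) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  r <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  rigid_transform(r, as.double(centre - r %*% centre))
}

#' Re-slice a grid parallel to the occlusal plane
#'
#' Resamples the grid onto a lattice whose third axis equals the occlusal
#' normal, correcting for head positioning at acquisition. The rotation is
#' the minimal one mapping the current slice normal onto the plane normal;
#' grey values are interpolated trilinearly and the output field of view is
#' the bounding box of the input FOV in the new axes, so no content is
#' cropped. If the grid is already aligned it is returned unchanged.
#'
#' @param grid A [voxel_grid()].
#' @param occlusal A [plane()]; only its normal direction is used.
#' @param fill Grey value for voxels outside the source FOV.
#' @return A [voxel_grid()] whose third axis is the occlusal normal.
#' @export
reslice_to_plane <- function(grid, occlusal, fill = 0) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(occlusal, "plane"))
  a <- grid$axes[, 3]
  n <- occlusal$normal
  if (sum(a * n) < 0) n <- -n  # minimal of the two antipodal rotations
  axis <- c(a[2] * n[3] - a[3] * n[2], a[3] * n[1] - a[1] * n[3],
            a[1] * n[2] - a[2] * n[1])
  s <- sqrt(sum(axis^2))
  co <- sum(a * n)
  if (s < 1e-12) return(grid)
  th <- atan2(s, co)
  k <- axis / s
  km <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  rm <- diag(3) + sin(th) * km + (1 - cos(th)) * (km %*% km)
  new_axes <- rm %*% grid$axes

  d <- dim(grid$values)
  corners <- as.matrix(expand.grid(c(-0.5, d[1] - 0.5), c(-0.5, d[2] - 0.5),
                                   c(-0.5, d[3] - 0.5)))
  wc <- index_to_world(grid, corners)
  proj <- wc %*% new_axes
  smin <- apply(proj, 2, min)
  smax <- apply(proj, 2, max)
  new_dim <- as.integer(ceiling((smax - smin) / grid$spacing))
  new_origin <- as.double(new_axes %*% (smin + grid$spacing / 2))

  vals <- cpp_resample_lin(as.double(grid$values), d, grid$spacing,
                           grid$origin, grid$axes, new_dim, grid$spacing,
                           new_origin, new_axes, c(diag(3)), c(0, 0, 0),
                           fill)
  voxel_grid(array(vals, new_dim), spacing = grid$spacing,
             origin = new_origin, axes = new_axes)
}

#' Mirror a mask across the mid-sagittal plane
#'
#' Applies the reflection `x -> x - 2 ((x - p) . n) n` across the plane and
#' resamples the reflected model back onto the input lattice with
#' nearest-neighbour interpolation (masks stay binary). On a
#' lattice-aligned plane the operation is an exact involution.
#'
#' @param mask A [binary_mask()].
#' @param sagittal A [plane()] (the median palatine suture plane).
#' @return A [binary_mask()] on the same geometry, labelled "mirrored".
#' @export
mirror_mask <- function(mask, sagittal) {
  stopifnot(inherits(mask, "binary_mask"), inherits(sagittal, "plane"))
  n <- sagittal$normal
  h <- diag(3) - 2 * tcrossprod(n)
  tv <- sagittal$point - as.double(h %*% sagittal$point)
  d <- dim(mask$voxels)
  # a reflection is its own inverse
  vox <- cpp_resample_nn(mask$voxels, d, mask$spacing, mask$origin,
                         mask$axes, d, mask$spacing, mask$origin, mask$axes,
                         c(h), tv)
  binary_mask(array(vox, d), spacing = mask$spacing, origin = mask$origin,
              axes = mask$axes,
              label = paste0(mask$label, if (nzchar(mask$label)) "_",
                             "mirrored"))
}

#' Resample a mask through a rigid transform onto a reference lattice
#'
#' Nearest-neighbour resampling of the transformed mask: output voxel
#' centres are pulled back through the inverse transform; positions outside
#' the source FOV become background.
#'
#' @param mask A [binary_mask()].
#' @param transform A [rigid_transform()] mapping mask world coordinates to
#'   reference world coordinates.
#' @param reference A [voxel_grid()], [binary_mask()] or geometry list
#'   providing the target lattice.
#' @return A [binary_mask()] on the reference geometry.
#' @export
resample_mask <- function(mask, transform, reference) {
  stopifnot(inherits(mask, "binary_mask"),
            inherits(transform, "rigid_transform"))
  g <- grid_geometry_of(reference)
  rinv <- t(transform$rotation)
  tinv <- -as.double(rinv %*% transform$translation)
  vox <- cpp_resample_nn(mask$voxels, dim(mask$voxels), mask$spacing,
                         mask$origin, mask$axes, g$dim, g$spacing, g$origin,
                         g$axes, c(rinv), tinv)
  binary_mask(array(vox, g$dim), spacing = g$spacing, origin = g$origin,
              axes = g$axes, label = mask$label)
}

#' Rigid registration of binary models by overlap maximization
#'
#' Finds the rigid transform that maximizes the Dice overlap between the
#' fixed model and the transformed moving model. The search is
#' deterministic and coarse-to-fine: centre-of-mass initialization
#' (composed with `init`), exhaustive translation and rotation scans on
#' box-filter pyramid levels, derivative-free Nelder-Mead refinement over
#' all 6 degrees of freedom (intrinsic ZYX Euler angles + translation) at
#' the mid level, then a rotation re-scan and re-centred polish rounds on
#' the full-resolution surface band of the fixed model. Because the hard
#' Dice of a nearest-neighbour resampled mask is piecewise constant in
#' the parameters, the optimizer maximizes a smooth surrogate (the
#' trilinearly interpolated moving model summed over weighted fixed
#' sample points; see the methods vignette for the weighting and
#' smoothing details that keep the surrogate's optimum at the true
#' alignment); the returned `overlap` is the hard Dice at the optimum.
#'
#' @param moving,fixed Non-empty [binary_mask()] objects.
#' @param init Initial [rigid_transform()] (e.g. a mirroring hint).
#' @param control List overriding search parameters: `coarse_range_mm`
#'   (default 10), `coarse_step_mm` (2), `coarse_rot_range_deg` (8),
#'   `coarse_rot_step_deg` (4), `downsample` (c(4, 2)), `maxit`
#'   (c(400, 250)).
#' @return A `registration_result`: list with `transform`
#'   ([rigid_transform()] mapping moving to fixed world), `overlap` (Dice
#'   at optimum), `iterations`, `converged`.
#' @export
register_rigid <- function(moving, fixed, init = rigid_transform(),
                           control = list()) {
  stopifnot(inherits(moving, "binary_mask"), inherits(fixed, "binary_mask"))
  if (sum(moving$voxels) == 0L) stop("moving mask is empty")
  if (sum(fixed$voxels) == 0L) stop("fixed mask is empty")
  ctl <- list(coarse_range_mm = 10, coarse_step_mm = 2,
              coarse_rot_range_deg = 8, coarse_rot_step_deg = 4,
              downsample = c(4L, 2L), maxit = c(400L, 250L))
  ctl[names(control)] <- control

  com_m <- mask_centroid(moving)
  com_f <- mask_centroid(fixed)
  # balance the Nelder-Mead step sizes: one degree of rotation displaces
  # the model surface by about (pi/180) * gyration radius millimetres
  fpts <- mask_world_points(fixed)
  r_gyr <- sqrt(mean(colSums((fpts - com_f)^2)))
  deg_scale <- 180 / (pi * max(r_gyr, 1))
  parscale <- c(1, 1, 1, deg_scale, deg_scale, deg_scale)
  # centre-of-mass initialization composed with init
  t0 <- rigid_transform(init$rotation,
                        com_f - as.double(init$rotation %*% com_m))

  # parameters are a perturbation (3 translations mm, 3 intrinsic ZYX Euler
  # angles deg, rotating about the fixed centroid) of a base transform
  param_transform <- function(p, base) {
    re <- euler_zyx(p[4:6])
    rigid_transform(re %*% base$rotation,
                    as.double(re %*% (base$translation - com_f)) + com_f +
                      p[1:3])
  }

  # --- multiscale search ---------------------------------------------------
  # Every level maximizes a weighted sum of the interpolated moving field
  # over sample points of the fixed model. On downsampled block levels the
  # weights are (occupancy - 1/2) over the fixed support plus a background
  # halo: the negative background weights penalize poses that push the
  # moving model past the fixed boundary (a constant-denominator overlap
  # sum would reward them), which keeps the coarse optimum at alignment.
  # The moving block field is 7-point smoothed so that lattice-
  # commensurate poses get no interpolation bonus. At full resolution the
  # samples are a thin surface band of the fixed model with unit weights
  # and the raw moving field: there the true-pose signal dominates, and
  # the residual lattice preference snaps near-commensurate optima (e.g.
  # mirror alignments) exactly onto the lattice, minimizing nearest-
  # neighbour resampling damage.
  level <- function(factor) {
    mb <- block_mean_level(moving, factor)
    fb <- block_mean_level(fixed, factor)
    if (is.null(mb) || is.null(fb)) return(NULL)
    if (max(mb$values) == 0 || max(fb$values) == 0) return(NULL)
    support <- fb$values > 0
    d2 <- cpp_edt_sq(array(as.integer(support), fb$dim), fb$dim,
                     fb$spacing)
    halo_r <- 3 * max(fb$spacing)
    idx <- which(support | d2 <= halo_r^2)
    ai <- arrayInd(idx, fb$dim) - 1L
    list(mvals = cpp_smooth7(as.double(mb$values), mb$dim), mdim = mb$dim,
         mspacing = mb$spacing, morigin = mb$origin, maxes = mb$axes,
         pts = t(index_to_world(fb, ai)), wts = fb$values[idx] - 0.5)
  }

  band_level <- function() {
    # deep-interior fixed voxels contribute a constant near the optimum;
    # sample the objective only on a thin surface band, deterministically
    # thinned when large, for sensitivity at a fraction of the cost
    d2 <- cpp_edt_sq(array(1L - fixed$voxels, dim(fixed$voxels)),
                     dim(fixed$voxels), fixed$spacing)
    band <- fixed$voxels == 1L & d2 <= (1.2 * max(fixed$spacing))^2
    idx <- which(band)
    if (length(idx) > 50000L)
      idx <- idx[seq(1L, length(idx), by = 2L)]
    ai <- arrayInd(idx, dim(fixed$voxels)) - 1L
    pts <- t(index_to_world(fixed, ai))
    list(mvals = as.double(moving$voxels), mdim = dim(moving$voxels),
         mspacing = moving$spacing, morigin = moving$origin,
         maxes = moving$axes, pts = pts, wts = rep(1, ncol(pts)))
  }
  neg_mass <- function(p, lv, base) {
    if (any(!is.finite(p))) stop("non-finite transform parameters during optimization")
    tf <- param_transform(p, base)
    rinv <- t(tf$rotation)
    tinv <- -as.double(rinv %*% tf$translation)
    -cpp_overlap_mass(lv$mvals, lv$mdim, lv$mspacing, lv$morigin,
                      c(lv$maxes), lv$pts, lv$wts, c(rinv), tinv)
  }

  evals <- 0L
  # exhaustive coarse translation scan
  f_coarse <- ctl$downsample[1]
  lv_c <- level(f_coarse)
  while (is.null(lv_c) && f_coarse > 1L) {
    f_coarse <- f_coarse %/% 2L
    lv_c <- level(f_coarse)
  }
  best <- c(0, 0, 0)
  best_a <- c(0, 0, 0)
  lv_m <- level(ctl$downsample[2])
  if (is.null(lv_m)) lv_m <- lv_c
  if (!is.null(lv_c)) {
    steps <- seq(-ctl$coarse_range_mm, ctl$coarse_range_mm,
                 by = ctl$coarse_step_mm)
    grid_t <- as.matrix(expand.grid(steps, steps, steps))
    best_val <- Inf
    for (i in seq_len(nrow(grid_t))) {
      val <- neg_mass(c(grid_t[i, ], 0, 0, 0), lv_c, t0)
      evals <- evals + 1L
      if (val < best_val) {
        best_val <- val
        best <- grid_t[i, ]
      }
    }
    # coarse rotation scan from the best translation, one level finer
    asteps <- seq(-ctl$coarse_rot_range_deg, ctl$coarse_rot_range_deg,
                  by = ctl$coarse_rot_step_deg)
    grid_a <- as.matrix(expand.grid(asteps, asteps, asteps))
    best_val <- neg_mass(c(best, best_a), lv_m, t0)
    for (i in seq_len(nrow(grid_a))) {
      val <- neg_mass(c(best, grid_a[i, ]), lv_m, t0)
      evals <- evals + 1L
      if (val < best_val) {
        best_val <- val
        best_a <- grid_a[i, ]
      }
    }
  }

  # mid-level derivative-free refinement
  if (!is.null(lv_m)) {
    opt1 <- optim(c(best, best_a), neg_mass, lv = lv_m, base = t0,
                  method = "Nelder-Mead",
                  control = list(maxit = ctl$maxit[1], reltol = 1e-9,
                                 parscale = parscale))
    evals <- evals + opt1$counts[1]
    tf <- param_transform(opt1$par, t0)
  } else {
    tf <- param_transform(c(best, best_a), t0)
  }

  # rotation information can live entirely at fine scale (block levels
  # blur small features away), so rescan rotations on the full-resolution
  # band around the mid-level result; the current pose is in the grid, so
  # this can only improve the basin handed to the polish rounds
  lv_f <- band_level()
  fsteps <- seq(-6, 6, by = 3)
  grid_fa <- as.matrix(expand.grid(fsteps, fsteps, fsteps))
  best_val <- neg_mass(rep(0, 6), lv_f, tf)
  best_fa <- c(0, 0, 0)
  for (i in seq_len(nrow(grid_fa))) {
    val <- neg_mass(c(0, 0, 0, grid_fa[i, ]), lv_f, tf)
    evals <- evals + 1L
    if (val < best_val) {
      best_val <- val
      best_fa <- grid_fa[i, ]
    }
  }
  tf <- param_transform(c(0, 0, 0, best_fa), tf)

  # raw-field full-resolution polish: re-centred Nelder-Mead rounds with a
  # shrinking trust region around the current optimum
  converged <- FALSE
  for (shrink in c(1, 0.25, 0.08)) {
    opt2 <- optim(rep(0, 6), neg_mass, lv = lv_f, base = tf,
                  method = "Nelder-Mead",
                  control = list(maxit = ctl$maxit[2], reltol = 1e-10,
                                 parscale = parscale * shrink))
    evals <- evals + opt2$counts[1]
    tf <- param_transform(opt2$par, tf)
    converged <- opt2$convergence == 0L
  }
  moved <- resample_mask(moving, tf, grid_geometry(fixed))
  structure(list(transform = tf, overlap = dice_coefficient(moved, fixed),
                 iterations = as.integer(evals), converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result> Dice %.4f after %d evaluations",
                     " (%s); rotation %.3f deg, translation (%s) mm\n"),
              x$overlap, x$iterations,
              if (x$converged) "converged" else "iteration limit",
              rotation_angle_deg(x$transform),
              paste(sprintf("%.3f", x$transform$translation),
                    collapse = ", ")))
  invisible(x)
}
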