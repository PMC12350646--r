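#' Read and write volumes as NIfTI
#'
#' NIfTI is the lossless working format of the pipeline: grey grids are
#' stored as float, masks as int16, and the rigid affine carries the
#' spacing/origin/axes geometry. NIfTI affines address RAS world space;
#' internally the package uses the LPS convention of DICOM, so the first
#' two world axes are negated on the way in and out. Only rigid affines
#' (orthogonal directions, no shear) are accepted.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a [voxel_grid()]; `read_mask()` a
#'   [binary_mask()]; the writers return `path` invisibly.
#' @examples
#' g <- voxel_grid(array(rnorm(27), c(3, 3, 3)), spacing = c(1, 1, 1))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(g, f)
#' g2 <- read_volume(f)
#' stopifnot(max(abs(g2$values - g$values)) < 1e-6)
#' @export
read_volume <- function(path) {
  obj <- read_nifti_raw(path)
  voxel_grid(obj$values, spacing = obj$spacing, origin = obj$origin,
             axes = obj$axes)
}

#' @rdname read_volume
#' @param label Role tag attached to the mask.
#' @export
read_mask <- function(path, label = "") {
  obj <- read_nifti_raw(path)
  vox <- obj$values
  if (!all(vox %in% c(0, 1)))
    stop("file does not contain a binary mask: ", path)
  binary_mask(array(as.integer(vox), dim(vox)), spacing = obj$spacing,
              origin = obj$origin, axes = obj$axes, label = label)
}

#' @rdname read_volume
#' @param x A [voxel_grid()] or [binary_mask()].
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    vals <- x$voxels
    datatype <- "int16"
  } else if (inherits(x, "voxel_grid")) {
    vals <- x$values
    datatype <- "double"
  } else {
    stop("'x' must be a voxel_grid or binary_mask")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to missing directory: ", dir)
  affine_lps <- rbind(cbind(x$axes %*% diag(x$spacing), x$origin),
                      c(0, 0, 0, 1))
  affine_ras <- diag(c(-1, -1, 1, 1)) %*% affine_lps
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  img <- RNifti::`qform<-`(img, structure(affine_ras, code = 2L))
  img <- RNifti::`sform<-`(img, structure(affine_ras, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D volume: ", path)
  aff <- RNifti::xform(img)
  m_ras <- aff[1:3, 1:3, drop = FALSE]
  m_lps <- diag(c(-1, -1, 1)) %*% m_ras
  spacing <- sqrt(colSums(m_lps^2))
  if (any(spacing <= 0)) stop("degenerate affine in ", path)
  axes <- sweep(m_lps, 2, spacing, "/")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-4)
    stop("non-rigid (sheared) affine not supported: ", path)
  # re-orthonormalize float32 header jitter
  sv <- svd(axes)
  axes <- sv$u %*% t(sv$v)
  origin <- as.double(diag(c(-1, -1, 1)) %*% aff[1:3, 4])
  vals <- array(as.double(vals), dim(vals))  # drop niftiImage attributes
  list(values = vals, spacing = spacing, origin = origin, axes = axes)
}
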