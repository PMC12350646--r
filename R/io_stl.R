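#' Export a binary mask as a triangulated surface (binary STL)
#'
#' Extracts the 0.5 iso-surface of the mask by marching tetrahedra on the
#' Kuhn 6-tetrahedra decomposition of each voxel cell (a watertight,
#' consistently oriented triangulation) and writes it in the binary STL
#' dialect, vertices in world millimetres. The mask is implicitly padded
#' with background so the surface is closed at the field-of-view border.
#'
#' @param mask A non-empty [binary_mask()].
#' @param path Output `.stl` file path.
#' @return `path`, invisibly. The number of triangles is reported as an
#'   attribute `"triangles"`.
#' @examples
#' m <- binary_mask(array(1L, c(5, 5, 5)), spacing = c(1, 1, 1))
#' f <- tempfile(fileext = ".stl")
#' export_stl(m, f)
#' @export
export_stl <- function(mask, path) {
  if (!inherits(mask, "binary_mask")) stop("'mask' must be a binary_mask")
  if (sum(mask$voxels) == 0L) stop("cannot export an empty mask as STL")
  verts <- cpp_march_tets(mask$voxels, dim(mask$voxels), mask$spacing,
                          mask$origin, mask$axes)
  ntri <- nrow(verts) / 3L
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL surface"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(ntri), con, size = 4L, endian = "little")
  v0 <- verts[seq(1, nrow(verts), by = 3), , drop = FALSE]
  v1 <- verts[seq(2, nrow(verts), by = 3), , drop = FALSE]
  v2 <- verts[seq(3, nrow(verts), by = 3), , drop = FALSE]
  e1 <- v1 - v0
  e2 <- v2 - v0
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # 12 float32 per facet (normal + 3 vertices), then a 0 attribute uint16
  block <- t(cbind(nrm, v0, v1, v2))  # 12 floats per facet, facet-major
  fl <- writeBin(as.numeric(block), raw(), size = 4L, endian = "little")
  facets <- rbind(matrix(fl, nrow = 48L),
                  matrix(as.raw(0), nrow = 2L, ncol = ntri))
  writeBin(as.vector(facets), con)
  invisible(structure(path, triangles = ntri))
}
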