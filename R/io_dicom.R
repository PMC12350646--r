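#' Read an axial DICOM series as a voxel grid
#'
#' Reads a directory containing one single-frame axial DICOM stack
#' (explicit VR, little endian — the standard export of CBCT consoles) and
#' assembles it into a [voxel_grid()]. Slices are ordered by the projection
#' of Image Position (Patient) onto the slice normal, so the result is
#' independent of file listing order. World coordinates are DICOM-native
#' LPS millimetres.
#'
#' @param directory Path containing the `.dcm` files of exactly one series.
#' @return A [voxel_grid()].
#' @details The inter-slice gap must be uniform within 1e-3 mm (scanner
#'   jitter is tolerated, broken stacks are rejected). Mixed Series
#'   Instance UIDs, missing geometry tags, or inconsistent in-plane
#'   spacing raise errors naming the conflict.
#' @export
read_dicom_series <- function(directory) {
  if (!dir.exists(directory)) stop("directory not found: ", directory)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L)
    stop("need at least two DICOM slices in ", directory)
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(s) s$series_uid, "")
  if (length(unique(uids)) != 1L)
    stop("mixed Series Instance UIDs in one directory: ",
         paste(unique(uids), collapse = " vs "))
  ps <- vapply(slices, function(s) s$pixel_spacing, numeric(2))
  if (max(abs(ps - ps[, 1])) > 1e-9)
    stop("inconsistent Pixel Spacing across slices")
  rc <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(rc[1, ] != rc[1, 1]) || any(rc[2, ] != rc[2, 1]))
    stop("inconsistent Rows/Columns across slices")
  iop <- vapply(slices, function(s) s$orientation, numeric(6))
  if (max(abs(iop - iop[, 1])) > 1e-6)
    stop("inconsistent Image Orientation (Patient) across slices")

  rdir <- iop[1:3, 1]
  cdir <- iop[4:6, 1]
  normal <- c(rdir[2] * cdir[3] - rdir[3] * cdir[2],
              rdir[3] * cdir[1] - rdir[1] * cdir[3],
              rdir[1] * cdir[2] - rdir[2] * cdir[1])
  pos <- vapply(slices, function(s) sum(s$position * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  gaps <- diff(pos)
  if (any(gaps <= 0)) stop("duplicate slice positions in series")
  gap <- stats::median(gaps)
  if (max(abs(gaps - gap)) > 1e-3)
    stop(sprintf("non-uniform slice spacing (max deviation %.4g mm > 1e-3 mm)",
                 max(abs(gaps - gap))))

  ncol_px <- slices[[1]]$cols
  nrow_px <- slices[[1]]$rows
  vals <- array(0, c(ncol_px, nrow_px, length(slices)))
  for (k in seq_along(slices))
    vals[, , k] <- slices[[k]]$pixels
  spacing <- c(slices[[1]]$pixel_spacing[2], slices[[1]]$pixel_spacing[1], gap)
  axes <- cbind(rdir, cdir, normal)
  voxel_grid(vals, spacing = spacing, origin = slices[[1]]$position,
             axes = axes)
}

# --- minimal explicit-VR little-endian parser (internal) -------------------

dcm_u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}

dcm_u32 <- function(raw, off) {
  as.numeric(raw[off]) + 256 * as.numeric(raw[off + 1L]) +
    65536 * as.numeric(raw[off + 2L]) + 16777216 * as.numeric(raw[off + 3L])
}

dcm_string <- function(raw) {
  s <- rawToChar(raw[raw != as.raw(0)])
  trimws(s)
}

dcm_numbers <- function(raw) {
  as.numeric(strsplit(dcm_string(raw), "\\", fixed = TRUE)[[1]])
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  off <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM")
    off <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  n <- length(raw)
  while (off + 7L <= n) {
    group <- dcm_u16(raw, off)
    elem <- dcm_u16(raw, off + 2L)
    vr <- rawToChar(raw[(off + 4L):(off + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported DICOM encoding (implicit VR?) in ", path)
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, off + 8L)
      body <- off + 12L
    } else {
      len <- dcm_u16(raw, off + 6L)
      body <- off + 8L
    }
    if (len == 4294967295) stop("undefined-length elements unsupported in ",
                                path)
    if (vr == "SQ") {
      off <- body + len
      next
    }
    value <- raw[seq.int(body, length.out = len)]
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, value = value)
    off <- body + len
    if (key == "7fe0,0010") break
  }

  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("missing DICOM tag ", what, " in ", path)
    tags[[key]]
  }
  rows <- dcm_u16(need("0028,0010", "Rows")$value, 1L)
  cols <- dcm_u16(need("0028,0011", "Columns")$value, 1L)
  pixel_spacing <- dcm_numbers(need("0028,0030", "PixelSpacing")$value)
  position <- dcm_numbers(need("0020,0032", "ImagePositionPatient")$value)
  orientation <- dcm_numbers(need("0020,0037", "ImageOrientationPatient")$value)
  series_uid <- dcm_string(need("0020,000e", "SeriesInstanceUID")$value)
  bits <- if (!is.null(tags[["0028,0100"]]))
    dcm_u16(tags[["0028,0100"]]$value, 1L) else 16L
  signed <- if (!is.null(tags[["0028,0103"]]))
    dcm_u16(tags[["0028,0103"]]$value, 1L) == 1L else FALSE
  if (bits != 16L) stop("only 16-bit pixel data supported (", path, ")")
  px_raw <- need("7fe0,0010", "PixelData")$value
  px <- readBin(px_raw, "integer", n = rows * cols, size = 2L,
                signed = signed, endian = "little")
  slope <- if (!is.null(tags[["0028,1053"]]))
    dcm_numbers(tags[["0028,1053"]]$value) else 1
  intercept <- if (!is.null(tags[["0028,1052"]]))
    dcm_numbers(tags[["0028,1052"]]$value) else 0
  if (length(position) != 3L || length(orientation) != 6L ||
      length(pixel_spacing) != 2L)
    stop("malformed geometry tags in ", path)
  list(rows = rows, cols = cols, pixel_spacing = pixel_spacing,
       position = position, orientation = orientation,
       series_uid = series_uid,
       pixels = matrix(px * slope + intercept, nrow = cols, ncol = rows))
}
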