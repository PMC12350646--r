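# Minimal explicit-VR little-endian DICOM writer for test fixtures,
# independent of the package's reader code path.

dcm_fixture_element <- function(group, elem, vr, value) {
  if (vr %in% c("UI", "DS", "CS", "LO")) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1)
      v <- c(v, if (vr == "UI") as.raw(0) else charToRaw(" "))
  } else if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "OW") {
    v <- value
  } else {
    stop("unsupported fixture VR ", vr)
  }
  head_ <- c(writeBin(as.integer(c(group, elem)), raw(), size = 2,
                      endian = "little"), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head_, as.raw(c(0, 0)),
      writeBin(length(v), raw(), size = 4, endian = "little"), v)
  } else {
    c(head_, writeBin(length(v), raw(), size = 2, endian = "little"), v)
  }
}

write_dicom_slice <- function(path, px, nx, ny, pixel_spacing, ipp,
                              series_uid, instance,
                              orientation = c(1, 0, 0, 0, 1, 0)) {
  ds <- function(x) paste(sprintf("%.6f", x), collapse = "\\")
  meta <- dcm_fixture_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  body <- c(
    dcm_fixture_element(0x0008, 0x0018, "UI",
                        paste0(series_uid, ".", instance)),
    dcm_fixture_element(0x0020, 0x000E, "UI", series_uid),
    dcm_fixture_element(0x0020, 0x0032, "DS", ds(ipp)),
    dcm_fixture_element(0x0020, 0x0037, "DS", ds(orientation)),
    dcm_fixture_element(0x0028, 0x0010, "US", ny),
    dcm_fixture_element(0x0028, 0x0011, "US", nx),
    dcm_fixture_element(0x0028, 0x0030, "DS",
                        ds(c(pixel_spacing[2], pixel_spacing[1]))),
    dcm_fixture_element(0x0028, 0x0100, "US", 16L),
    dcm_fixture_element(0x0028, 0x0103, "US", 0L),
    dcm_fixture_element(0x7FE0, 0x0010, "OW",
                        writeBin(as.integer(px), raw(), size = 2,
                                 endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(body, con)
  invisible(path)
}

# Write a whole axial stack; `values` has dim (nx, ny, nslices), slice gap
# and in-plane spacing in mm. File names can be supplied to exercise
# listing-order independence.
write_dicom_stack <- function(dir, values, spacing, origin,
                              series_uid = "1.2.826.0.1.999999.1",
                              filenames = NULL, gaps = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(values)
  if (is.null(filenames))
    filenames <- sprintf("slice_%03d.dcm", seq_len(d[3]))
  z <- if (is.null(gaps)) (seq_len(d[3]) - 1) * spacing[3] else
    cumsum(c(0, gaps))
  for (k in seq_len(d[3]))
    write_dicom_slice(file.path(dir, filenames[k]),
                      as.vector(values[, , k]), d[1], d[2], spacing[1:2],
                      origin + c(0, 0, z[k]), series_uid, k)
  invisible(dir)
}
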