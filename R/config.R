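#' Read and write case configuration files
#'
#' A case configuration holds everything [run_case()] needs: paths to the
#' three timepoint volumes (NIfTI file or DICOM directory), the threshold
#' specification, the occlusal and mid-sagittal planes, the trim box and
#' the smoothing radius. YAML (`.yml`/`.yaml`) and JSON are supported.
#'
#' @param path Config file path.
#' @return `read_case_config()` returns a list with typed components
#'   (`thresholds` as [threshold_spec()], planes as [plane()], `trim_box`
#'   as [trim_box()]); relative volume paths are resolved against the
#'   config file's directory.
#' @export
read_case_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  vols <- lapply(raw$volumes, function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  })
  th <- raw$thresholds %||% list()
  config <- list(
    case_id = raw$case_id %||% sub("\\.[^.]+$", "", basename(path)),
    volumes = vols,
    thresholds = threshold_spec(
      bone_low = th$bone_low %||% 200, bone_high = th$bone_high %||% 700,
      teeth_low = th$teeth_low %||% 700,
      teeth_high = th$teeth_high %||% 2000,
      closing_radius_mm = th$closing_radius_mm %||% 0.5,
      fill_internal = th$fill_internal %||% TRUE),
    occlusal_plane = plane(raw$occlusal_plane$point %||% c(0, 0, 0),
                           raw$occlusal_plane$normal %||% c(0, 0, 1)),
    sagittal_plane = plane(raw$sagittal_plane$point %||% c(0, 0, 0),
                           raw$sagittal_plane$normal %||% c(1, 0, 0)),
    trim_box = trim_box(unlist(raw$trim_box$lower),
                        unlist(raw$trim_box$upper)),
    smoothing_radius_mm = raw$smoothing_radius_mm %||% 0.3,
    registration_control = raw$registration_control %||% list(),
    output_dir = raw$output_dir)
  config
}

#' @rdname read_case_config
#' @param config A list as produced by [read_case_config()] or assembled
#'   by the phantom generator.
#' @export
write_case_config <- function(config, path) {
  ser <- list(
    case_id = config$case_id,
    volumes = config$volumes,
    thresholds = unclass(config$thresholds),
    occlusal_plane = lapply(unclass(config$occlusal_plane), as.numeric),
    sagittal_plane = lapply(unclass(config$sagittal_plane), as.numeric),
    trim_box = lapply(unclass(config$trim_box), as.numeric),
    smoothing_radius_mm = config$smoothing_radius_mm,
    registration_control = config$registration_control,
    output_dir = config$output_dir)
  ser <- ser[!vapply(ser, is.null, TRUE)]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(ser, path)
  invisible(path)
}
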