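#' Per-case volumetric report
#'
#' Bundles the five volumes and three clinical rates computed for one
#' patient or phantom case. The constructor enforces the exact bookkeeping
#' identities of the workflow: `v_resorption = v_graft - v_integrated`,
#' `0 <= v_integrated <= v_graft`, and (when the graft is non-empty)
#' `resorption_pct = 100 - 100 * v_integrated / v_graft`.
#'
#' @param case_id Unique case identifier.
#' @param v_cleft_mm3,v_graft_mm3,v_integrated_mm3,v_missing_mm3 Volumes in
#'   cubic millimetres.
#' @param filling_rate_pct,restoration_pct,resorption_pct Percentages as
#'   defined by [compute_rates()]; may be `NA` for degenerate cases.
#' @return A `case_report` object (also a one-row list).
#' @export
case_report <- function(case_id, v_cleft_mm3, v_graft_mm3, v_integrated_mm3,
                        v_missing_mm3, filling_rate_pct = NA_real_,
                        restoration_pct = NA_real_,
                        resorption_pct = NA_real_) {
  vols <- c(v_cleft_mm3, v_graft_mm3, v_integrated_mm3, v_missing_mm3)
  if (any(!is.finite(vols)) || any(vols < 0))
    stop("volumes must be finite and nonnegative")
  if (v_integrated_mm3 > v_graft_mm3 + 1e-9)
    stop("v_integrated must not exceed v_graft")
  v_resorption_mm3 <- v_graft_mm3 - v_integrated_mm3
  structure(list(case_id = as.character(case_id),
                 v_cleft_mm3 = v_cleft_mm3,
                 v_graft_mm3 = v_graft_mm3,
                 v_integrated_mm3 = v_integrated_mm3,
                 v_resorption_mm3 = v_resorption_mm3,
                 v_missing_mm3 = v_missing_mm3,
                 filling_rate_pct = filling_rate_pct,
                 restoration_pct = restoration_pct,
                 resorption_pct = resorption_pct),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf(paste0("<case_report %s> cleft %.1f, graft %.1f, integrated ",
                     "%.1f, resorbed %.1f, missing %.1f mm^3 | filling ",
                     "%.1f%%, restoration %.1f%%, resorption %.1f%%\n"),
              x$case_id, x$v_cleft_mm3, x$v_graft_mm3, x$v_integrated_mm3,
              x$v_resorption_mm3, x$v_missing_mm3, x$filling_rate_pct,
              x$restoration_pct, x$resorption_pct))
  invisible(x)
}

report_fields <- c("case_id", "v_cleft_mm3", "v_graft_mm3",
                   "v_integrated_mm3", "v_resorption_mm3", "v_missing_mm3",
                   "filling_rate_pct", "restoration_pct", "resorption_pct")

#' Convert case reports to a data frame
#'
#' @param reports A list of [case_report()] objects.
#' @return A data frame with one row per case and one column per field.
#' @export
reports_to_frame <- function(reports) {
  if (inherits(reports, "case_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    as.data.frame(r[report_fields], stringsAsFactors = FALSE)
  }))
}

#' Write case reports as CSV with a full-precision JSON sidecar
#'
#' @param reports A non-empty list of [case_report()] objects with unique
#'   `case_id`s.
#' @param path Output CSV path; a `.json` sidecar with unrounded values is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "case_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("no case reports to write")
  df <- reports_to_frame(reports)
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id in reports: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "))
  write.csv(df, path, row.names = FALSE)
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read back a CSV report written by [write_report()]
#'
#' @param path CSV path.
#' @return A list of [case_report()] objects.
#' @export
read_report <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    case_report(df$case_id[i], df$v_cleft_mm3[i], df$v_graft_mm3[i],
                df$v_integrated_mm3[i], df$v_missing_mm3[i],
                df$filling_rate_pct[i], df$restoration_pct[i],
                df$resorption_pct[i])
  })
}
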