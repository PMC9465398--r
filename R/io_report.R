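#' Write a result report
#'
#' Writes a data frame (a validation report, cover summary, calibration table
#' or per-location summary) as CSV with a commented header block documenting
#' each column. Numeric columns are written at full double precision so that
#' [read_report()] reproduces every value exactly.
#'
#' @param report Data frame to write.
#' @param path Output path.
#' @param column_notes Optional named character vector of per-column
#'   descriptions for the header block.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, column_notes = NULL) {
  report <- as.data.frame(report)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(report)) {
    note <- if (!is.null(column_notes) && nm %in% names(column_notes)) {
      paste0(": ", column_notes[[nm]])
    } else ""
    writeLines(sprintf("# %s%s", nm, note), con)
  }
  close(con)
  on.exit()
  tmp <- write_full_precision_csv(report, tempfile(fileext = ".csv"))
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with the report rows.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("cannot read report: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
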