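#' Read and write the pipeline's plain-text formats
#'
#' Tracking: CSV with header `time_s,x_cm,y_cm`. Event logs: CSV
#' `time_s,event` with `event` in `puff`, `led`. Lap tables: one row per lap
#' with the lap fields. Traces: CSV whose first column is `time_s` and the
#' remaining columns one per cell.
#'
#' @param path File path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_tracking <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(d))) {
    stop("tracking file ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  d[need]
}

#' @rdname pipeline_io
#' @export
read_event_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "event") %in% names(d))) {
    stop("event log ", path, " must have columns time_s, event")
  }
  bad <- setdiff(unique(d$event), c("puff", "led"))
  if (length(bad)) stop("unknown event type(s) in ", path, ": ",
                        paste(bad, collapse = ", "))
  d
}

#' @rdname pipeline_io
#' @export
read_traces <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "time_s") {
    stop("trace file ", path, " must have time_s as its first column")
  }
  d
}

#' @rdname pipeline_io
#' @param x Object to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
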