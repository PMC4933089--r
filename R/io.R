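#' Write or read a metrics time series
#'
#' One CSV row per generation with a stable column order; a written file
#' reads back into an identical data frame.
#'
#' @param records metrics data.frame (e.g. `run$metrics`), non-empty.
#' @param path output file.
#' @return `write_timeseries()` returns `path` invisibly;
#'   `read_timeseries()` the data.frame.
#' @export
write_timeseries <- function(records, path) {
  if (is.null(records) || nrow(records) == 0)
    stop("no records to write")
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  df <- read.csv(path)
  # an all-NA metric column (e.g. dominance in a tumour-free run) must come
  # back numeric, not logical
  for (j in seq_along(df))
    if (is.logical(df[[j]]) && all(is.na(df[[j]]))) df[[j]] <- as.numeric(df[[j]])
  df
}

#' Write an element-state snapshot
#'
#' Writes a grid's element-state matrix (integer codes, see
#' [element_state_codes()]) as headerless CSV, one row per grid row, and
#' optionally as a plain-text portable greymap (`P2`) for quick viewing.
#'
#' @param states integer matrix of element-state codes.
#' @param path output file.
#' @param format `"csv"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(states, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(states, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    maxcode <- max(ELEMENT_STATES)
    lines <- c("P2", paste(ncol(states), nrow(states)), as.character(maxcode),
               apply(states, 1, paste, collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}
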