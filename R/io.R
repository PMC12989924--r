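#' Read a right-censored survival table from CSV/TSV
#'
#' Reads a delimited file with a header, validates the time and event
#' columns, and drops rows with missing values in the used columns (reported
#' via a message, mirroring complete-case analysis).
#'
#' @param path file path (comma- or tab-separated, detected from the
#'   extension: \code{.tsv}/\code{.txt} are read as tab-separated).
#' @param time_col,event_col column names of observed time and 0/1 event
#'   indicator.
#' @param covariate_cols covariate column names; default all other columns.
#' @return validated data.frame with \code{time}, \code{event} and covariate
#'   columns; attribute \code{n_dropped} counts excluded rows.
#' @export
read_survival_table <- function(path, time_col = "time", event_col = "event",
                                covariate_cols = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE)
  for (col in c(time_col, event_col)) {
    if (!col %in% names(raw)) stop("column '", col, "' not found in ", path)
  }
  if (is.null(covariate_cols)) {
    covariate_cols <- setdiff(names(raw), c(time_col, event_col))
  } else if (!all(covariate_cols %in% names(raw))) {
    stop("covariate column(s) not found: ",
         paste(setdiff(covariate_cols, names(raw)), collapse = ", "))
  }
  used <- c(time_col, event_col, covariate_cols)
  time <- suppressWarnings(as.numeric(raw[[time_col]]))
  bad_time <- which(!is.na(raw[[time_col]]) & is.na(time))
  if (length(bad_time)) {
    stop("non-numeric time in column '", time_col, "', row(s) ",
         paste(utils::head(bad_time, 5), collapse = ", "))
  }
  ev <- raw[[event_col]]
  bad_ev <- which(!is.na(ev) & !(ev %in% c(0, 1)))
  if (length(bad_ev)) {
    stop("event column '", event_col, "' must be 0/1; offending row(s) ",
         paste(utils::head(bad_ev, 5), collapse = ", "))
  }
  neg <- which(!is.na(time) & time < 0)
  if (length(neg)) {
    stop("negative time in column '", time_col, "', row(s) ",
         paste(utils::head(neg, 5), collapse = ", "))
  }
  keep <- stats::complete.cases(raw[used])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing values in used columns removed")
  }
  out <- raw[keep, used, drop = FALSE]
  names(out)[1:2] <- c("time", "event")
  out$time <- as.numeric(out$time)
  out$event <- as.integer(out$event)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a simulated dataset with its configuration sidecar
#'
#' Writes the survival table as full-precision CSV and, when the dataset
#' carries a generating config attribute, a JSON sidecar
#' (\code{<path>.config.json}) for provenance.
#'
#' @param dat dataset from one of the \code{simulate_*} generators (or any
#'   data.frame with \code{time}/\code{event}).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_survival_table <- function(dat, path) {
  write.csv(dat, path, row.names = FALSE, quote = FALSE)
  cfg <- attr(dat, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
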