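# Device-style run logs and diagnostic traces.
#
# Comma-delimited with a header row, period decimal separator, UTF-8. The
# first line is a versioned format marker so readers can reject files written
# by an incompatible major version.

RUNLOG_MAGIC <- "# apc_runlog v1.0"
DIAG_MAGIC <- "# apc_diagnostic v1.0"

fmt_num <- function(x) {
  # round-trip-lossless formatting for doubles
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

runlog_columns <- c("run_id", "target", "counted", "dispensed", "residual_out",
                    "carryover_in", "duration", "mean_lps", "complete",
                    "detector", "lps_setting", "seed")

#' Write a dispensing run log
#'
#' One row per run, comma-delimited, preceded by a versioned format marker
#' line. Numeric fields are written with enough digits to round-trip
#' losslessly.
#'
#' @param runs A `dispense_chain`, list of `dispense_run`s, or a data.frame
#'   as returned by [runs_table()] / [read_runlog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_runlog <- function(runs, path) {
  tab <- if (is.data.frame(runs)) runs else runs_table(runs)
  missing_cols <- setdiff(runlog_columns, names(tab))
  if (length(missing_cols) > 0 && nrow(tab) > 0)
    stop("run table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) tab <- as.data.frame(
    stats::setNames(rep(list(logical(0)), length(runlog_columns)), runlog_columns))
  tab <- tab[runlog_columns]
  out <- tab
  out$duration <- fmt_num(tab$duration)
  out$mean_lps <- fmt_num(tab$mean_lps)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(RUNLOG_MAGIC, con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_numeric_field <- function(raw, field, offset = 2L) {
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(v) & !(raw %in% c("NA", "")))
  if (length(bad))
    stop(sprintf("run log parse error at line %d, field '%s': '%s' is not numeric",
                 bad[1] + offset, field, raw[bad[1]]), call. = FALSE)
  v
}

#' Read a dispensing run log
#'
#' Validates the format-marker line (rejecting unknown major versions) and
#' each numeric field, reporting the offending line and field on failure.
#'
#' @param path File written by [write_runlog()].
#' @return data.frame with one row per run.
#' @export
read_runlog <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# apc_runlog v", first))
    stop("not an apc run log: missing format marker")
  ver <- sub("^# apc_runlog v", "", first)
  major <- as.integer(strsplit(ver, ".", fixed = TRUE)[[1]][1])
  if (is.na(major) || major != 1L)
    stop("unsupported run log major version: ", ver)
  tab <- utils::read.csv(path, skip = 1, colClasses = "character")
  if (!setequal(names(tab), runlog_columns))
    stop("unexpected run log columns")
  tab <- tab[runlog_columns]
  if (nrow(tab) == 0) {
    for (cl in c("run_id", "target", "counted", "dispensed", "residual_out",
                 "carryover_in", "seed")) tab[[cl]] <- integer(0)
    for (cl in c("duration", "mean_lps")) tab[[cl]] <- numeric(0)
    tab$complete <- logical(0)
    return(tab)
  }
  for (cl in c("run_id", "target", "counted", "dispensed", "residual_out",
               "carryover_in", "seed"))
    tab[[cl]] <- as.integer(check_numeric_field(tab[[cl]], cl))
  for (cl in c("duration", "mean_lps"))
    tab[[cl]] <- check_numeric_field(tab[[cl]], cl)
  tab$complete <- as.logical(tab$complete)
  tab
}

#' Export a diagnostic-mode trace
#'
#' Per-sample rows of the full intensity series with indicators for samples
#' flagged above the detection threshold and samples at which a count was
#' tabulated -- the device's diagnostic output used to develop settings.
#'
#' @param trace A `sensor_trace`.
#' @param events Count-event data.frame from the same run (e.g. from
#'   [smoothed_zscore_count()]); its `"flagged"` attribute supplies the flag
#'   column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_diagnostic <- function(trace, events, path) {
  y <- trace$intensity
  flagged <- attr(events, "flagged")
  if (is.null(flagged)) flagged <- rep(FALSE, length(y))
  if (length(flagged) != length(y))
    stop("trace and events lengths do not match")
  if (nrow(events) && max(events$sample_index) > length(y))
    stop("count events fall outside the trace")
  counted <- rep(0L, length(y))
  counted[events$sample_index] <- 1L
  tab <- data.frame(time_msec = fmt_num((seq_along(y) - 1) / trace$sampling_rate),
                    intensity = fmt_num(y),
                    flagged = as.integer(flagged),
                    count = counted)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(DIAG_MAGIC, con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a diagnostic-mode trace file
#'
#' @param path File written by [export_diagnostic()].
#' @return data.frame with `time_msec`, `intensity`, `flagged`, `count`.
#' @export
read_diagnostic <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# apc_diagnostic v", first))
    stop("not an apc diagnostic file: missing format marker")
  tab <- utils::read.csv(path, skip = 1)
  if (any(tab$count > tab$flagged & tab$count == 1 & tab$flagged == 0)) {
    # a tabulated count always lies on a flagged sample
    stop("malformed diagnostic file: count indicator without flag")
  }
  tab
}
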