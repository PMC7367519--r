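#' Read minute-epoch wearable data
#'
#' Reads one epoch CSV file, or every `*.csv` file in a directory, in the
#' canonical dialect: comma-separated, UTF-8, mandatory header, columns
#' `participant_id`, `date` (ISO-8601), `minute_of_day` (0-1439), `met`
#' (non-negative float), `steps` (non-negative integer), `on_body` (0/1),
#' `asleep` (0/1). Files named `<participant_id>_<week>.csv` contribute a
#' `week` column parsed from the filename. Rows are sorted by
#' (participant, date, minute); duplicate minutes within a participant-day
#' are an error; missing minutes are allowed and treated as off-body by the
#' summarisation step.
#'
#' @param path A file or a directory of epoch CSV files.
#' @param week Assessment week to attach when it cannot be parsed from the
#'   filename (optional).
#' @return A `data.table` of epochs (one row per recorded minute).
#' @export
read_epochs <- function(path, week = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no .csv files in ", path, call. = FALSE)
    return(data.table::rbindlist(lapply(files, read_epochs, week = week)))
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "participant_id"))
  required <- c("participant_id", "date", "minute_of_day", "met", "steps",
                "on_body", "asleep")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("epoch file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .validate_epochs(dt, path)
  if (!"week" %in% names(dt)) {
    wk <- sub("^.*_([0-9]+)\\.csv$", "\\1", basename(path))
    if (grepl("^[0-9]+$", wk)) {
      dt[, week := as.integer(wk)]
    } else if (!is.null(week)) {
      dt[, week := as.integer(week)]
    }
  }
  data.table::setorderv(dt, intersect(c("participant_id", "date",
                                        "minute_of_day"), names(dt)))
  dt[]
}

.validate_epochs <- function(dt, path) {
  bad_row <- function(i, field, why) {
    stop(sprintf("%s: row %d, field '%s': %s", path, i, field, why),
         call. = FALSE)
  }
  m <- dt$minute_of_day
  if (anyNA(m) || any(m < 0L | m > 1439L)) {
    i <- which(is.na(m) | m < 0L | m > 1439L)[1L]
    bad_row(i, "minute_of_day", "must be an integer in 0..1439")
  }
  if (anyNA(dt$met) || any(dt$met < 0)) {
    i <- which(is.na(dt$met) | dt$met < 0)[1L]
    bad_row(i, "met", "must be a non-negative number")
  }
  if (anyNA(dt$steps) || any(dt$steps < 0)) {
    i <- which(is.na(dt$steps) | dt$steps < 0)[1L]
    bad_row(i, "steps", "must be a non-negative integer")
  }
  for (fl in c("on_body", "asleep")) {
    v <- dt[[fl]]
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      bad_row(which(is.na(v) | !(v %in% c(0L, 1L)))[1L], fl, "must be 0 or 1")
    }
  }
  if (any(dt$asleep == 1L & dt$on_body == 0L)) {
    i <- which(dt$asleep == 1L & dt$on_body == 0L)[1L]
    bad_row(i, "asleep", "off-body minutes carry no sleep classification")
  }
  dup <- duplicated(dt[, c("participant_id", "date", "minute_of_day")])
  if (any(dup)) {
    i <- which(dup)[1L]
    bad_row(i, "minute_of_day",
            "duplicate (participant, date, minute) record")
  }
  invisible(TRUE)
}

#' Write minute-epoch data in the canonical CSV dialect
#'
#' Numeric fields are written unquoted; `met` is written with full precision
#' so that a read/write round trip is lossless.
#'
#' @param epochs Epoch table with the canonical columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  cols <- c("participant_id", "date", "minute_of_day", "met", "steps",
            "on_body", "asleep")
  dt <- data.table::as.data.table(epochs)[, cols, with = FALSE]
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Flag valid wear days and decide assessment validity
#'
#' A wear day is valid when its on-body minutes reach
#' `min_on_body_minutes` (inclusive bound); an assessment is valid when at
#' least `min_valid_days` of its days are valid. An empty day list yields an
#' invalid assessment, not an error.
#'
#' @param days `data.frame` of per-day on-body counts with a column
#'   `on_body_minutes` (e.g. the output of [summarize_days()]), all
#'   belonging to one participant-assessment.
#' @param min_valid_days Minimum count of valid days (default 4).
#' @param min_on_body_minutes On-body minutes per valid day (default 1140).
#' @return List with `days` (input plus/with updated `valid` flag),
#'   `n_valid_days`, and `assessment_valid`.
#' @export
validate_assessment <- function(days, min_valid_days = 4L,
                                min_on_body_minutes = 1140L) {
  if (is.null(days) || nrow(days) == 0L) {
    return(list(days = days, n_valid_days = 0L, assessment_valid = FALSE))
  }
  stopifnot("on_body_minutes" %in% names(days))
  days$valid <- days$on_body_minutes >= min_on_body_minutes
  n_valid <- sum(days$valid)
  list(days = days, n_valid_days = n_valid,
       assessment_valid = n_valid >= min_valid_days)
}
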