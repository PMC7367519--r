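#' Detect bouts in a single day's minute-epoch MET sequence
#'
#' Scans one calendar day of per-minute MET values left to right and returns
#' every maximal episode satisfying the rule: the first and last minute of a
#' bout meet the MET threshold, every internal run of consecutive
#' off-threshold minutes is within the interruption allowance, off-body
#' minutes (and asleep minutes, for waking-only rules) terminate any
#' candidate, and the episode lasts at least the rule's minimum duration.
#' The greedy maximal-extension scan is deterministic and produces the unique
#' disjoint segmentation into maximal valid windows.
#'
#' @param met Numeric vector of per-minute MET values (one calendar day,
#'   length <= 1440).
#' @param rule A [bout_rule()].
#' @param on_body Logical vector, same length as `met`; `FALSE` minutes are
#'   ineligible for any bout. Defaults to all `TRUE`.
#' @param asleep Logical vector, same length as `met`; for waking-only rules
#'   asleep minutes are ineligible. Defaults to all `FALSE`.
#'
#' @return A `data.frame` with one row per bout: `start_minute` and
#'   `end_minute` (0-based, half-open `[start, end)`), `duration_minutes`,
#'   `qualifying_minutes` (minutes meeting the threshold) and
#'   `interruption_minutes` (`duration - qualifying`).
#' @export
#' @examples
#' met <- c(rep(1, 10), rep(3.5, 12), rep(1, 10))
#' detect_bouts(met, default_bout_rules()$mvpa)
detect_bouts <- function(met, rule, on_body = NULL, asleep = NULL) {
  stopifnot(inherits(rule, "bout_rule"))
  n <- length(met)
  if (is.null(on_body)) on_body <- rep(TRUE, n)
  if (is.null(asleep)) asleep <- rep(FALSE, n)
  if (length(on_body) != n || length(asleep) != n) {
    stop("'on_body' and 'asleep' must have the same length as 'met'",
         call. = FALSE)
  }
  if (n > 1440L) stop("a day has at most 1440 minutes", call. = FALSE)
  empty <- data.frame(
    start_minute = integer(), end_minute = integer(),
    duration_minutes = integer(), qualifying_minutes = integer(),
    interruption_minutes = integer()
  )
  if (n == 0L) return(empty)

  eligible <- on_body & (!rule$waking_only | !asleep)
  qualifies <- if (rule$met_comparator == "at_least") {
    met >= rule$met_threshold
  } else {
    met <= rule$met_threshold
  }
  # per-minute code: 2 qualifying, 1 eligible interruption, 0 ineligible
  code <- ifelse(eligible & qualifies, 2L, ifelse(eligible, 1L, 0L))
  r <- rle(code)
  run_len <- r$lengths
  run_val <- r$values
  run_end <- cumsum(run_len)          # 1-based inclusive end of each run
  run_start <- run_end - run_len + 1L

  allow <- rule$max_interruption_run
  total_mode <- rule$interruption_mode == "total"

  bouts <- vector("list", 8L)
  nb <- 0L
  open <- FALSE
  b_start <- b_last_q_end <- 0L
  qual <- intr <- pending <- 0L

  close_block <- function() {
    dur <- b_last_q_end - b_start + 1L
    if (dur >= rule$min_bout_minutes) {
      nb <<- nb + 1L
      bouts[[nb]] <<- c(b_start - 1L, b_last_q_end, dur, qual, intr)
    }
    open <<- FALSE
    qual <<- 0L; intr <<- 0L; pending <<- 0L
  }

  for (k in seq_along(run_val)) {
    v <- run_val[k]
    if (v == 2L) {                    # qualifying run
      if (!open) {
        open <- TRUE
        b_start <- run_start[k]
      } else {
        intr <- intr + pending
      }
      pending <- 0L
      qual <- qual + run_len[k]
      b_last_q_end <- run_end[k]
    } else if (v == 1L && open) {     # interruption run inside a candidate
      ok <- if (total_mode) intr + run_len[k] <= allow else run_len[k] <= allow
      if (ok) pending <- run_len[k] else close_block()
    } else if (v == 0L && open) {     # ineligible minutes terminate
      close_block()
    }
  }
  if (open) close_block()

  if (nb == 0L) return(empty)
  m <- do.call(rbind, bouts[seq_len(nb)])
  data.frame(
    start_minute = m[, 1L], end_minute = m[, 2L],
    duration_minutes = m[, 3L], qualifying_minutes = m[, 4L],
    interruption_minutes = m[, 5L]
  )
}

#' Total bouted minutes for one day under one rule
#'
#' @inheritParams detect_bouts
#' @param credit `"full"` credits a bout's full duration including tolerated
#'   interruption minutes (time accumulated in bouts); `"qualifying_only"`
#'   credits only minutes meeting the threshold.
#' @return Total credited minutes (integer).
#' @export
bouted_minutes <- function(met, rule, on_body = NULL, asleep = NULL,
                           credit = c("full", "qualifying_only")) {
  credit <- match.arg(credit)
  b <- detect_bouts(met, rule, on_body, asleep)
  if (credit == "full") sum(b$duration_minutes) else sum(b$qualifying_minutes)
}

#' Summarize one wear day into daily activity outcomes
#'
#' @param day A `data.frame` of one participant-day of epochs with columns
#'   `minute_of_day`, `met`, `steps`, `on_body`, `asleep`. Minutes absent
#'   from the data are treated as off-body.
#' @param rules Named list of [bout_rule()]s (default [default_bout_rules()]).
#' @param min_on_body_minutes On-body minutes required for a valid wear day
#'   (default 1140, i.e. 19 h of a 24 h wear protocol).
#' @param credit Bout time crediting mode, see [bouted_minutes()].
#'
#' @return One-row `data.frame`: `<rule>_bout_minutes` for each rule,
#'   `steps_total` (steps during on-body waking minutes), `on_body_minutes`,
#'   and `valid`.
#' @export
summarize_day <- function(day, rules = default_bout_rules(),
                          min_on_body_minutes = 1140L,
                          credit = c("full", "qualifying_only")) {
  credit <- match.arg(credit)
  stopifnot(all(c("minute_of_day", "met", "steps", "on_body", "asleep")
                %in% names(day)))
  idx <- day$minute_of_day + 1L
  met <- numeric(1440L)
  steps <- integer(1440L)
  on_body <- logical(1440L)
  asleep <- logical(1440L)
  met[idx] <- day$met
  steps[idx] <- day$steps
  on_body[idx] <- as.logical(day$on_body)
  asleep[idx] <- as.logical(day$asleep)

  out <- lapply(rules, function(r) {
    bouted_minutes(met, r, on_body, asleep, credit = credit)
  })
  names(out) <- paste0(names(rules), "_bout_minutes")
  out$steps_total <- sum(steps[on_body & !asleep])
  out$on_body_minutes <- sum(on_body)
  out$valid <- out$on_body_minutes >= min_on_body_minutes
  as.data.frame(out)
}

#' Summarize all participant-days of an epoch table
#'
#' Applies [summarize_day()] to every (participant, week, date) group of a
#' long epoch table (as returned by [read_epochs()]).
#'
#' @param epochs Epoch `data.frame`/`data.table` with columns
#'   `participant_id`, `week`, `date`, `minute_of_day`, `met`, `steps`,
#'   `on_body`, `asleep`.
#' @inheritParams summarize_day
#' @return A `data.table` with one row per participant-day.
#' @export
summarize_days <- function(epochs, rules = default_bout_rules(),
                           min_on_body_minutes = 1140L,
                           credit = c("full", "qualifying_only")) {
  credit <- match.arg(credit)
  dt <- data.table::as.data.table(epochs)
  keys <- intersect(c("participant_id", "week", "date"), names(dt))
  dt[, summarize_day(.SD, rules = rules,
                     min_on_body_minutes = min_on_body_minutes,
                     credit = credit),
     by = keys]
}

#' Summarize one participant-assessment from its daily summaries
#'
#' Computes mean daily outcomes over valid wear days only. An assessment is
#' valid when at least `min_valid_days` days are valid; invalid assessments
#' are flagged (`assessment_valid = FALSE`) with `NA` outcome means so they
#' can be excluded downstream rather than silently dropped.
#'
#' @param daily Daily summary rows for one participant-assessment (output of
#'   [summarize_days()]). An empty table yields an invalid assessment.
#' @param min_valid_days Minimum number of valid wear days (default 4).
#' @param guideline_weekly_minutes Weekly bouted-MVPA minutes defining
#'   guideline attainment (default 150).
#' @return One-row `data.frame` with mean daily outcomes, `n_valid_days`,
#'   `assessment_valid`, and `meets_guideline` (mean daily bouted MVPA x 7 >=
#'   the guideline).
#' @export
summarize_assessment <- function(daily, min_valid_days = 4L,
                                 guideline_weekly_minutes = 150) {
  daily <- as.data.frame(daily)
  value_cols <- c(grep("_bout_minutes$", names(daily), value = TRUE),
                  "steps_total")
  ok <- nrow(daily) > 0L
  valid <- if (ok) daily[daily$valid %in% TRUE, , drop = FALSE] else daily
  n_valid <- if (ok) nrow(valid) else 0L
  assessment_valid <- n_valid >= min_valid_days
  means <- if (assessment_valid) {
    vapply(valid[, value_cols, drop = FALSE], mean, numeric(1))
  } else {
    stats::setNames(rep(NA_real_, length(value_cols)), value_cols)
  }
  out <- as.data.frame(as.list(means))
  names(out) <- sub("_bout_minutes$", "_mean", names(out))
  names(out)[names(out) == "steps_total"] <- "steps_mean"
  out$n_valid_days <- n_valid
  out$assessment_valid <- assessment_valid
  out$meets_guideline <- if (assessment_valid && "mvpa_mean" %in% names(out)) {
    out$mvpa_mean * 7 >= guideline_weekly_minutes
  } else {
    NA
  }
  out
}

#' Per-assessment summaries for a whole trial
#'
#' Groups daily summaries by participant and assessment week and applies
#' [summarize_assessment()].
#'
#' @param daily Output of [summarize_days()] with `participant_id` and
#'   `week` columns.
#' @inheritParams summarize_assessment
#' @return `data.table`, one row per participant x assessment week.
#' @export
summarize_assessments <- function(daily, min_valid_days = 4L,
                                  guideline_weekly_minutes = 150) {
  dt <- data.table::as.data.table(daily)
  dt[, summarize_assessment(.SD, min_valid_days = min_valid_days,
                            guideline_weekly_minutes = guideline_weekly_minutes),
     by = c("participant_id", "week")]
}
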