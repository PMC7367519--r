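# Intervention-fidelity scoring: the three protocol adherence criteria and
# their per-arm summary percentages.

# half-up integer rounding (2.5 -> 3), matching how the printed adherence
# percentages behave (e.g. 21/26 -> 81)
round_half_up <- function(x) floor(x + 0.5)

#' Score the three intervention-fidelity criteria for one participant
#'
#' A participant adheres to the 12-week protocol if they (1) attended the
#' education session, (2) used their activity tracker on at least 5 days per
#' week in at least 11 of the 12 weeks (a day counts when steps were
#' recorded), and (3) completed at least 3 of the 4 counseling calls.
#'
#' @param attended_education Logical/0-1 flag.
#' @param calls_completed Integer 0-4.
#' @param weekly_wear_days Integer vector of exactly 12 weekly wear-day
#'   counts, each 0-7 (weeks 1-12 from program start).
#' @return List: `edu_met`, `calls_met`, `fitbit_met`, `n_met` (0-3),
#'   `all_met`.
#' @export
score_adherence <- function(attended_education, calls_completed,
                            weekly_wear_days) {
  calls_completed <- as.integer(calls_completed)
  weekly_wear_days <- as.integer(weekly_wear_days)
  if (is.na(calls_completed) || calls_completed < 0L ||
      calls_completed > 4L) {
    stop("'calls_completed' must be an integer in 0..4", call. = FALSE)
  }
  if (length(weekly_wear_days) != 12L || anyNA(weekly_wear_days) ||
      any(weekly_wear_days < 0L | weekly_wear_days > 7L)) {
    stop("'weekly_wear_days' must be 12 integers in 0..7", call. = FALSE)
  }
  edu_met <- isTRUE(as.logical(attended_education))
  calls_met <- calls_completed >= 3L
  fitbit_met <- sum(weekly_wear_days >= 5L) >= 11L
  n_met <- edu_met + calls_met + fitbit_met
  list(edu_met = edu_met, calls_met = calls_met, fitbit_met = fitbit_met,
       n_met = n_met, all_met = n_met == 3L)
}

#' Read an adherence log in the canonical CSV dialect
#'
#' Columns: `participant_id`, `attended_education` (0/1),
#' `calls_completed` (0-4), `wk1`..`wk12` (weekly wear-day counts 0-7).
#'
#' @param path CSV file path.
#' @return `data.frame` of adherence records.
#' @export
read_adherence <- function(path) {
  dt <- data.table::fread(path,
                          colClasses = list(character = "participant_id"))
  need <- c("participant_id", "attended_education", "calls_completed",
            sprintf("wk%d", 1:12))
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("adherence log lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as.data.frame(dt)
}

#' Score an adherence log participant by participant
#'
#' @param records Adherence `data.frame` (see [read_adherence()]).
#' @return Input with logical columns `edu_met`, `calls_met`, `fitbit_met`
#'   and integer `n_met`, logical `all_met` appended.
#' @export
score_adherence_records <- function(records) {
  wk_cols <- sprintf("wk%d", 1:12)
  scored <- lapply(seq_len(nrow(records)), function(i) {
    score_adherence(records$attended_education[i],
                    records$calls_completed[i],
                    unlist(records[i, wk_cols]))
  })
  records$edu_met <- vapply(scored, `[[`, logical(1), "edu_met")
  records$calls_met <- vapply(scored, `[[`, logical(1), "calls_met")
  records$fitbit_met <- vapply(scored, `[[`, logical(1), "fitbit_met")
  records$n_met <- vapply(scored, `[[`, integer(1), "n_met")
  records$all_met <- vapply(scored, `[[`, logical(1), "all_met")
  records
}

#' Per-arm adherence summary (counts and percentages)
#'
#' For each arm and overall: the count and percentage of participants
#' meeting each criterion, at least two criteria, and all three.
#' Percentages are integers rounded half-up; for an empty arm they are
#' `NA` (blank), not 0.
#'
#' @param records Adherence `data.frame`.
#' @param roster Roster with `participant_id` and `arm`.
#' @return `data.frame`: one row per (group in IG/DG/Overall) x criterion,
#'   columns `group`, `criterion`, `n_met`, `n_total`, `pct`.
#' @export
summarize_adherence <- function(records, roster) {
  unknown <- setdiff(records$participant_id, roster$participant_id)
  if (length(unknown)) {
    stop("adherence record(s) without roster arm: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  scored <- score_adherence_records(records)
  scored$arm <- roster$arm[match(scored$participant_id,
                                 roster$participant_id)]
  crits <- c(education = "edu_met", calls = "calls_met",
             fitbit = "fitbit_met", at_least_2 = NA, all_3 = "all_met")
  one_group <- function(d, label) {
    n <- nrow(d)
    counts <- c(
      education = sum(d$edu_met), calls = sum(d$calls_met),
      fitbit = sum(d$fitbit_met), at_least_2 = sum(d$n_met >= 2L),
      all_3 = sum(d$all_met)
    )
    data.frame(
      group = label, criterion = names(counts), n_met = as.integer(counts),
      n_total = n,
      pct = if (n > 0L) as.integer(round_half_up(100 * counts / n))
            else NA_integer_
    )
  }
  out <- rbind(
    one_group(scored[scored$arm == "IG", , drop = FALSE], "IG"),
    one_group(scored[scored$arm == "DG", , drop = FALSE], "DG"),
    one_group(scored, "Overall")
  )
  rownames(out) <- NULL
  out
}
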