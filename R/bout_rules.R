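#' Define a bout detection rule
#'
#' A bout rule classifies each minute of a day by its MET (metabolic
#' equivalent of task) value and specifies how long an episode must be
#' sustained, and how much sub-threshold interruption it may contain, to
#' count as a bout.
#'
#' @param name Label for the rule (e.g. `"mvpa"`).
#' @param met_threshold MET cutoff defining a qualifying minute.
#' @param met_comparator `"at_least"` (minute qualifies when
#'   `met >= met_threshold`, used for activity rules) or `"at_most"`
#'   (`met <= met_threshold`, used for sedentary behaviour).
#' @param min_bout_minutes Minimum bout duration in minutes.
#' @param max_interruption_run Longest tolerated run of consecutive
#'   off-threshold minutes inside a bout. `0` means no interruption allowed.
#' @param waking_only If `TRUE`, minutes flagged asleep are ineligible and
#'   terminate any candidate bout (used for sedentary behaviour, which is
#'   defined during waking hours only).
#' @param interruption_mode How the interruption allowance is interpreted:
#'   `"run"` (default) bounds each maximal run of consecutive off-threshold
#'   minutes by `max_interruption_run`; `"total"` bounds the total number of
#'   interruption minutes per bout by the same value.
#'
#' @return An object of class `bout_rule`.
#' @seealso [default_bout_rules()] for the standard MVPA / purposeful /
#'   sedentary rule set.
#' @export
#' @examples
#' bout_rule("mvpa", met_threshold = 3, min_bout_minutes = 10,
#'           max_interruption_run = 2)
bout_rule <- function(name,
                      met_threshold,
                      met_comparator = c("at_least", "at_most"),
                      min_bout_minutes = 10L,
                      max_interruption_run = 0L,
                      waking_only = FALSE,
                      interruption_mode = c("run", "total")) {
  met_comparator <- match.arg(met_comparator)
  interruption_mode <- match.arg(interruption_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(met_threshold) || length(met_threshold) != 1L ||
      met_threshold <= 0) {
    stop("'met_threshold' must be a single positive number", call. = FALSE)
  }
  min_bout_minutes <- as.integer(min_bout_minutes)
  max_interruption_run <- as.integer(max_interruption_run)
  if (is.na(min_bout_minutes) || min_bout_minutes < 1L) {
    stop("'min_bout_minutes' must be >= 1", call. = FALSE)
  }
  if (is.na(max_interruption_run) || max_interruption_run < 0L) {
    stop("'max_interruption_run' must be >= 0", call. = FALSE)
  }
  structure(
    list(
      name = name,
      met_threshold = as.numeric(met_threshold),
      met_comparator = met_comparator,
      min_bout_minutes = min_bout_minutes,
      max_interruption_run = max_interruption_run,
      waking_only = isTRUE(waking_only),
      interruption_mode = interruption_mode
    ),
    class = "bout_rule"
  )
}

#' @export
print.bout_rule <- function(x, ...) {
  cmp <- if (x$met_comparator == "at_least") ">=" else "<="
  cat(sprintf(
    "<bout_rule '%s'>: MET %s %.1f, bout >= %d min, interruption %s <= %d min%s\n",
    x$name, cmp, x$met_threshold, x$min_bout_minutes,
    if (x$interruption_mode == "run") "run" else "total",
    x$max_interruption_run,
    if (x$waking_only) ", waking hours only" else ""
  ))
  invisible(x)
}

#' Standard bout rules for wearable physical-activity outcomes
#'
#' Returns the three conventional rules used for daily activity outcomes:
#' \describe{
#'   \item{mvpa}{moderate-to-vigorous physical activity: >= 3 MET sustained
#'     for >= 10 minutes, tolerating interruptions of up to 2 consecutive
#'     minutes below the threshold.}
#'   \item{purposeful}{purposeful activity (e.g. brisk walking): >= 4 MET,
#'     >= 10 minutes, same 2-minute interruption allowance.}
#'   \item{sedentary}{sedentary behaviour: <= 1.5 MET sustained for
#'     >= 20 minutes during waking hours, with no interruption allowance.}
#' }
#'
#' @return Named list of [bout_rule()] objects.
#' @export
default_bout_rules <- function() {
  list(
    mvpa = bout_rule("mvpa", 3.0, "at_least", 10L, 2L),
    purposeful = bout_rule("purposeful", 4.0, "at_least", 10L, 2L),
    sedentary = bout_rule("sedentary", 1.5, "at_most", 20L, 0L,
                          waking_only = TRUE)
  )
}

#' Read bout rules from a YAML file
#'
#' The file maps rule names to fields of [bout_rule()]; omitted fields take
#' that constructor's defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of `bout_rule` objects.
#' @export
read_bout_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("no rules found in ", path, call. = FALSE)
  out <- lapply(names(raw), function(nm) {
    args <- raw[[nm]]
    args$name <- nm
    do.call(bout_rule, args)
  })
  names(out) <- names(raw)
  out
}

#' Write bout rules to a YAML file
#'
#' @param rules Named list of `bout_rule` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bout_rules <- function(rules, path) {
  stopifnot(all(vapply(rules, inherits, logical(1), "bout_rule")))
  yaml::write_yaml(lapply(rules, function(r) r[setdiff(names(r), "name")]),
                   path)
  invisible(path)
}
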