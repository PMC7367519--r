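#' Configuration for a synthetic delay-control trial
#'
#' Defines the ground-truth parameters of a two-arm delay-control (waitlist)
#' trial: the immediate group (IG) starts the program after baseline, the
#' delay group (DG) starts it one assessment later, so exposure is staggered
#' across arms and calendar time. Assessments occur at `assessment_weeks`
#' (baseline plus follow-ups); time since program initiation at each
#' assessment is 0/12/25/38 weeks for the IG and 0/0/12/25 for the DG under
#' the default schedule.
#'
#' The latent mean daily bouted-MVPA for participant *i* in arm *a* at
#' assessment *t* is
#' `(L_i + trend_t + effect_e(a,t)) * R_it`, where `L_i` is a gamma-shaped
#' participant level (mean `baseline_mean_by_arm[a]`, SD `participant_sd`,
#' with an outlier mixture component of rate `skew_outlier_rate` and mean
#' `outlier_mean`), `trend` is the secular trend, `effect` the exposure
#' effect, and `R_it` mean-one gamma noise whose SD scales to
#' `residual_sd` at the reference activity level. Realized daily values add
#' mean-one gamma day noise with coefficient of variation `day_cv`. All
#' multiplicative noise has mean one, so `true_exposure_effects` are exact
#' additive effects on mean minutes/day and recovery against ground truth is
#' well defined.
#'
#' @param n_per_arm Participants per arm.
#' @param assessment_weeks Strictly increasing integer weeks, first one the
#'   baseline (default `c(0, 13, 26, 39)`).
#' @param exposure_weeks_by_arm Named list (`IG`, `DG`) of exposure levels
#'   (weeks since program initiation), one per assessment week. Default
#'   derives the delay design: IG `0/12/25/38`, DG `0/0/12/25`.
#' @param true_exposure_effects Named vector mapping nonzero exposure levels
#'   to added minutes/day of bouted MVPA.
#' @param true_secular_trend Named vector mapping follow-up assessment weeks
#'   to minutes/day of occasion effect common to both arms.
#' @param baseline_mean_by_arm Named vector (`IG`, `DG`) of baseline mean
#'   daily bouted-MVPA minutes.
#' @param participant_sd Between-participant SD of the baseline level
#'   (minutes/day).
#' @param residual_sd Within-participant between-assessment SD at the
#'   reference level (minutes/day).
#' @param day_cv Coefficient of variation of day-to-day noise around the
#'   assessment-level latent mean.
#' @param skew_outlier_rate Probability that a participant is a
#'   high-activity outlier.
#' @param outlier_mean,outlier_sd Mean/SD of the outlier baseline level
#'   (minutes/day; outliers accumulate >300 min/day on average).
#' @param dropout_prob Probability that a participant misses any given
#'   follow-up assessment (baseline is always observed).
#' @param wear_days_per_assessment Monitoring days per assessment.
#' @param block_sizes Permitted permuted-block sizes for randomization.
#' @param steps_base_mean,steps_base_sd Between-participant distribution of
#'   the daily step base.
#' @param steps_per_mvpa_min Steps added per daily bouted-MVPA minute
#'   (couples steps to MVPA).
#' @param steps_day_sd Day-level step noise SD.
#' @param sedentary_mean,sedentary_sd,sedentary_day_sd Sedentary bout
#'   minutes/day: between-participant mean/SD and day-level SD.
#' @param sleep_start_minute,sleep_end_minute Nightly sleep window (minutes
#'   of day; default 23:00-07:00). Defines the waking hours used by the
#'   sedentary rule.
#' @param seed Default seed used by generation functions when no explicit
#'   seed is passed.
#'
#' @return An object of class `trial_config` (validated list).
#' @export
trial_config <- function(n_per_arm = 25L,
                         assessment_weeks = c(0L, 13L, 26L, 39L),
                         exposure_weeks_by_arm = NULL,
                         true_exposure_effects = c("12" = 9.4, "25" = -3.0,
                                                   "38" = 0.2),
                         true_secular_trend = c("13" = 2, "26" = 4, "39" = 3),
                         baseline_mean_by_arm = c(IG = 45, DG = 45),
                         participant_sd = 30,
                         residual_sd = 15,
                         day_cv = 0.6,
                         skew_outlier_rate = 0.04,
                         outlier_mean = 320,
                         outlier_sd = 80,
                         dropout_prob = 0.1,
                         wear_days_per_assessment = 7L,
                         block_sizes = c(2L, 4L),
                         steps_base_mean = 6500,
                         steps_base_sd = 2000,
                         steps_per_mvpa_min = 60,
                         steps_day_sd = 1200,
                         sedentary_mean = 550,
                         sedentary_sd = 120,
                         sedentary_day_sd = 60,
                         sleep_start_minute = 1380L,
                         sleep_end_minute = 420L,
                         seed = 1L) {
  n_per_arm <- as.integer(n_per_arm)
  assessment_weeks <- as.integer(assessment_weeks)
  if (n_per_arm < 1L) stop("'n_per_arm' must be >= 1", call. = FALSE)
  if (length(assessment_weeks) < 2L ||
      any(diff(assessment_weeks) <= 0L) || assessment_weeks[1L] != 0L) {
    stop("'assessment_weeks' must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (is.null(exposure_weeks_by_arm)) {
    ig <- c(0L, pmax(0L, assessment_weeks[-1L] - 1L))
    dg <- c(0L, ig[-length(ig)])  # DG lags IG by one assessment
    exposure_weeks_by_arm <- list(IG = ig, DG = dg)
  }
  for (arm in c("IG", "DG")) {
    ex <- exposure_weeks_by_arm[[arm]]
    if (length(ex) != length(assessment_weeks)) {
      stop("exposure schedule for ", arm,
           " must have one level per assessment week", call. = FALSE)
    }
    if (ex[1L] != 0L) {
      stop("both arms must have exposure 0 at baseline", call. = FALSE)
    }
  }
  sds <- c(participant_sd, residual_sd, day_cv, outlier_sd, steps_base_sd,
           steps_day_sd, sedentary_sd, sedentary_day_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (skew_outlier_rate < 0 || skew_outlier_rate > 1 ||
      dropout_prob < 0 || dropout_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  nonzero <- setdiff(unique(unlist(exposure_weeks_by_arm)), 0L)
  missing_eff <- setdiff(as.character(nonzero), names(true_exposure_effects))
  if (length(missing_eff)) {
    stop("'true_exposure_effects' lacks level(s): ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  }
  missing_tr <- setdiff(as.character(assessment_weeks[-1L]),
                        names(true_secular_trend))
  if (length(missing_tr)) {
    stop("'true_secular_trend' lacks week(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  if (!all(c("IG", "DG") %in% names(baseline_mean_by_arm))) {
    stop("'baseline_mean_by_arm' must name both IG and DG", call. = FALSE)
  }
  structure(
    list(
      n_per_arm = n_per_arm,
      assessment_weeks = assessment_weeks,
      exposure_weeks_by_arm = lapply(exposure_weeks_by_arm, as.integer),
      true_exposure_effects = true_exposure_effects,
      true_secular_trend = true_secular_trend,
      baseline_mean_by_arm = baseline_mean_by_arm,
      participant_sd = participant_sd,
      residual_sd = residual_sd,
      day_cv = day_cv,
      skew_outlier_rate = skew_outlier_rate,
      outlier_mean = outlier_mean,
      outlier_sd = outlier_sd,
      dropout_prob = dropout_prob,
      wear_days_per_assessment = as.integer(wear_days_per_assessment),
      block_sizes = as.integer(block_sizes),
      steps_base_mean = steps_base_mean,
      steps_base_sd = steps_base_sd,
      steps_per_mvpa_min = steps_per_mvpa_min,
      steps_day_sd = steps_day_sd,
      sedentary_mean = sedentary_mean,
      sedentary_sd = sedentary_sd,
      sedentary_day_sd = sedentary_day_sd,
      sleep_start_minute = as.integer(sleep_start_minute),
      sleep_end_minute = as.integer(sleep_end_minute),
      seed = as.integer(seed)
    ),
    class = "trial_config"
  )
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("<trial_config>: %d per arm, assessments at weeks %s\n",
              x$n_per_arm, paste(x$assessment_weeks, collapse = "/")))
  cat(sprintf("  exposure IG %s | DG %s\n",
              paste(x$exposure_weeks_by_arm$IG, collapse = "/"),
              paste(x$exposure_weeks_by_arm$DG, collapse = "/")))
  cat(sprintf("  effects: %s; trend: %s\n",
              paste(sprintf("E%s=%.1f", names(x$true_exposure_effects),
                            x$true_exposure_effects), collapse = " "),
              paste(sprintf("T%s=%.1f", names(x$true_secular_trend),
                            x$true_secular_trend), collapse = " ")))
  invisible(x)
}

#' Read a trial configuration from YAML or JSON
#'
#' The file's keys map 1:1 to the arguments of [trial_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `trial_config`.
#' @export
read_trial_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (nm in c("true_exposure_effects", "true_secular_trend",
               "baseline_mean_by_arm")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(trial_config, raw)
}

#' Exposure level (weeks since program initiation) for an arm at a week
#'
#' @param arm `"IG"` or `"DG"`.
#' @param week An assessment week of the configuration.
#' @param config A [trial_config()].
#' @return Integer exposure level.
#' @export
exposure_weeks <- function(arm, week, config) {
  n <- max(length(arm), length(week))
  arm <- rep_len(arm, n)
  i <- rep_len(match(week, config$assessment_weeks), n)
  if (anyNA(i) || !all(arm %in% c("IG", "DG"))) {
    stop("unknown (arm, week) combination", call. = FALSE)
  }
  vapply(seq_len(n), function(k) {
    config$exposure_weeks_by_arm[[arm[k]]][i[k]]
  }, integer(1))
}
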