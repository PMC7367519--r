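# Synthetic-trial generator: rosters, latent outcomes, minute-epoch days,
# questionnaires and adherence logs with known ground truth.

# mean-one / mean-sd gamma draws (sd == 0 collapses to the mean)
.rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0 || mean <= 0) return(rep(max(mean, 0), n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

#' Generate a permuted-block randomized participant roster
#'
#' Allocates `2 * n_per_arm` participants 1:1 to the immediate group (IG)
#' and the delay group (DG) using randomly permuted variable blocks whose
#' sizes are drawn from `config$block_sizes`. Within every completed block
#' the arm counts are exactly equal, so total arm counts are equal.
#' Demographics (age, sex, BMI) are drawn at the scale typical of a knee
#' osteoarthritis trial population.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return `data.frame`: `participant_id`, `arm`, `block_id`, `age`, `sex`,
#'   `bmi`, ordered by randomization sequence.
#' @export
generate_roster <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  if (any(config$block_sizes %% 2L != 0L)) {
    stop("block sizes must be even for 1:1 allocation", call. = FALSE)
  }
  set.seed(seed)
  n_total <- 2L * config$n_per_arm
  arm <- character(0)
  block <- integer(0)
  b <- 0L
  while (length(arm) < n_total) {
    remaining <- n_total - length(arm)
    sizes_ok <- config$block_sizes[config$block_sizes <= remaining]
    size <- if (length(sizes_ok)) sizes_ok[sample.int(length(sizes_ok), 1L)]
            else remaining
    b <- b + 1L
    arm <- c(arm, sample(rep(c("IG", "DG"), size / 2L)))
    block <- c(block, rep(b, size))
  }
  n <- length(arm)
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    arm = arm,
    block_id = block,
    age = round(stats::rnorm(n, 62, 9)),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.82, 0.18)),
    bmi = round(pmax(17, stats::rnorm(n, 29.4, 7.7)), 1)
  )
}

#' Latent mean daily bouted-MVPA for a participant-timepoint
#'
#' The deterministic fixed-effect mean: arm baseline + secular trend at the
#' assessment + exposure effect for the arm's weeks-since-initiation at that
#' assessment, plus the participant's own intercept (level deviation).
#'
#' @param arm `"IG"` or `"DG"`.
#' @param week Assessment week (must belong to the configuration).
#' @param config A [trial_config()].
#' @param intercept Participant-level deviation from the arm baseline mean
#'   (minutes/day, default 0).
#' @return Latent mean minutes/day.
#' @export
latent_outcome <- function(arm, week, config, intercept = 0) {
  ex <- exposure_weeks(arm, week, config)
  trend <- ifelse(week == 0L, 0,
                  config$true_secular_trend[as.character(week)])
  eff <- ifelse(ex == 0L, 0,
                config$true_exposure_effects[as.character(ex)])
  unname(config$baseline_mean_by_arm[arm] + trend + eff + intercept)
}

# Participant-level ground truth (levels, propensities), drawn from the
# current RNG stream.
.draw_participants <- function(config, roster) {
  n <- nrow(roster)
  is_outlier <- stats::runif(n) < config$skew_outlier_rate
  level <- numeric(n)
  for (a in c("IG", "DG")) {
    sel <- roster$arm == a & !is_outlier
    level[sel] <- .rgamma_ms(sum(sel), config$baseline_mean_by_arm[[a]],
                             config$participant_sd)
  }
  level[is_outlier] <- .rgamma_ms(sum(is_outlier), config$outlier_mean,
                                  config$outlier_sd)
  data.frame(
    participant_id = roster$participant_id,
    arm = roster$arm,
    block_id = roster$block_id,
    outlier = is_outlier,
    level = level,
    intercept = level - unname(config$baseline_mean_by_arm[roster$arm]),
    steps_base = stats::rnorm(n, config$steps_base_mean,
                              config$steps_base_sd),
    sedentary_base = pmax(0, stats::rnorm(n, config$sedentary_mean,
                                          config$sedentary_sd)),
    wear_propensity = stats::rbeta(n, 12, 1.6),
    call_prob = rep(0.88, n),
    edu_prob = rep(1.0, n)
  )
}

# Latent assessment-level means m_it for every participant x week, plus
# observation (dropout) flags.
.draw_latent <- function(config, participants) {
  ref <- mean(config$baseline_mean_by_arm)
  grid <- expand.grid(
    participant_id = participants$participant_id,
    week = config$assessment_weeks,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$participant_id, grid$week), , drop = FALSE]
  i <- match(grid$participant_id, participants$participant_id)
  grid$arm <- participants$arm[i]
  grid$block_id <- participants$block_id[i]
  grid$exposure <- exposure_weeks(grid$arm, grid$week, config)
  fixed <- latent_outcome(grid$arm, grid$week, config)
  base_mean <- pmax(0, fixed + participants$intercept[i])
  resid_cv <- if (ref > 0) config$residual_sd / ref else 0
  r_noise <- if (resid_cv > 0) {
    .rgamma_ms(nrow(grid), 1, resid_cv)
  } else {
    rep(1, nrow(grid))
  }
  grid$latent_mean <- base_mean * r_noise
  grid$observed <- grid$week == 0L |
    stats::runif(nrow(grid)) >= config$dropout_prob
  grid
}

#' Simulate assessment-level trial outcomes (fast path)
#'
#' Draws the full latent trial and returns assessment-level observed mean
#' daily bouted-MVPA per participant-week — the values the epoch pipeline
#' would produce, without synthesizing minute epochs (day-level gamma noise
#' is averaged over the configured wear days). Used for Monte-Carlo
#' recovery, coverage, and error-rate experiments where thousands of trials
#' are needed.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return List: `data` (one row per observed participant-week:
#'   `participant_id`, `arm`, `block_id`, `week`, `exposure`, `outcome`
#'   (`"mvpa"`), `value`), and `truth` (`participants`, `latent`, `config`).
#' @export
simulate_outcomes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  roster <- generate_roster(config, seed = seed)  # seeds the stream
  participants <- .draw_participants(config, roster)
  latent <- .draw_latent(config, participants)
  k <- config$wear_days_per_assessment
  day_noise <- if (config$day_cv > 0) {
    matrix(.rgamma_ms(nrow(latent) * k, 1, config$day_cv), nrow(latent), k)
  } else {
    matrix(1, nrow(latent), k)
  }
  value <- latent$latent_mean * rowMeans(day_noise)
  data <- data.frame(
    participant_id = latent$participant_id,
    arm = latent$arm,
    block_id = latent$block_id,
    week = latent$week,
    exposure = latent$exposure,
    outcome = "mvpa",
    value = value
  )[latent$observed, , drop = FALSE]
  rownames(data) <- NULL
  list(data = data,
       truth = list(participants = participants, latent = latent,
                    config = config))
}

#' Synthesize one 1440-minute epoch day with known bouted outcomes
#'
#' Constructive inverse of the bout engine: builds a full day of per-minute
#' MET/steps/wear flags such that the engine, run with the default rules,
#' reports exactly `target_bouted_mvpa` minutes of bouted MVPA and at least
#' `target_sedentary_bout_min` minutes of sedentary bouts. Above-threshold
#' time is placed as explicit bouts (each >= 10 min, separated by >= 3
#' sub-threshold minutes so bouts cannot merge), optionally carrying legal
#' interruption runs of 1-2 minutes counted inside the bout. Non-bout waking
#' time is filled with MET values in (1.5, 3) — classifiable as neither MVPA
#' nor sedentary — including short "junk" runs of >= 3 MET under 10 minutes
#' that a correct engine must not count. Steps are allocated to sum exactly
#' to `target_steps`. Draws from the current RNG stream.
#'
#' @param target_bouted_mvpa Integer minutes; 0 or >= 10 (a positive total
#'   below the minimum bout duration is infeasible).
#' @param target_steps Total daily steps (integer >= 0).
#' @param target_sedentary_bout_min Minimum sedentary bout minutes to place
#'   (blocks of >= 20 min during waking hours; the realized total may exceed
#'   the target by < 20 min).
#' @param allow_interruptions Insert legal sub-threshold interruption runs
#'   inside MVPA bouts.
#' @param n_junk_runs Number of sub-10-minute >= 3 MET runs to scatter.
#' @param mvpa_met_range Range of per-bout base MET for MVPA bouts; bouts
#'   with base >= 4 also accrue purposeful activity.
#' @param sleep_start_minute,sleep_end_minute Nightly sleep window.
#' @param participant_id,date Identifiers stamped on the rows.
#' @return `data.table` of 1440 epoch rows in the canonical dialect.
#' @export
synthesize_epoch_day <- function(target_bouted_mvpa,
                                 target_steps = 6000L,
                                 target_sedentary_bout_min = 0L,
                                 allow_interruptions = TRUE,
                                 n_junk_runs = 2L,
                                 mvpa_met_range = c(3.1, 5.0),
                                 sleep_start_minute = 1380L,
                                 sleep_end_minute = 420L,
                                 participant_id = "P001",
                                 date = as.Date("2020-01-06")) {
  tm <- as.integer(round(target_bouted_mvpa))
  ts <- as.integer(round(target_steps))
  tsed <- as.integer(round(target_sedentary_bout_min))
  if (tm < 0 || ts < 0 || tsed < 0) {
    stop("targets must be non-negative", call. = FALSE)
  }
  if (tm > 0 && tm < 10L) {
    stop("infeasible target: positive bouted MVPA below the 10-minute ",
         "minimum bout duration", call. = FALSE)
  }

  minute <- 0:1439
  asleep <- minute >= sleep_start_minute | minute < sleep_end_minute
  waking_idx <- which(!asleep)
  n_waking <- length(waking_idx)

  # split MVPA target into bouts of 10-40 min
  mvpa_lens <- integer(0)
  rem <- tm
  while (rem > 0L) {
    b <- if (rem <= 40L) rem else sample(10:min(30L, rem - 10L), 1L)
    mvpa_lens <- c(mvpa_lens, b)
    rem <- rem - b
  }
  # sedentary blocks of 20-60 min covering at least the target
  sed_lens <- integer(0)
  rem <- tsed
  while (rem > 0L) {
    b <- max(20L, min(rem, sample(20:60, 1L)))
    sed_lens <- c(sed_lens, b)
    rem <- rem - b
  }
  junk_lens <- if (n_junk_runs > 0L) sample(4:9, n_junk_runs, replace = TRUE)
               else integer(0)

  features <- c(
    lapply(mvpa_lens, function(l) list(type = "mvpa", len = l)),
    lapply(sed_lens, function(l) list(type = "sed", len = l)),
    lapply(junk_lens, function(l) list(type = "junk", len = l))
  )
  if (length(features)) features <- features[sample.int(length(features))]
  need <- sum(mvpa_lens) + sum(sed_lens) + sum(junk_lens) +
    3L * (length(features) + 1L)
  if (need > n_waking) {
    stop(sprintf(
      "infeasible targets: %d feature minutes + separators exceed the %d",
      need, n_waking), " waking minutes", call. = FALSE)
  }

  met <- stats::runif(1440, 1.6, 2.9)       # neutral filler everywhere
  met[asleep] <- stats::runif(sum(asleep), 0.8, 1.0)
  is_mvpa_min <- logical(1440)

  # lay features along the waking window with >= 3 filler minutes between,
  # spreading the slack randomly over the gaps
  n_gaps <- length(features) + 1L
  slack <- n_waking - need
  extra <- if (slack > 0L && n_gaps > 0L) {
    stats::rmultinom(1L, slack, rep(1, n_gaps))[, 1L]
  } else {
    rep(0L, n_gaps)
  }
  pos <- 1L
  for (k in seq_along(features)) {
    pos <- pos + 3L + extra[k]              # gap before feature k
    f <- features[[k]]
    idx <- waking_idx[pos:(pos + f$len - 1L)]
    if (f$type == "mvpa") {
      base <- stats::runif(1, mvpa_met_range[1], mvpa_met_range[2])
      met[idx] <- pmax(3.01, base + stats::runif(f$len, -0.3, 0.3))
      is_mvpa_min[idx] <- TRUE
      if (allow_interruptions && f$len >= 14L) {
        for (at in unique(c(floor(f$len / 3), floor(2 * f$len / 3)))) {
          ilen <- sample(1:2, 1L)
          ii <- idx[at:(at + ilen - 1L)]
          met[ii] <- stats::runif(ilen, 1.8, 2.8)
          is_mvpa_min[ii] <- FALSE
        }
      }
    } else if (f$type == "sed") {
      met[idx] <- stats::runif(f$len, 0.9, 1.49)
    } else {
      met[idx] <- stats::runif(f$len, 3.2, 4.5)
    }
    pos <- pos + f$len
  }

  # exact integer step allocation, weighted toward MVPA minutes
  steps <- integer(1440)
  w <- numeric(1440)
  w[waking_idx] <- 1
  w[is_mvpa_min] <- 10
  if (ts > 0L) {
    alloc <- ts * w / sum(w)
    steps <- floor(alloc)
    shortfall <- ts - sum(steps)
    if (shortfall > 0L) {
      top <- order(alloc - steps, decreasing = TRUE)[seq_len(shortfall)]
      steps[top] <- steps[top] + 1L
    }
  }

  data.table::data.table(
    participant_id = participant_id,
    date = as.character(date),
    minute_of_day = minute,
    met = round(met, 3),
    steps = as.integer(steps),
    on_body = 1L,
    asleep = as.integer(asleep)
  )
}

# internal: snap a continuous daily MVPA value to a feasible integer target
# (bouted minutes are 0 or >= 10 by construction of the bout definition)
.snap_mvpa_target <- function(x) {
  t <- as.integer(round(pmax(0, x)))
  t[t > 0L & t < 5L] <- 0L
  t[t >= 5L & t < 10L] <- 10L
  pmin(t, 700L)  # beyond this a 16-h waking window cannot hold the bouts
}

# largest sedentary target that is guaranteed feasible next to `mvpa`
# bouted minutes: worst-case block split (20-min sedentary blocks, 10-min
# bouts) needs 3 separator minutes per feature plus the junk runs
.max_sedentary_target <- function(mvpa) {
  pmax(0L, as.integer(floor((960 - 1.3 * mvpa - 40) / 1.15)))
}

.instruments <- function() {
  data.frame(
    instrument = c(rep("KOOS", 5), "PIHS", "PHQ9", rep("SRHI", 3),
                   rep("TPB", 4)),
    subscale = c("symptoms", "pain", "adl", "sport_rec", "qol",
                 "total", "total", "sitting_work", "sitting_leisure",
                 "walking", "attitude", "subjective_norm",
                 "perceived_control", "intention"),
    min = c(rep(0, 5), 0, 0, rep(1, 3), rep(1, 4)),
    max = c(rep(100, 5), 96, 27, rep(7, 3), rep(7, 4)),
    mean = c(67, 69, 74, 47, 46, 77, 5.3, 4.8, 4.9, 4.5,
             6.0, 6.2, 5.9, 6.2),
    sd_between = c(rep(11, 5), 9, 3.8, 1.4, 1.1, 1.5, 0.45, 0.55, 0.7, 0.6),
    sd_within = c(rep(7, 5), 5, 2.2, 0.8, 0.7, 0.8, 0.3, 0.35, 0.5, 0.4)
  )
}

# questionnaire scores for every observed participant-week, clamped to
# instrument bounds
.draw_questionnaires <- function(config, participants, latent) {
  ins <- .instruments()
  obs <- latent[latent$observed, c("participant_id", "week")]
  n_p <- nrow(participants)
  rows <- vector("list", nrow(ins))
  for (j in seq_len(nrow(ins))) {
    base <- stats::rnorm(n_p, ins$mean[j], ins$sd_between[j])
    names(base) <- participants$participant_id
    score <- base[obs$participant_id] +
      stats::rnorm(nrow(obs), 0, ins$sd_within[j])
    rows[[j]] <- data.frame(
      participant_id = obs$participant_id,
      week = obs$week,
      instrument = ins$instrument[j],
      subscale = ins$subscale[j],
      score = round(pmin(ins$max[j], pmax(ins$min[j], score)), 1)
    )
  }
  out <- do.call(rbind, rows)
  out[order(out$participant_id, out$week, out$instrument, out$subscale), ]
}

.draw_adherence <- function(config, participants) {
  n <- nrow(participants)
  wk <- matrix(
    stats::rbinom(n * 12L, 7L, rep(participants$wear_propensity, 12L)),
    nrow = n, ncol = 12L
  )
  colnames(wk) <- sprintf("wk%d", 1:12)
  out <- data.frame(
    participant_id = participants$participant_id,
    attended_education = as.integer(stats::runif(n) < participants$edu_prob),
    calls_completed = stats::rbinom(n, 4L, participants$call_prob)
  )
  cbind(out, as.data.frame(wk))
}

#' Generate a complete synthetic trial on disk
#'
#' Writes every artifact a real trial of this design would produce: a
#' permuted-block roster, per-participant minute-epoch CSV files for each
#' assessment (`wear_days_per_assessment` synthesized days whose bouted-MVPA
#' minutes are known exactly), a long questionnaire table, an adherence log,
#' and a `truth.json` with all ground-truth parameters and latent values for
#' recovery testing. Fully reproducible from the seed.
#'
#' @param config A [trial_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (default `config$seed`).
#' @return Invisible list with file paths (`roster`, `epochs_dir`,
#'   `questionnaires`, `adherence`, `truth`) and the in-memory `truth`.
#' @export
generate_trial <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "trial_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  epochs_dir <- file.path(out_dir, "epochs")
  dir.create(epochs_dir, showWarnings = FALSE)

  sim <- simulate_outcomes(config, seed = seed)
  participants <- sim$truth$participants
  latent <- sim$truth$latent
  roster <- participants[, c("participant_id", "arm", "block_id")]
  ros_full <- generate_roster(config, seed = seed)  # same seed: same roster
  set.seed(seed + 1L)                               # stream for artifacts

  ref <- mean(config$baseline_mean_by_arm)
  k <- config$wear_days_per_assessment
  start_date <- as.Date("2020-01-06")
  obs <- latent[latent$observed, , drop = FALSE]
  daily_truth <- vector("list", nrow(obs))
  for (r in seq_len(nrow(obs))) {
    pid <- obs$participant_id[r]
    wkn <- obs$week[r]
    p <- participants[participants$participant_id == pid, ]
    day_noise <- if (config$day_cv > 0) .rgamma_ms(k, 1, config$day_cv)
                 else rep(1, k)
    mvpa_d <- .snap_mvpa_target(obs$latent_mean[r] * day_noise)
    sed_d <- pmax(0, round(p$sedentary_base +
                             stats::rnorm(k, 0, config$sedentary_day_sd)))
    sed_d <- pmin(sed_d, .max_sedentary_target(mvpa_d))
    steps_d <- pmax(0, round(p$steps_base +
                               config$steps_per_mvpa_min * (mvpa_d - ref) +
                               stats::rnorm(k, 0, config$steps_day_sd)))
    days <- lapply(seq_len(k), function(d) {
      synthesize_epoch_day(
        target_bouted_mvpa = mvpa_d[d],
        target_steps = steps_d[d],
        target_sedentary_bout_min = sed_d[d],
        sleep_start_minute = config$sleep_start_minute,
        sleep_end_minute = config$sleep_end_minute,
        participant_id = pid,
        date = start_date + wkn * 7L + (d - 1L)
      )
    })
    write_epochs(data.table::rbindlist(days),
                 file.path(epochs_dir, sprintf("%s_%d.csv", pid, wkn)))
    daily_truth[[r]] <- data.frame(
      participant_id = pid, week = wkn, day = seq_len(k),
      mvpa_target = mvpa_d, sedentary_target = sed_d, steps_target = steps_d
    )
  }
  daily_truth <- do.call(rbind, daily_truth)

  questionnaires <- .draw_questionnaires(config, participants, latent)
  adherence <- .draw_adherence(config, participants)

  paths <- list(
    roster = file.path(out_dir, "roster.csv"),
    epochs_dir = epochs_dir,
    questionnaires = file.path(out_dir, "questionnaires.csv"),
    adherence = file.path(out_dir, "adherence.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  data.table::fwrite(ros_full, paths$roster, quote = FALSE)
  data.table::fwrite(questionnaires, paths$questionnaires, quote = FALSE)
  data.table::fwrite(adherence, paths$adherence, quote = FALSE)

  truth <- list(
    seed = seed,
    config = unclass(config),
    participants = participants,
    latent = latent,
    daily = daily_truth
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
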