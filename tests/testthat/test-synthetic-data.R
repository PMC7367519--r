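test_that("permuted-block roster gives exact 1:1 allocation", {
  cfg <- trial_config(n_per_arm = 25L)
  ros <- generate_roster(cfg, seed = 7)
  expect_equal(nrow(ros), 50L)
  expect_equal(as.integer(table(ros$arm)[c("DG", "IG")]), c(25L, 25L))
  expect_equal(anyDuplicated(ros$participant_id), 0L)

  tiny <- generate_roster(trial_config(n_per_arm = 1L), seed = 3)
  expect_equal(sort(tiny$arm), c("DG", "IG"))

  # completed blocks are internally balanced
  for (b in unique(ros$block_id)) {
    tab <- table(ros$arm[ros$block_id == b])
    expect_equal(unname(tab["IG"]), unname(tab["DG"]))
  }
})

test_that("with block size 2 every consecutive pair holds one of each arm", {
  cfg <- trial_config(n_per_arm = 20L, block_sizes = 2L)
  for (seed in 1:5) {
    ros <- generate_roster(cfg, seed = seed)
    pairs <- matrix(ros$arm, nrow = 2)
    expect_true(all(apply(pairs, 2, function(p) setequal(p, c("IG", "DG")))))
  }
})

test_that("latent outcome is the sum of its stated components", {
  cfg <- trial_config(
    baseline_mean_by_arm = c(IG = 30, DG = 30),
    true_exposure_effects = c("12" = 10, "25" = 5, "38" = 1),
    true_secular_trend = c("13" = 2, "26" = 1, "39" = 0)
  )
  # week 0: all offsets zero
  expect_equal(latent_outcome("IG", 0L, cfg, intercept = 4), 34)
  # IG at week 13: baseline + trend(T13) + effect(12wk)
  expect_equal(latent_outcome("IG", 13L, cfg, intercept = 0), 42)
  # DG at week 13 is still unexposed: baseline + trend only
  expect_equal(latent_outcome("DG", 13L, cfg, intercept = 0), 32)
  expect_error(latent_outcome("IG", 14L, cfg), "unknown")
})

test_that("exposure schedule respects the delay design", {
  cfg <- trial_config()
  expect_equal(exposure_weeks("IG", c(0L, 13L, 26L, 39L), cfg),
               c(0L, 12L, 25L, 38L))
  expect_equal(exposure_weeks("DG", c(0L, 13L, 26L, 39L), cfg),
               c(0L, 0L, 12L, 25L))
  # DG exposure at week w equals IG exposure one assessment earlier
  for (i in 2:4) {
    expect_equal(cfg$exposure_weeks_by_arm$DG[i],
                 cfg$exposure_weeks_by_arm$IG[i - 1L])
  }
})

test_that("synthesized epoch days round-trip exactly through the bout engine", {
  set.seed(11)
  rules <- default_bout_rules()
  targets <- c(0L, 10L, sample(10:240, 40L))
  for (t in targets) {
    sed <- sample(c(0L, 30L, 120L), 1L)
    d <- synthesize_epoch_day(t, target_steps = sample(0:15000, 1L),
                              target_sedentary_bout_min = sed,
                              allow_interruptions = sample(c(TRUE, FALSE), 1L))
    expect_equal(
      bouted_minutes(d$met, rules$mvpa, d$on_body == 1, d$asleep == 1), t)
    expect_gte(
      bouted_minutes(d$met, rules$sedentary, d$on_body == 1, d$asleep == 1),
      sed)
  }
})

test_that("infeasible epoch-day targets fail loudly", {
  expect_error(synthesize_epoch_day(5), "infeasible")
  expect_error(synthesize_epoch_day(950, target_sedentary_bout_min = 500),
               "infeasible")
  expect_error(synthesize_epoch_day(-1), "non-negative")
})

test_that("generated trials are byte-identical under a fixed seed", {
  cfg <- trial_config(n_per_arm = 2L, wear_days_per_assessment = 4L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_trial(cfg, d1, seed = 42)
  generate_trial(cfg, d2, seed = 42)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) > 5)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("noiseless construction gives the exact configured arm contrast", {
  cfg <- trial_config(n_per_arm = 6L, participant_sd = 0, residual_sd = 0,
                      day_cv = 0, skew_outlier_rate = 0, dropout_prob = 0,
                      true_exposure_effects = c("12" = 10, "25" = 5,
                                                "38" = 1))
  sim <- simulate_outcomes(cfg, seed = 5)
  d13 <- sim$data[sim$data$week == 13L, ]
  diff13 <- mean(d13$value[d13$arm == "IG"]) -
    mean(d13$value[d13$arm == "DG"])
  expect_equal(diff13, 10, tolerance = 1e-12)
})

test_that("large null trials have vanishing arm differences", {
  cfg <- trial_config(n_per_arm = 400L,
                      true_exposure_effects = c("12" = 0, "25" = 0,
                                                "38" = 0),
                      skew_outlier_rate = 0, dropout_prob = 0)
  sim <- simulate_outcomes(cfg, seed = 9)
  d13 <- sim$data[sim$data$week == 13L, ]
  diff13 <- mean(d13$value[d13$arm == "IG"]) -
    mean(d13$value[d13$arm == "DG"])
  # MC error scale: sd ~ 37 per participant mean, n = 400/arm -> se ~ 2.6
  expect_lt(abs(diff13), 8)
})

test_that("questionnaire scores stay within instrument bounds", {
  cfg <- trial_config(n_per_arm = 100L, wear_days_per_assessment = 1L)
  dir <- withr::local_tempdir()
  generate_trial(cfg, dir, seed = 21)
  q <- read.csv(file.path(dir, "questionnaires.csv"))
  bounds <- list(KOOS = c(0, 100), PIHS = c(0, 96), PHQ9 = c(0, 27),
                 SRHI = c(1, 7), TPB = c(1, 7))
  for (ins in names(bounds)) {
    v <- q$score[q$instrument == ins]
    expect_true(length(v) > 100)
    expect_gte(min(v), bounds[[ins]][1])
    expect_lte(max(v), bounds[[ins]][2])
  }
  # adherence log shape
  a <- read.csv(file.path(dir, "adherence.csv"))
  expect_true(all(a$calls_completed %in% 0:4))
  wk <- as.matrix(a[, sprintf("wk%d", 1:12)])
  expect_true(all(wk >= 0 & wk <= 7))
})
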