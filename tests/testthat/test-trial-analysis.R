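# small deterministic dataset builders -------------------------------------

mk_dataset <- function(n_per_arm = 10L, seed = 1L, cfg = trial_config()) {
  simulate_outcomes(
    trial_config(n_per_arm = n_per_arm,
                 true_exposure_effects = cfg$true_exposure_effects,
                 true_secular_trend = cfg$true_secular_trend,
                 dropout_prob = 0),
    seed = seed
  )$data
}

test_that("exposure derivation in the analysis dataset follows the delay map", {
  cfg <- trial_config(n_per_arm = 4L, dropout_prob = 0)
  sim <- simulate_outcomes(cfg, seed = 2)
  summaries <- data.frame(participant_id = sim$data$participant_id,
                          week = sim$data$week, outcome = "mvpa",
                          value = sim$data$value)
  roster <- unique(sim$data[, c("participant_id", "arm", "block_id")])
  ds <- build_analysis_dataset(summaries, roster, cfg)
  expect_equal(unique(ds$exposure[ds$arm == "DG" & ds$week == 13L]), 0L)
  expect_equal(unique(ds$exposure[ds$arm == "IG" & ds$week == 39L]), 38L)
  expect_equal(unique(ds$exposure[ds$week == 0L]), 0L)

  # unknown participant and duplicated cells are hard errors
  bad <- rbind(summaries, data.frame(participant_id = "ZZZ", week = 0,
                                     outcome = "mvpa", value = 1))
  expect_error(build_analysis_dataset(bad, roster, cfg), "roster")
  expect_error(build_analysis_dataset(rbind(summaries, summaries[1, ]),
                                      roster, cfg), "duplicated")
})

test_that("ANCOVA coefficient equals an independent normal-equations solve", {
  ds <- mk_dataset(n_per_arm = 15L, seed = 8L)
  fit <- ancova_adjusted_difference(ds, "mvpa")
  base <- ds[ds$week == 0L, ]
  endp <- ds[ds$week == 13L, ]
  cc <- merge(base[, c("participant_id", "arm", "value")],
              endp[, c("participant_id", "value")], by = "participant_id")
  X <- cbind(1, as.numeric(cc$arm == "IG"), cc$value.x)
  beta <- solve(t(X) %*% X, t(X) %*% cc$value.y)
  expect_equal(fit$estimate, beta[2], tolerance = 1e-8)
})

test_that("ANCOVA is symmetric and shift invariant", {
  # identical noiseless arms: difference exactly zero
  ds <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:10), each = 2),
    arm = rep(c("IG", "DG"), each = 10),
    block_id = 1L,
    week = rep(c(0L, 13L), 10),
    exposure = 0L,
    outcome = "mvpa",
    value = rep(c(20, 25, 30, 35, 40), each = 4)
  )
  fit <- ancova_adjusted_difference(ds, "mvpa")
  expect_equal(fit$estimate, 0, tolerance = 1e-10)

  # adding a constant to all values leaves the arm estimate unchanged
  ds2 <- mk_dataset(n_per_arm = 12L, seed = 4L)
  f1 <- ancova_adjusted_difference(ds2, "mvpa")
  ds2$value <- ds2$value + 1000
  f2 <- ancova_adjusted_difference(ds2, "mvpa")
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("ANCOVA errors on degenerate inputs", {
  ds <- mk_dataset(n_per_arm = 4L, seed = 3L)
  ds$value[ds$week == 0L] <- 50
  expect_error(ancova_adjusted_difference(ds, "mvpa"), "zero variance")
  tiny <- mk_dataset(n_per_arm = 2L, seed = 3L)
  expect_error(ancova_adjusted_difference(tiny, "mvpa"), "fewer than 3")
})

test_that("noiseless data identify all 8 mixed-model coefficients exactly", {
  cfg <- trial_config(n_per_arm = 10L, participant_sd = 0, residual_sd = 0,
                      day_cv = 0, skew_outlier_rate = 0, dropout_prob = 0,
                      baseline_mean_by_arm = c(IG = 48, DG = 45),
                      true_exposure_effects = c("12" = 13, "25" = 7,
                                                "38" = 2),
                      true_secular_trend = c("13" = 2, "26" = 4, "39" = 3))
  sim <- simulate_outcomes(cfg, seed = 6)
  fit <- fit_delay_control_lmm(sim$data, "mvpa", cfg)
  truth <- c(`(Intercept)` = 45, group_IG = 3, T13 = 2, T26 = 4, T39 = 3,
             E12 = 13, E25 = 7, E38 = 2)
  est <- setNames(fit$estimate[1:8], fit$term[1:8])
  expect_equal(est, truth, tolerance = 1e-7)
})

test_that("GLS with zero random-intercept variance degenerates to OLS", {
  ds <- mk_dataset(n_per_arm = 12L, seed = 10L)
  fit <- fit_delay_control_lmm(ds, "mvpa",
                               variance_components = list(tau2 = 0,
                                                          sigma2 = 1))
  X <- cbind(1, as.numeric(ds$arm == "IG"),
             as.numeric(ds$week == 13L), as.numeric(ds$week == 26L),
             as.numeric(ds$week == 39L), as.numeric(ds$exposure == 12L),
             as.numeric(ds$exposure == 25L), as.numeric(ds$exposure == 38L))
  ols <- qr.solve(X, ds$value)
  expect_equal(fit$estimate[1:8], unname(ols), tolerance = 1e-6)
})

test_that("sandwich standard errors are invariant to relabeling participants", {
  ds <- mk_dataset(n_per_arm = 10L, seed = 12L)
  f1 <- fit_delay_control_lmm(ds, "mvpa")
  relabel <- setNames(sprintf("Q%03d", sample(20)),
                      unique(ds$participant_id))
  ds2 <- ds
  ds2$participant_id <- unname(relabel[ds$participant_id])
  f2 <- fit_delay_control_lmm(ds2, "mvpa")
  expect_equal(f1$se_sandwich, f2$se_sandwich, tolerance = 1e-8)
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-8)
})

test_that("sandwich intervals keep nominal coverage under occasion heteroskedasticity", {
  mk <- function(seed) {
    set.seed(seed)
    n <- 25L
    ids <- sprintf("P%03d", 1:(2 * n))
    arm <- rep(c("IG", "DG"), each = n)
    b <- rnorm(2 * n, 0, 15)
    g <- expand.grid(i = 1:(2 * n), week = c(0L, 13L, 26L, 39L))
    g$participant_id <- ids[g$i]
    g$arm <- arm[g$i]
    g$exposure <- exposure_weeks(g$arm, g$week, trial_config())
    sdv <- ifelse(g$week == 0L, 10, 10 * sqrt(2))  # variance doubles later
    g$value <- 45 + b[g$i] + rnorm(nrow(g), 0, sdv)
    g$outcome <- "mvpa"
    g$block_id <- 1L
    g
  }
  cover <- 0L
  reps <- 400L
  for (r in seq_len(reps)) {
    f <- fit_delay_control_lmm(mk(1000L + r), "mvpa")
    e <- f[f$term == "E12", ]
    cover <- cover + (e$ci_low <= 0 & 0 <= e$ci_high)
  }
  expect_gte(cover / reps, 0.92)
  expect_lte(cover / reps, 0.98)
})

test_that("rank-deficient designs fail naming the aliased column", {
  ds <- mk_dataset(n_per_arm = 8L, seed = 13L)
  ds <- ds[ds$week != 39L, ]  # E38 never observed
  expect_error(fit_delay_control_lmm(ds, "mvpa"), "E38")
})

test_that("estimate_all covers every outcome with the full term set", {
  ds <- mk_dataset(n_per_arm = 10L, seed = 14L)
  res <- estimate_all(ds)
  # one ANCOVA row + 8 LMM fixed effects + 2 trend contrasts
  expect_equal(nrow(res), 1L + 8L + 2L)
  expect_setequal(unique(res$estimator), c("ancova", "lmm_sandwich"))

  res2 <- estimate_all(ds)
  expect_identical(res, res2)  # deterministic

  # a second outcome multiplies rows; its failure must not abort the rest
  ds_bad <- ds[ds$week %in% c(0L, 13L), ]
  ds_bad$outcome <- "short"
  both <- rbind(ds, ds_bad)
  expect_message(res3 <- estimate_all(both), "failed")
  expect_equal(sum(res3$outcome == "mvpa" & is.na(res3$error)), 11L)
  expect_true(any(res3$outcome == "short" & !is.na(res3$error)))
})

test_that("analytic power matches theory at the edges and is monotone", {
  # null alternative: power equals alpha (one- and two-sided)
  expect_equal(power_two_sample(50, 10, 50, 10, 50, alpha = 0.1,
                                one_sided = TRUE), 0.1, tolerance = 1e-10)
  expect_equal(power_two_sample(50, 10, 50, 10, 50, alpha = 0.05), 0.05,
               tolerance = 1e-10)
  # monotone in alpha and n
  p1 <- power_two_sample(60, 20, 50, 20, 40, alpha = 0.05)
  p2 <- power_two_sample(60, 20, 50, 20, 40, alpha = 0.10)
  p3 <- power_two_sample(60, 20, 50, 20, 80, alpha = 0.05)
  expect_gt(p2, p1)
  expect_gt(p3, p1)
  expect_error(power_two_sample(60, 0, 50, 20, 40), "SDs")
})

test_that("analytic power agrees with a Monte-Carlo t-test simulation", {
  set.seed(31)
  mc_power <- function(ma, sa, mb, sb, n_tot, alpha, one_sided,
                       reps = 20000L) {
    n <- n_tot / 2
    a <- matrix(rnorm(reps * n, ma, sa), n)
    b <- matrix(rnorm(reps * n, mb, sb), n)
    sp2 <- (colSums((a - rep(colMeans(a), each = n))^2) +
              colSums((b - rep(colMeans(b), each = n))^2)) / (n_tot - 2)
    tstat <- (colMeans(a) - colMeans(b)) / sqrt(2 * sp2 / n)
    if (one_sided) mean(tstat > qt(1 - alpha, n_tot - 2))
    else mean(abs(tstat) > qt(1 - alpha / 2, n_tot - 2))
  }
  cases <- list(
    list(75.5, 54.3, 50.0, 46.8, 50, 0.1, TRUE),
    list(60, 20, 50, 20, 60, 0.05, FALSE)
  )
  for (cs in cases) {
    analytic <- do.call(power_two_sample, setNames(
      cs, c("mean_a", "sd_a", "mean_b", "sd_b", "n_total", "alpha",
            "one_sided")))
    mc <- do.call(mc_power, cs)
    expect_equal(analytic, mc, tolerance = 0.015)
  }
})
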