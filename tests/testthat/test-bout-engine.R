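rules <- default_bout_rules()

test_that("single sustained episodes are detected with exact boundaries", {
  # 10 consecutive minutes at >= 3 MET surrounded by light activity
  met <- c(rep(1, 30), rep(3.2, 10), rep(1, 30))
  b <- detect_bouts(met, rules$mvpa)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_minute, 30L)
  expect_equal(b$end_minute, 40L)
  expect_equal(b$duration_minutes, 10L)
  expect_equal(b$interruption_minutes, 0L)

  # 9 minutes falls below the minimum duration
  expect_equal(nrow(detect_bouts(c(rep(1, 10), rep(3.5, 9), rep(1, 10)),
                                 rules$mvpa)), 0L)

  # a quiet day yields nothing
  expect_equal(nrow(detect_bouts(rep(1.0, 1440), rules$mvpa)), 0L)
})

test_that("the 2-minute interruption allowance joins flanks, 3 minutes splits", {
  met_ok <- c(rep(1, 20), rep(3.5, 5), rep(2, 2), rep(3.5, 5), rep(1, 20))
  b <- detect_bouts(met_ok, rules$mvpa)
  expect_equal(b$duration_minutes, 12L)
  expect_equal(b$qualifying_minutes, 10L)
  expect_equal(b$interruption_minutes, 2L)

  met_bad <- c(rep(1, 20), rep(3.5, 5), rep(2, 3), rep(3.5, 5), rep(1, 20))
  expect_equal(nrow(detect_bouts(met_bad, rules$mvpa)), 0L)

  # interruptions are internal: bout boundaries are threshold-meeting
  met_edge <- c(rep(2, 5), rep(3.5, 12), rep(2, 2), rep(1, 20))
  b2 <- detect_bouts(met_edge, rules$mvpa)
  expect_equal(b2$start_minute, 5L)
  expect_equal(b2$end_minute, 17L)
})

test_that("multiple legal interruption runs are allowed within one bout", {
  met <- c(rep(1, 5), rep(3.5, 4), rep(2, 2), rep(3.5, 4), rep(2, 2),
           rep(3.5, 4), rep(1, 5))
  b <- detect_bouts(met, rules$mvpa)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_minutes, 16L)
  expect_equal(b$interruption_minutes, 4L)
  # under 'total' semantics the budget stops at the second interruption:
  # only the first Q-I-Q stretch (10 min, 2 interruption min) survives
  rule_total <- bout_rule("mvpa", 3, "at_least", 10L, 2L,
                          interruption_mode = "total")
  bt <- detect_bouts(met, rule_total)
  expect_equal(bt$duration_minutes, 10L)
  expect_equal(bt$interruption_minutes, 2L)
})

test_that("off-body minutes terminate candidates; sleep gates sedentary only", {
  met <- c(rep(3.5, 8), rep(3.5, 8), rep(1, 10))
  on_body <- rep(TRUE, 26)
  on_body[9] <- FALSE  # split the 16-minute episode
  expect_equal(nrow(detect_bouts(met, rules$mvpa, on_body = on_body)), 0L)

  # 25 sedentary minutes during waking count; the same pattern asleep does not
  met_sed <- c(rep(2, 5), rep(1.0, 25), rep(2, 5))
  expect_equal(detect_bouts(met_sed, rules$sedentary)$duration_minutes, 25L)
  asleep <- c(rep(FALSE, 5), rep(TRUE, 25), rep(FALSE, 5))
  expect_equal(nrow(detect_bouts(met_sed, rules$sedentary, asleep = asleep)),
               0L)
  # but asleep minutes do not gate MVPA (a 24-hour outcome)
  met_mvpa <- c(rep(1, 5), rep(3.5, 25), rep(1, 5))
  expect_equal(detect_bouts(met_mvpa, rules$mvpa,
                            asleep = asleep)$duration_minutes, 25L)
})

test_that("sedentary rule takes zero interruption allowance", {
  met <- c(rep(1.0, 15), 2.0, rep(1.0, 15))
  expect_equal(nrow(detect_bouts(met, rules$sedentary)), 0L)
  met2 <- c(rep(1.0, 21), 2.0, rep(1.0, 20))
  expect_equal(detect_bouts(met2, rules$sedentary)$duration_minutes,
               c(21L, 20L))
})

test_that("credit modes differ exactly by tolerated interruption minutes", {
  met <- c(rep(1, 5), rep(3.5, 6), rep(2, 2), rep(3.5, 6), rep(1, 5))
  expect_equal(bouted_minutes(met, rules$mvpa, credit = "full"), 14L)
  expect_equal(bouted_minutes(met, rules$mvpa, credit = "qualifying_only"),
               12L)
})

test_that("greedy scan agrees with the brute-force maximal-window oracle", {
  set.seed(101)
  for (i in 1:300) {
    day <- random_met_day()
    for (r in rules) {
      expect_identical(
        bouted_minutes(day$met, r, day$on_body, day$asleep),
        oracle_bouted_minutes(day$met, r, day$on_body, day$asleep),
        info = sprintf("seq %d rule %s", i, r$name)
      )
    }
  }
})

test_that("bout totals are monotone in threshold and allowance, nested, and translation invariant", {
  set.seed(202)
  for (i in 1:50) {
    day <- random_met_day(600)
    m <- bouted_minutes(day$met, rules$mvpa, day$on_body, day$asleep)
    # purposeful (>= 4 MET) minutes can never exceed MVPA (>= 3 MET) minutes
    purp <- bout_rule("purposeful", 4, "at_least", 10L, 2L)
    expect_lte(bouted_minutes(day$met, purp, day$on_body, day$asleep), m)
    # raising the threshold never increases totals
    hi <- bout_rule("hi", 3.6, "at_least", 10L, 2L)
    expect_lte(bouted_minutes(day$met, hi, day$on_body, day$asleep), m)
    # raising the allowance never decreases totals
    lax <- bout_rule("lax", 3, "at_least", 10L, 4L)
    expect_gte(bouted_minutes(day$met, lax, day$on_body, day$asleep), m)
    # shifting the whole pattern leaves totals unchanged
    k <- sample(1:100, 1)
    expect_identical(
      bouted_minutes(c(rep(1, k), day$met), rules$mvpa,
                     c(rep(TRUE, k), day$on_body),
                     c(rep(FALSE, k), day$asleep)),
      m
    )
  }
})

test_that("daily summaries add disjoint bouts and respect wear validity", {
  met <- rep(1.0, 1440)
  met[101:115] <- 3.5
  met[201:215] <- 3.5
  day <- data.frame(minute_of_day = 0:1439, met = met, steps = 5L,
                    on_body = 1L, asleep = 0L)
  s <- summarize_day(day)
  expect_equal(s$mvpa_bout_minutes, 30L)
  expect_true(s$valid)
  expect_equal(s$steps_total, 1440L * 5L)

  # entirely off-body: all outcomes zero and the day invalid
  day_off <- transform(day, on_body = 0L)
  s_off <- summarize_day(day_off)
  expect_equal(s_off$mvpa_bout_minutes, 0L)
  expect_equal(s_off$sedentary_bout_minutes, 0L)
  expect_equal(s_off$steps_total, 0L)
  expect_false(s_off$valid)
})

test_that("assessment summaries average valid days and flag the guideline", {
  mk_daily <- function(mvpa) {
    data.frame(mvpa_bout_minutes = mvpa,
               purposeful_bout_minutes = 0,
               sedentary_bout_minutes = 400,
               steps_total = 6000,
               on_body_minutes = 1440L, valid = TRUE)
  }
  s <- summarize_assessment(mk_daily(c(20, 30, 40, 30, 30)))
  expect_equal(s$mvpa_mean, 30)
  expect_true(s$meets_guideline)  # 30 * 7 = 210 >= 150

  # weekly total just under the guideline
  s2 <- summarize_assessment(mk_daily(rep(21.4, 5)))
  expect_false(s2$meets_guideline)  # 149.8 < 150

  # 3 valid days: assessment invalid, means withheld
  s3 <- summarize_assessment(mk_daily(c(20, 30, 40)))
  expect_false(s3$assessment_valid)
  expect_true(is.na(s3$mvpa_mean))
})
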