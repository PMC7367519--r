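# Effect estimation for the delay-control design: baseline-adjusted ANCOVA
# at the primary endpoint and the longitudinal random-intercept mixed model
# separating secular trend from exposure effects, with cluster-robust
# (sandwich) standard errors.

#' Assemble the long-format analysis dataset
#'
#' Joins outcome summaries to the roster, derives the exposure level (weeks
#' since program initiation) from (arm, assessment week) under the delay
#' design, and emits one row per available (participant, week, outcome).
#' Every randomized participant with data appears regardless of adherence
#' (intention-to-treat); missing follow-ups are simply absent rows.
#'
#' @param summaries Long `data.frame` with columns `participant_id`, `week`,
#'   `outcome`, `value` (e.g. melted output of [summarize_assessments()]
#'   and/or questionnaire subscale scores).
#' @param roster Roster `data.frame` with `participant_id`, `arm`,
#'   `block_id`.
#' @param config A [trial_config()] supplying the exposure schedule
#'   (default schedule if omitted).
#' @return `data.frame` with columns `participant_id`, `arm`, `block_id`,
#'   `week`, `exposure`, `outcome`, `value`.
#' @export
build_analysis_dataset <- function(summaries, roster,
                                   config = trial_config()) {
  need <- c("participant_id", "week", "outcome", "value")
  stopifnot(all(need %in% names(summaries)),
            all(c("participant_id", "arm") %in% names(roster)))
  unknown <- setdiff(summaries$participant_id, roster$participant_id)
  if (length(unknown)) {
    stop("outcome rows for participant(s) absent from roster: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(summaries$participant_id, summaries$week, summaries$outcome)
  if (anyDuplicated(key)) {
    stop("duplicated (participant, week, outcome) rows: ",
         key[anyDuplicated(key)], call. = FALSE)
  }
  i <- match(summaries$participant_id, roster$participant_id)
  out <- data.frame(
    participant_id = summaries$participant_id,
    arm = roster$arm[i],
    block_id = if ("block_id" %in% names(roster)) roster$block_id[i]
               else NA_integer_,
    week = as.integer(summaries$week),
    outcome = summaries$outcome,
    value = summaries$value
  )
  out$exposure <- exposure_weeks(out$arm, out$week, config)
  out <- out[!is.na(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("participant_id", "arm", "block_id", "week", "exposure",
          "outcome", "value")]
}

.effect_row <- function(term, estimate, se_model, se_sandwich, ci_low,
                        ci_high, p, estimator, n_obs, n_participants) {
  data.frame(term = term, estimate = estimate, se_model = se_model,
             se_sandwich = se_sandwich, ci_low = ci_low, ci_high = ci_high,
             p = p, estimator = estimator, n_obs = n_obs,
             n_participants = n_participants)
}

#' ANCOVA adjusted mean difference at the endpoint
#'
#' Fits endpoint value on an arm indicator (IG = 1) plus the baseline value
#' of the same outcome (plus randomization-block factors when
#' `adjust_block`), on participants with both baseline and endpoint
#' observed (complete case at the endpoint). The arm coefficient is the
#' adjusted mean difference (IG minus DG); its interval and p-value use the
#' t distribution with the residual degrees of freedom.
#'
#' @param dataset Output of [build_analysis_dataset()].
#' @param outcome Outcome name to analyse.
#' @param endpoint_week Endpoint assessment week (default 13).
#' @param adjust_block Also adjust for randomization block (default `FALSE`,
#'   the arm estimate is nearly identical either way in this design).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row `data.frame` (term `"arm_IG"`, estimator `"ancova"`).
#' @export
ancova_adjusted_difference <- function(dataset, outcome,
                                       endpoint_week = 13L,
                                       adjust_block = FALSE,
                                       conf_level = 0.95) {
  d <- dataset[dataset$outcome == outcome, , drop = FALSE]
  base <- d[d$week == 0L, c("participant_id", "arm", "block_id", "value")]
  endp <- d[d$week == endpoint_week, c("participant_id", "value")]
  names(base)[names(base) == "value"] <- "baseline"
  names(endp)[names(endp) == "value"] <- "endpoint"
  cc <- merge(base, endp, by = "participant_id")
  n_arm <- table(factor(cc$arm, levels = c("DG", "IG")))
  if (any(n_arm < 3L)) {
    stop("fewer than 3 complete cases in arm ",
         names(n_arm)[which.min(n_arm)], " for outcome '", outcome, "'",
         call. = FALSE)
  }
  if (stats::var(cc$baseline) == 0) {
    stop("degenerate covariate: baseline '", outcome,
         "' has zero variance", call. = FALSE)
  }
  cc$arm_IG <- as.integer(cc$arm == "IG")
  fml <- if (adjust_block) {
    endpoint ~ arm_IG + baseline + factor(block_id)
  } else {
    endpoint ~ arm_IG + baseline
  }
  fit <- stats::lm(fml, data = cc)
  est <- stats::coef(fit)[["arm_IG"]]
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["arm_IG"]])
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- if (se > 0) 2 * stats::pt(-abs(est / se), df) else as.numeric(est == 0)
  .effect_row("arm_IG", est, se, NA_real_, est - tq * se, est + tq * se, p,
              "ancova", nrow(cc), nrow(cc))
}

# build the 8-column fixed-effects design for the delay-control LMM:
# intercept, group indicator, follow-up occasion indicators (secular
# trend), exposure-level indicators (intervention effects)
.lmm_design <- function(d, config = trial_config()) {
  weeks <- sort(setdiff(unique(config$assessment_weeks), 0L))
  expos <- sort(setdiff(unique(unlist(config$exposure_weeks_by_arm)), 0L))
  X <- cbind(`(Intercept)` = rep(1, nrow(d)),
             group_IG = as.numeric(d$arm == "IG"))
  for (w in weeks) X <- cbind(X, as.numeric(d$week == w))
  for (e in expos) X <- cbind(X, as.numeric(d$exposure == e))
  colnames(X) <- c("(Intercept)", "group_IG", paste0("T", weeks),
                   paste0("E", expos))
  X
}

# cluster-robust covariance of GLS fixed effects for the random-intercept
# model: V_i = sigma2 I + tau2 J, closed-form inverse by Woodbury
.lmm_sandwich <- function(X, y, cluster, beta, tau2, sigma2,
                          small_sample = c("none", "cr1")) {
  small_sample <- match.arg(small_sample)
  p <- ncol(X)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  xtviy <- numeric(p)
  for (cl in unique(cluster)) {
    sel <- cluster == cl
    Xi <- X[sel, , drop = FALSE]
    yi <- y[sel]
    ni <- nrow(Xi)
    shrink <- tau2 / (sigma2 + ni * tau2)
    # V_i^{-1} M = (M - shrink * J M) / sigma2
    ViX <- (Xi - shrink * matrix(colSums(Xi), ni, p, byrow = TRUE)) / sigma2
    A <- A + crossprod(Xi, ViX)
    xtviy <- xtviy + crossprod(ViX, yi)[, 1L]
    ri <- yi - Xi %*% beta
    g <- crossprod(ViX, ri)[, 1L]
    B <- B + tcrossprod(g)
  }
  Ainv <- solve(A)
  G <- length(unique(cluster))
  if (small_sample == "cr1") B <- B * G / (G - 1)
  list(A = A, Ainv = Ainv, B = B, vcov_sandwich = Ainv %*% B %*% Ainv,
       vcov_model = Ainv, xtviy = xtviy)
}

#' Fit the delay-control longitudinal mixed model
#'
#' Fits, by restricted maximum likelihood (via \pkg{lme4}), the linear
#' mixed model with fixed effects for (1) the randomization-group indicator
#' (baseline difference), (2) indicators for each follow-up assessment
#' occasion (secular trend, `T13`/`T26`/`T39` under the default schedule),
#' and (3) indicators for each length of time since program initiation
#' (intervention effects, `E12`/`E25`/`E38`), plus a participant random
#' intercept. Standard errors are reported both model-based and empirical
#' (cluster-robust sandwich by participant); the sandwich intervals use
#' large-sample normal quantiles. Secular-trend contrasts between
#' follow-up occasions (e.g. `T26 - T13`) are additionally emitted with
#' delta-method standard errors.
#'
#' @param dataset Output of [build_analysis_dataset()].
#' @param outcome Outcome name to analyse.
#' @param config A [trial_config()] defining the occasion/exposure levels.
#' @param variance_components Optional list `list(tau2 =, sigma2 =)`. When
#'   supplied, the fixed effects are computed by direct generalized least
#'   squares at those variance components instead of REML estimation;
#'   `tau2 = 0` reduces the estimator to ordinary least squares on the same
#'   design (used to verify the degenerate case).
#' @param small_sample Sandwich small-sample correction: `"none"` (default)
#'   or `"cr1"` (multiplies the meat by G/(G-1) clusters).
#' @param conf_level Confidence level.
#' @return `data.frame` of effect rows: the 8 fixed effects with
#'   `estimator = "lmm_sandwich"` (sandwich SE/CI/p; model-based SE in
#'   `se_model`), plus trend-contrast rows. Attribute `"varcomp"` carries
#'   the estimated `tau2`/`sigma2`.
#' @export
fit_delay_control_lmm <- function(dataset, outcome,
                                  config = trial_config(),
                                  variance_components = NULL,
                                  small_sample = c("none", "cr1"),
                                  conf_level = 0.95) {
  small_sample <- match.arg(small_sample)
  d <- dataset[dataset$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop("no rows for outcome '", outcome, "'", call. = FALSE)
  X <- .lmm_design(d, config)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  y <- d$value
  cluster <- d$participant_id

  if (is.null(variance_components)) {
    df <- data.frame(y = y, participant_id = cluster,
                     as.data.frame(X[, -1L, drop = FALSE]))
    preds <- colnames(X)[-1L]
    fml <- stats::as.formula(paste(
      "y ~", paste(preds, collapse = " + "), "+ (1 | participant_id)"))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = df, REML = TRUE),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
    vc <- lme4::VarCorr(fit)
    tau2 <- as.numeric(vc$participant_id[1L, 1L])
    sigma2 <- attr(vc, "sc")^2
    beta <- lme4::fixef(fit)[colnames(X)]
    vcov_model <- as.matrix(stats::vcov(fit))[colnames(X), colnames(X)]
    sw <- .lmm_sandwich(X, y, cluster, beta, tau2, sigma2, small_sample)
  } else {
    tau2 <- variance_components$tau2
    sigma2 <- variance_components$sigma2
    sw0 <- .lmm_sandwich(X, y, cluster, rep(0, ncol(X)), tau2, sigma2,
                         small_sample)
    beta <- drop(sw0$Ainv %*% sw0$xtviy)
    names(beta) <- colnames(X)
    sw <- .lmm_sandwich(X, y, cluster, beta, tau2, sigma2, small_sample)
    vcov_model <- sw$vcov_model
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_m <- sqrt(pmax(diag(vcov_model), 0))       # guard tiny negative roundoff
  se_s <- sqrt(pmax(diag(sw$vcov_sandwich), 0))
  p <- 2 * stats::pnorm(-abs(ifelse(se_s > 0, beta / se_s,
                                    ifelse(beta == 0, 0, Inf))))
  out <- .effect_row(colnames(X), unname(beta), unname(se_m), unname(se_s),
                     unname(beta - z * se_s), unname(beta + z * se_s),
                     unname(p), "lmm_sandwich", length(y),
                     length(unique(cluster)))

  # secular-trend contrasts between consecutive follow-up occasions
  tcols <- grep("^T", colnames(X), value = TRUE)
  if (length(tcols) >= 2L) {
    for (j in 2:length(tcols)) {
      cvec <- stats::setNames(numeric(ncol(X)), colnames(X))
      cvec[tcols[j]] <- 1
      cvec[tcols[1L]] <- -1
      est <- sum(cvec * beta)
      ses <- sqrt(max(drop(t(cvec) %*% sw$vcov_sandwich %*% cvec), 0))
      sem <- sqrt(max(drop(t(cvec) %*% vcov_model %*% cvec), 0))
      pj <- 2 * stats::pnorm(-abs(if (ses > 0) est / ses else Inf * sign(est)))
      out <- rbind(out, .effect_row(
        paste0(tcols[j], "_vs_", tcols[1L]), est, sem, ses,
        est - z * ses, est + z * ses, pj, "lmm_sandwich",
        length(y), length(unique(cluster))))
    }
  }
  attr(out, "varcomp") <- c(tau2 = tau2, sigma2 = sigma2)
  out
}

#' Estimate every outcome: ANCOVA at the endpoint plus the mixed model
#'
#' Runs [ancova_adjusted_difference()] (endpoint week 13 by default) and
#' [fit_delay_control_lmm()] for each outcome present in the dataset. One
#' outcome's failure is logged and flagged, not propagated.
#'
#' @inheritParams ancova_adjusted_difference
#' @param config A [trial_config()].
#' @param small_sample Passed to [fit_delay_control_lmm()].
#' @return Tidy `data.frame`: one row per outcome x term, columns
#'   `outcome`, `term`, `estimate`, `se_model`, `se_sandwich`, `ci_low`,
#'   `ci_high`, `p`, `estimator`, `n_obs`, `n_participants`, `error`.
#' @export
estimate_all <- function(dataset, endpoint_week = 13L, adjust_block = FALSE,
                         config = trial_config(),
                         small_sample = c("none", "cr1")) {
  small_sample <- match.arg(small_sample)
  outcomes <- unique(dataset$outcome)
  rows <- lapply(outcomes, function(oc) {
    res <- list()
    anc <- tryCatch(
      ancova_adjusted_difference(dataset, oc, endpoint_week, adjust_block),
      error = function(e) conditionMessage(e))
    if (is.character(anc)) {
      message("ANCOVA failed for '", oc, "': ", anc)
      res$anc <- cbind(.effect_row("arm_IG", NA_real_, NA_real_, NA_real_,
                                   NA_real_, NA_real_, NA_real_, "ancova",
                                   NA_integer_, NA_integer_), error = anc)
    } else {
      res$anc <- cbind(anc, error = NA_character_)
    }
    lmm <- tryCatch(
      fit_delay_control_lmm(dataset, oc, config,
                            small_sample = small_sample),
      error = function(e) conditionMessage(e))
    if (is.character(lmm)) {
      message("LMM failed for '", oc, "': ", lmm)
      res$lmm <- cbind(.effect_row("(LMM)", NA_real_, NA_real_, NA_real_,
                                   NA_real_, NA_real_, NA_real_,
                                   "lmm_sandwich", NA_integer_,
                                   NA_integer_), error = lmm)
    } else {
      res$lmm <- cbind(as.data.frame(lmm), error = NA_character_)
    }
    cbind(outcome = oc, rbind(res$anc, res$lmm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power of the two-sample pooled-variance t test
#'
#' Computes power under the alternative `(mean_a - mean_b)` with per-group
#' SDs, using the noncentral-t distribution with the pooled degrees of
#' freedom (`n_total - 2`) and noncentrality
#' `(mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)`, equal allocation.
#' This is exact for equal true SDs and an accurate approximation otherwise.
#'
#' @param mean_a,sd_a Mean and SD in group A (the anticipated intervention
#'   group values).
#' @param mean_b,sd_b Mean and SD in group B.
#' @param n_total Total sample size, split equally.
#' @param alpha Significance level.
#' @param one_sided Use a one-sided test in the direction `mean_a > mean_b`.
#' @return Power (probability of rejection) as a number in `[0, 1]`.
#' @export
#' @examples
#' power_two_sample(75.5, 54.3, 50.0, 46.8, n_total = 50, alpha = 0.1,
#'                  one_sided = TRUE)
power_two_sample <- function(mean_a, sd_a, mean_b, sd_b, n_total,
                             alpha = 0.05, one_sided = FALSE) {
  if (sd_a <= 0 || sd_b <= 0) stop("SDs must be > 0", call. = FALSE)
  if (n_total < 4) stop("'n_total' must be >= 4", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)",
                                     call. = FALSE)
  n <- n_total / 2
  df <- n_total - 2
  ncp <- (mean_a - mean_b) / sqrt(sd_a^2 / n + sd_b^2 / n)
  if (one_sided) {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}
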