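# Independent brute-force oracle for bout detection: for every qualifying
# start minute, exhaustively extend right while eligibility and the
# interruption run-length constraint hold, recording the farthest
# qualifying end; keep windows not contained in another window; then apply
# the minimum-duration invariant. Sums credited (full-duration) minutes.
oracle_bouted_minutes <- function(met, rule, on_body = NULL, asleep = NULL) {
  n <- length(met)
  if (is.null(on_body)) on_body <- rep(TRUE, n)
  if (is.null(asleep)) asleep <- rep(FALSE, n)
  elig <- on_body & (!rule$waking_only | !asleep)
  q <- if (rule$met_comparator == "at_least") met >= rule$met_threshold
       else met <= rule$met_threshold
  q <- q & elig
  starts <- which(q)
  if (!length(starts)) return(0L)
  win <- matrix(NA_integer_, length(starts), 2L)
  for (k in seq_along(starts)) {
    s <- starts[k]
    last_q <- s
    run <- 0L
    j <- s + 1L
    while (j <= n) {
      if (!elig[j]) break
      if (q[j]) {
        last_q <- j
        run <- 0L
      } else {
        run <- run + 1L
        if (run > rule$max_interruption_run) break
      }
      j <- j + 1L
    }
    win[k, ] <- c(s, last_q)
  }
  # drop windows contained in another window
  keep <- rep(TRUE, nrow(win))
  for (k in seq_len(nrow(win))) {
    contained <- win[, 1L] <= win[k, 1L] & win[, 2L] >= win[k, 2L] &
      (win[, 1L] != win[k, 1L] | win[, 2L] != win[k, 2L])
    if (any(contained)) keep[k] <- FALSE
  }
  win <- win[keep, , drop = FALSE]
  dur <- win[, 2L] - win[, 1L] + 1L
  sum(dur[dur >= rule$min_bout_minutes])
}

# random MET/mask day generator for property tests: block-structured so that
# realistic bout-like runs occur
random_met_day <- function(n = NULL) {
  if (is.null(n)) n <- sample(200:1440, 1L)
  met <- numeric(0)
  while (length(met) < n) {
    len <- sample(1:30, 1L)
    lvl <- sample(c(0.9, 1.2, 1.6, 2.5, 3.2, 3.6, 4.5, 6.0), 1L)
    met <- c(met, rep(lvl, len) + stats::runif(len, -0.05, 0.05))
  }
  met <- met[seq_len(n)]
  on_body <- stats::runif(n) > 0.03
  asleep <- rep(FALSE, n)
  if (n > 100) asleep[seq_len(sample(0:80, 1L))] <- TRUE
  asleep <- asleep & on_body
  list(met = met, on_body = on_body, asleep = asleep)
}
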