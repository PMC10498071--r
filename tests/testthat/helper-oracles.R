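# Independent brute-force oracles, written directly from the task
# definitions. They deliberately share no code with the package internals.

# Replay the mode machine over a trial table: mode at each presentation,
# the deepest presented mode, and consecutive-error run lengths.
oracle_mode_trace <- function(trials) {
  mode <- 1L
  deepest <- 1L
  run <- 0L
  runs <- integer(0)
  mode_at <- integer(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    mode_at[i] <- mode
    if (mode > deepest) deepest <- mode
    out <- trials$outcome[i]
    if (out == "nogo_commission") {
      if (mode < 9L) mode <- mode + 1L
      run <- run + 1L
      if (trials$corrected[i]) { runs <- c(runs, run); run <- 0L; mode <- 1L }
    } else if (out == "nogo_correct") {
      if (run > 0L) { runs <- c(runs, run); run <- 0L }
      mode <- 1L
    } else if (out == "go_omission" && trials$corrected[i]) {
      if (run > 0L) { runs <- c(runs, run); run <- 0L }
      mode <- 1L
    }
  }
  if (run > 0L) runs <- c(runs, run)
  list(mode_at = mode_at, deepest = deepest, runs = runs)
}

# Brute-force scoring of a trial table from first principles.
oracle_score <- function(trials) {
  is_nogo <- trials$stim_class == "nogo"
  n_nogo <- sum(is_nogo); n_go <- sum(!is_nogo)
  nogo_err <- if (n_nogo) sum(trials$outcome == "nogo_commission") / n_nogo else NA_real_
  go_err <- if (n_go) sum(trials$outcome == "go_omission") / n_go else NA_real_

  # pre-no-go 4-RT sets with the three exclusion rules
  nogo_pos <- which(is_nogo)
  sets <- list()
  for (k in seq_along(nogo_pos)) {
    if (k <= 2) next
    i <- nogo_pos[k]
    gos_between <- 0
    j <- i - 1
    while (j >= 1 && trials$stim_class[j] == "go") { gos_between <- gos_between + 1; j <- j - 1 }
    if (gos_between < 4) next
    rts <- trials$rt_ms[(i - 4):(i - 1)]
    if (any(is.na(rts))) next
    sets[[length(sets) + 1]] <- rts
  }
  if (length(sets)) {
    mean_rt <- mean(sapply(sets, mean))
    rt_cv <- mean(sapply(sets, function(x) sd(x) / mean(x)))
  } else {
    mean_rt <- NA_real_; rt_cv <- NA_real_
  }

  dp <- NA_real_
  if (n_nogo && n_go) {
    hit <- sum(trials$outcome == "nogo_correct") / n_nogo
    fa <- sum(trials$outcome == "go_omission") / n_go
    if (hit == 0) hit <- 1 / (2 * n_nogo)
    if (hit == 1) hit <- 1 - 1 / (2 * n_nogo)
    if (fa == 0) fa <- 1 / (2 * n_go)
    if (fa == 1) fa <- 1 - 1 / (2 * n_go)
    dp <- qnorm(hit) - qnorm(fa)
  }

  trace <- oracle_mode_trace(trials)
  deepest <- max(trials$mode)
  list(
    nogo_error_rate = nogo_err, go_error_rate = go_err,
    mean_rt = mean_rt, rt_cv = rt_cv, d_prime = dp,
    deepest_mode = deepest,
    mw_class = c("mild", "moderate", "severe")[findInterval(deepest, c(1, 4, 7))],
    max_consecutive_errors = if (length(trace$runs)) max(trace$runs) else 0L,
    n_retained_rt_sets = length(sets)
  )
}

# Welch's ANOVA from the textbook formulas.
oracle_welch <- function(groups) {
  k <- length(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  v <- sapply(groups, var)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- 1 + (2 * (k - 2) / (k^2 - 1)) * sum((1 - w / sum(w))^2 / (n - 1))
  f <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - w / sum(w))^2 / (n - 1)))
  list(f = f, df1 = k - 1, df2 = df2,
       p = pf(f, k - 1, df2, lower.tail = FALSE))
}

# Games-Howell p-value for one pair, from the studentized-range formulas.
oracle_games_howell_pair <- function(x, y, k) {
  se2 <- var(x) / length(x) + var(y) / length(y)
  t_stat <- abs(mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                 (var(y) / length(y))^2 / (length(y) - 1))
  ptukey(t_stat * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
}

# Rank-partition two-way H statistics for a balanced layout.
oracle_srh_balanced <- function(values, a, b) {
  r <- rank(values)
  n <- length(r)
  gm <- mean(r)
  ma <- tapply(r, a, mean); na <- table(a)
  mb <- tapply(r, b, mean); nb <- table(b)
  mab <- tapply(r, interaction(a, b), mean); nab <- table(interaction(a, b))
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  cell_dev <- mab - ma[sub("\\..*", "", names(mab))] -
    mb[sub(".*\\.", "", names(mab))] + gm
  ss_ab <- sum(nab * cell_dev^2)
  ms_total <- sum((r - gm)^2) / (n - 1)
  list(H_a = ss_a / ms_total, H_b = ss_b / ms_total, H_ab = ss_ab / ms_total)
}

# A short seeded markov-responder session (~n_trials trials).
short_markov_log <- function(seed, n_trials = 50, severity = 0.5) {
  cfg <- session_config(session_duration = n_trials * 1.6, rng_seed = seed)
  run_session(cfg, markov_responder(responder_params(severity = severity)))
}

# Minimal trial table builder for metric unit tests.
trial_table <- function(stim_class, outcome, rt_ms = NULL, corrected = NULL,
                        mode = NULL, onset_s = NULL) {
  n <- length(stim_class)
  data.frame(
    index = seq_len(n),
    onset_s = if (is.null(onset_s)) seq_len(n) * 1.5 else onset_s,
    fixation_ms = 1000L,
    digit = ifelse(stim_class == "nogo", 3L, 5L),
    stim_class = stim_class,
    mode = if (is.null(mode)) 1L else mode,
    response = ifelse(outcome %in% c("go_correct", "nogo_commission"), "press", "withhold"),
    rt_ms = if (is.null(rt_ms)) ifelse(outcome %in% c("go_correct", "nogo_commission"), 300, NA_real_) else rt_ms,
    outcome = outcome,
    corrected = if (is.null(corrected)) FALSE else corrected,
    stringsAsFactors = FALSE
  )
}
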