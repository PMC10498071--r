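#' Create a mode-machine state
#'
#' @param mode Current mode (1--9).
#' @param consecutive_errors Current count of uncorrected consecutive no-go
#'   commissions.
#' @param deepest_mode Deepest mode credited so far.
#' @return An object of class `msart_mode_state`.
#' @export
mode_state <- function(mode = 1L, consecutive_errors = 0L, deepest_mode = 1L) {
  s <- structure(
    list(mode = as.integer(mode),
         consecutive_errors = as.integer(consecutive_errors),
         deepest_mode = as.integer(deepest_mode)),
    class = "msart_mode_state"
  )
  if (s$mode < 1L || s$mode > 9L) stop("mode must be in 1..9", call. = FALSE)
  if (s$consecutive_errors < 0L) stop("consecutive_errors must be >= 0", call. = FALSE)
  s
}

#' Advance the adaptive mode state machine by one no-go event
#'
#' The task difficulty escalates one mode per no-go commission error (capped
#' at mode 9, the table's last entry), returns to mode 1 on a correct no-go
#' withhold, and returns to mode 1 with the pending escalation annulled when
#' the participant presses the correction key ("b") after a slip.
#' `deepest_mode` is not touched here: mode depth is credited by
#' [run_session()] when a stimulus is actually presented at a mode, so a
#' correction made before the next stimulus prevents the would-be deeper
#' mode from counting.
#'
#' @param state An `msart_mode_state`.
#' @param event One of `"nogo_commission"`, `"nogo_correct"`, `"b_press"`.
#' @return The updated `msart_mode_state`.
#' @examples
#' s <- mode_state()
#' s <- next_mode(s, "nogo_commission")   # mode 2, one consecutive error
#' s <- next_mode(s, "nogo_correct")      # back to mode 1
#' @export
next_mode <- function(state, event = c("nogo_commission", "nogo_correct", "b_press")) {
  stopifnot(inherits(state, "msart_mode_state"))
  event <- match.arg(event)
  switch(event,
    nogo_commission = {
      state$mode <- min(state$mode + 1L, 9L)
      state$consecutive_errors <- state$consecutive_errors + 1L
    },
    nogo_correct = ,
    b_press = {
      state$mode <- 1L
      state$consecutive_errors <- 0L
    }
  )
  state
}

#' Sample one stimulus at a given mode
#'
#' Draws the no-go digit with the mode's no-go probability, otherwise a
#' uniformly chosen go digit. Draws are independent across calls given the
#' RNG stream.
#'
#' @param mode Mode index 1--9.
#' @param config An `msart_config`.
#' @return A list with `digit` and `stim_class` (`"go"` or `"nogo"`).
#' @export
sample_stimulus <- function(mode, config = session_config()) {
  if (length(mode) != 1L || is.na(mode) || mode < 1L || mode > length(config$mode_probs)) {
    stop("`mode` must index the mode probability table (1..9)", call. = FALSE)
  }
  if (stats::runif(1L) < config$mode_probs[[mode]]) {
    list(digit = config$nogo_digit, stim_class = "nogo")
  } else {
    list(digit = config$go_digits[[sample.int(length(config$go_digits), 1L)]],
         stim_class = "go")
  }
}

# one lognormal RT draw with given mean (ms) and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

new_session_log <- function(config, trials, responder_meta, final_state) {
  structure(
    list(config = config, trials = trials,
         responder = responder_meta, final_state = final_state),
    class = "msart_log"
  )
}

#' @export
print.msart_log <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("mSART session log: %d trials over %.1f s (seed %d)\n",
              n, if (n) max(x$trials$onset_s) else 0, x$config$rng_seed))
  cat(sprintf("  responder: %s\n", x$responder$label))
  cat(sprintf("  terminal mode %d, deepest credited mode %d\n",
              x$final_state$mode, x$final_state$deepest_mode))
  invisible(x)
}

#' Run one full adaptive go/no-go session
#'
#' Discrete-event simulation of the paradigm: each trial is a fixation cross
#' with uniform jitter, a digit sampled at the current mode, a responder
#' decision, outcome adjudication, and a mode-machine update. A press is a
#' commission error on the no-go digit and correct on a go digit; a withhold
#' is correct on no-go and an omission error on go. After an error the
#' responder may press the correction key before the next stimulus, which
#' resets the machine to mode 1. The session starts no trial whose stimulus
#' onset would fall at or beyond `session_duration`; with the 30-minute
#' default the task therefore ends automatically at 30 min.
#'
#' The whole session is reproducible from `config$rng_seed`: identical
#' configuration and responder parameters give an identical log.
#'
#' @param config An [session_config()] object.
#' @param responder A responder object (see [markov_responder()],
#'   [perfect_responder()], [always_press_responder()],
#'   [scripted_responder()]).
#' @return An `msart_log`: the configuration snapshot, a data frame of
#'   trials (columns `index`, `onset_s`, `fixation_ms`, `digit`,
#'   `stim_class`, `mode`, `response`, `rt_ms`, `outcome`, `corrected`),
#'   responder metadata and the terminal mode state.
#' @examples
#' log <- run_session(session_config(session_duration = 120, rng_seed = 7),
#'                    perfect_responder())
#' head(log$trials)
#' @export
run_session <- function(config = session_config(), responder = markov_responder()) {
  validate_config(config)
  stopifnot(inherits(responder, "msart_responder"))
  set.seed(config$rng_seed)

  dur <- config$session_duration
  fix_lo <- config$fixation_range[1L]
  fix_hi <- config$fixation_range[2L]
  stim_s <- config$stimulus_duration / 1000
  # worst-case trial count for preallocation
  cap <- ceiling(dur / ((fix_lo + config$stimulus_duration) / 1000)) + 2L

  onset_s <- numeric(cap); fixation_ms <- integer(cap); digit <- integer(cap)
  stim_class <- character(cap); mode_at <- integer(cap)
  response <- character(cap); rt_ms <- numeric(cap)
  outcome <- character(cap); corrected <- logical(cap)

  state <- mode_state()
  deepest_presented <- 1L
  deepest_entered <- 1L
  rstate <- responder_init(responder)

  t <- 0
  k <- 0L
  fix <- sample.int(fix_hi - fix_lo + 1L, 1L) + fix_lo - 1L
  repeat {
    onset <- t + fix / 1000
    if (onset >= dur) break
    k <- k + 1L

    stim <- sample_stimulus(state$mode, config)
    mode_now <- state$mode
    deepest_presented <- max(deepest_presented, mode_now)

    resp <- responder_step(responder, rstate, stim$stim_class)
    rstate <- resp$state

    # next trial's fixation also fixes this trial's onset-to-onset deadline
    fix_next <- sample.int(fix_hi - fix_lo + 1L, 1L) + fix_lo - 1L
    deadline <- if (is.na(config$response_deadline)) {
      config$stimulus_duration + fix_next
    } else {
      config$response_deadline
    }

    act <- resp$action
    rt <- resp$rt_ms
    if (act == "press" && !is.na(rt) && rt > deadline) {
      act <- "withhold"   # too late to register
      rt <- NA_real_
    }

    if (stim$stim_class == "nogo") {
      if (act == "press") {
        out <- "nogo_commission"
        state <- next_mode(state, "nogo_commission")
        deepest_entered <- max(deepest_entered, state$mode)
      } else {
        out <- "nogo_correct"
        state <- next_mode(state, "nogo_correct")
      }
    } else {
      out <- if (act == "press") "go_correct" else "go_omission"
    }

    corr <- FALSE
    if (out %in% c("nogo_commission", "go_omission") && isTRUE(resp$wants_b)) {
      state <- next_mode(state, "b_press")
      corr <- TRUE
    }

    onset_s[k] <- onset; fixation_ms[k] <- fix
    digit[k] <- stim$digit; stim_class[k] <- stim$stim_class
    mode_at[k] <- mode_now
    response[k] <- act
    rt_ms[k] <- if (act == "press") rt else NA_real_
    outcome[k] <- out; corrected[k] <- corr

    t <- onset + stim_s
    fix <- fix_next
  }

  idx <- seq_len(k)
  trials <- data.frame(
    index = idx, onset_s = onset_s[idx], fixation_ms = fixation_ms[idx],
    digit = digit[idx], stim_class = stim_class[idx], mode = mode_at[idx],
    response = response[idx], rt_ms = rt_ms[idx], outcome = outcome[idx],
    corrected = corrected[idx], stringsAsFactors = FALSE
  )
  state$deepest_mode <- if (config$deepest == "presented") deepest_presented else deepest_entered
  new_session_log(config, trials, responder_meta(responder), state)
}

#' Generate a practice block
#'
#' A fixed-composition warm-up block: exactly `practice_n_trials` stimuli of
#' which exactly `practice_n_nogo` are the no-go digit, at random positions.
#' The adaptive machine is inert during practice; every trial is labeled
#' mode 1 and no escalation occurs.
#'
#' @inheritParams run_session
#' @param n_trials,n_nogo Override the practice counts in `config`.
#' @return An `msart_log` with the practice trials.
#' @export
make_practice_block <- function(config = session_config(),
                                responder = perfect_responder(),
                                n_trials = config$practice_n_trials,
                                n_nogo = config$practice_n_nogo) {
  validate_config(config)
  n_trials <- as.integer(n_trials); n_nogo <- as.integer(n_nogo)
  if (n_nogo > n_trials || n_nogo < 0L || n_trials < 0L) {
    stop("practice block needs 0 <= n_nogo <= n_trials", call. = FALSE)
  }
  set.seed(config$rng_seed)
  nogo_pos <- sort(sample.int(n_trials, n_nogo))
  rstate <- responder_init(responder)

  fix_lo <- config$fixation_range[1L]; fix_hi <- config$fixation_range[2L]
  trials <- vector("list", n_trials)
  t <- 0
  for (k in seq_len(n_trials)) {
    fix <- sample.int(fix_hi - fix_lo + 1L, 1L) + fix_lo - 1L
    onset <- t + fix / 1000
    is_nogo <- k %in% nogo_pos
    dg <- if (is_nogo) config$nogo_digit else
      config$go_digits[[sample.int(length(config$go_digits), 1L)]]
    cls <- if (is_nogo) "nogo" else "go"
    resp <- responder_step(responder, rstate, cls)
    rstate <- resp$state
    out <- if (cls == "nogo") {
      if (resp$action == "press") "nogo_commission" else "nogo_correct"
    } else {
      if (resp$action == "press") "go_correct" else "go_omission"
    }
    trials[[k]] <- data.frame(
      index = k, onset_s = onset, fixation_ms = fix, digit = dg,
      stim_class = cls, mode = 1L, response = resp$action,
      rt_ms = if (resp$action == "press") resp$rt_ms else NA_real_,
      outcome = out, corrected = FALSE, stringsAsFactors = FALSE
    )
    t <- onset + config$stimulus_duration / 1000
  }
  new_session_log(config, do.call(rbind, trials), responder_meta(responder),
                  mode_state())
}
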