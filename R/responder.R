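#' Generative parameters for a synthetic responder
#'
#' The synthetic participant alternates between an on-task and an off-task
#' attentional state following a two-state Markov chain over trials, the
#' minimal generator of the repeated in-and-out-of-mind-wandering dynamics
#' the paradigm is built to detect. Each state carries its own no-go
#' commission probability, go omission probability and reaction-time
#' distribution (lognormal, parameterized by mean and coefficient of
#' variation). Off-task responding is more automatic: faster, more variable
#' and far more error-prone -- the behavioral signature of mind-wandering
#' (lower mean RT, higher RT CV, lower d-prime, deeper modes).
#'
#' `severity` in \[0, 1\] scales the chain toward the off-task state: the
#' effective transition probabilities are
#' `p_off_eff = p_off + severity * (p_off_max - p_off)` and
#' `p_on_eff = p_on - severity * (p_on - p_on_min)`, so occupancy of the
#' off-task state increases monotonically with severity. At the default
#' base values a mid-severity responder (severity 0.5) spends half the
#' session off-task and produces a no-go commission rate near 0.5.
#'
#' All parameters are constructs of the simulator, not estimates from any
#' human participant.
#'
#' @param severity Scalar in \[0, 1\]; 0 = fully attentive chain, 1 = chain
#'   maximally biased toward off-task.
#' @param p_off,p_on Base per-trial transition probabilities
#'   (on-task to off-task and back) at severity 0.
#' @param p_off_max,p_on_min Transition probabilities approached at
#'   severity 1.
#' @param commit_on,commit_off No-go commission probability in each state;
#'   `commit_off` must exceed `commit_on`.
#' @param omit_on,omit_off Go omission probability in each state.
#' @param rt_mean_on,rt_mean_off Mean go reaction time (ms) in each state;
#'   off-task responding must be faster (`rt_mean_off < rt_mean_on`).
#' @param rt_cv_on,rt_cv_off RT coefficient of variation in each state;
#'   off-task responding must be more variable (`rt_cv_off > rt_cv_on`).
#' @param p_correct_b Probability of pressing the correction key after an
#'   error committed while on-task (a noticed slip). Off-task errors are
#'   never corrected: the correction key exists to discount slips that are
#'   not mind-wandering.
#' @return An object of class `msart_responder_params`.
#' @seealso [markov_responder()], [responder_preset()]
#' @export
responder_params <- function(severity = 0.5,
                             p_off = 0.02, p_on = 0.32,
                             p_off_max = 0.32, p_on_min = 0.02,
                             commit_on = 0.15, commit_off = 0.85,
                             omit_on = 0.02, omit_off = 0.12,
                             rt_mean_on = 330, rt_mean_off = 290,
                             rt_cv_on = 0.12, rt_cv_off = 0.25,
                             p_correct_b = 0.5) {
  p <- structure(as.list(environment()), class = "msart_responder_params")
  probs <- unlist(p[c("severity", "p_off", "p_on", "p_off_max", "p_on_min",
                      "commit_on", "commit_off", "omit_on", "omit_off",
                      "p_correct_b")])
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and `severity` must lie in [0, 1]", call. = FALSE)
  }
  if (rt_mean_on <= 0 || rt_mean_off <= 0) {
    stop("RT means must be positive", call. = FALSE)
  }
  if (rt_mean_off >= rt_mean_on) {
    stop("`rt_mean_off` must be smaller than `rt_mean_on` (off-task responding is faster)",
         call. = FALSE)
  }
  if (rt_cv_off <= rt_cv_on) {
    stop("`rt_cv_off` must exceed `rt_cv_on` (off-task responding is more variable)",
         call. = FALSE)
  }
  if (commit_off <= commit_on) {
    stop("`commit_off` must exceed `commit_on`", call. = FALSE)
  }
  if (p_off_max < p_off || p_on_min > p_on) {
    stop("severity scaling requires p_off_max >= p_off and p_on_min <= p_on",
         call. = FALSE)
  }
  p
}

#' Effective Markov transition probabilities at a severity level
#'
#' @param params An [responder_params()] object.
#' @return Named numeric vector `c(p_off, p_on)` after severity scaling.
#' @export
effective_transitions <- function(params) {
  stopifnot(inherits(params, "msart_responder_params"))
  c(p_off = params$p_off + params$severity * (params$p_off_max - params$p_off),
    p_on = params$p_on - params$severity * (params$p_on - params$p_on_min))
}

#' Shipped responder presets
#'
#' Three parameter sets differing only in `severity`, chosen so that the
#' simulated cohorts reproduce the qualitative ordering of the
#' mind-wandering groups: with increasing severity, mean RT decreases,
#' RT CV increases, d-prime decreases and the deepest mode reached grows.
#'
#' @param level `"mild"`, `"moderate"` or `"severe"`.
#' @param ... Further overrides passed to [responder_params()].
#' @return An `msart_responder_params` object.
#' @export
responder_preset <- function(level = c("mild", "moderate", "severe"), ...) {
  level <- match.arg(level)
  sev <- c(mild = 0.15, moderate = 0.5, severe = 0.85)[[level]]
  responder_params(severity = sev, ...)
}

new_responder <- function(label, params, step) {
  structure(list(label = label, params = params, step = step),
            class = "msart_responder")
}

responder_meta <- function(responder) {
  list(label = responder$label,
       params = if (inherits(responder$params, "msart_responder_params")) {
         unclass(responder$params)
       } else {
         responder$params
       })
}

responder_init <- function(responder) {
  list(attention = "on_task", nogo_seen = 0L)
}

#' Query a responder for one trial
#'
#' The single contract the engine relies on: given the responder's internal
#' state and the stimulus class, return the action (`"press"` or
#' `"withhold"`), the reaction time in ms when pressing, whether the
#' responder will press the correction key should this response turn out to
#' be an error, and the updated state.
#'
#' @param responder An `msart_responder`.
#' @param state The responder's internal state list.
#' @param stim_class `"go"` or `"nogo"`.
#' @return A list with `action`, `rt_ms`, `wants_b` and `state`.
#' @export
responder_step <- function(responder, state, stim_class) {
  stopifnot(inherits(responder, "msart_responder"))
  responder$step(state, stim_class, responder$params)
}

#' Markov-attention synthetic responder
#'
#' @param params An [responder_params()] object.
#' @return An `msart_responder` implementing the two-state attention model.
#' @examples
#' r <- markov_responder(responder_preset("severe"))
#' log <- run_session(session_config(session_duration = 300, rng_seed = 3), r)
#' @export
markov_responder <- function(params = responder_params()) {
  stopifnot(inherits(params, "msart_responder_params"))
  tr <- effective_transitions(params)
  step <- function(state, stim_class, p) {
    on <- state$attention == "on_task"
    flip <- stats::runif(1L) < if (on) tr[["p_off"]] else tr[["p_on"]]
    if (flip) on <- !on
    state$attention <- if (on) "on_task" else "off_task"

    err_p <- if (stim_class == "nogo") {
      if (on) p$commit_on else p$commit_off
    } else {
      if (on) p$omit_on else p$omit_off
    }
    erred <- stats::runif(1L) < err_p
    press <- if (stim_class == "nogo") erred else !erred
    rt <- if (press) {
      if (on) rlnorm_mean_cv(1L, p$rt_mean_on, p$rt_cv_on)
      else rlnorm_mean_cv(1L, p$rt_mean_off, p$rt_cv_off)
    } else NA_real_
    wants_b <- erred && on && stats::runif(1L) < p$p_correct_b
    list(action = if (press) "press" else "withhold",
         rt_ms = rt, wants_b = wants_b, state = state)
  }
  new_responder("markov", params, step)
}

#' Deterministic reference responders
#'
#' `perfect_responder()` presses on every go digit and withholds on every
#' no-go digit, so the session never leaves mode 1. `always_press_responder()`
#' presses on everything and never corrects, so the mode ratchets to 9 and
#' stays there. Both draw go RTs from a fixed lognormal so their logs carry
#' realistic timing.
#'
#' @param rt_mean,rt_cv Parameters of the go RT distribution.
#' @return An `msart_responder`.
#' @export
perfect_responder <- function(rt_mean = 320, rt_cv = 0.1) {
  step <- function(state, stim_class, p) {
    press <- stim_class == "go"
    list(action = if (press) "press" else "withhold",
         rt_ms = if (press) rlnorm_mean_cv(1L, p$rt_mean, p$rt_cv) else NA_real_,
         wants_b = FALSE, state = state)
  }
  new_responder("perfect", list(rt_mean = rt_mean, rt_cv = rt_cv), step)
}

#' @rdname perfect_responder
#' @export
always_press_responder <- function(rt_mean = 320, rt_cv = 0.1) {
  step <- function(state, stim_class, p) {
    list(action = "press",
         rt_ms = rlnorm_mean_cv(1L, p$rt_mean, p$rt_cv),
         wants_b = FALSE, state = state)
  }
  new_responder("always_press", list(rt_mean = rt_mean, rt_cv = rt_cv), step)
}

#' Scripted responder following a fixed no-go action sequence
#'
#' Presses on every go digit; on the k-th no-go stimulus performs the k-th
#' entry of `nogo_actions` (`"press"` = commission, `"withhold"` = correct,
#' `"press_b"` = commission followed by the correction key). Once the
#' script is exhausted it withholds on every further no-go. Useful for
#' reproducing worked examples, e.g. five consecutive commissions followed
#' by a correct withhold yielding deepest mode 6.
#'
#' @param nogo_actions Character vector of scripted no-go actions.
#' @param rt_mean,rt_cv Go RT distribution.
#' @return An `msart_responder`.
#' @export
scripted_responder <- function(nogo_actions, rt_mean = 320, rt_cv = 0.1) {
  stopifnot(all(nogo_actions %in% c("press", "withhold", "press_b")))
  step <- function(state, stim_class, p) {
    if (stim_class == "go") {
      return(list(action = "press",
                  rt_ms = rlnorm_mean_cv(1L, p$rt_mean, p$rt_cv),
                  wants_b = FALSE, state = state))
    }
    state$nogo_seen <- state$nogo_seen + 1L
    act <- if (state$nogo_seen <= length(p$nogo_actions)) {
      p$nogo_actions[[state$nogo_seen]]
    } else "withhold"
    list(action = if (act == "withhold") "withhold" else "press",
         rt_ms = if (act == "withhold") NA_real_ else
           rlnorm_mean_cv(1L, p$rt_mean, p$rt_cv),
         wants_b = act == "press_b", state = state)
  }
  new_responder("scripted",
                list(nogo_actions = nogo_actions, rt_mean = rt_mean, rt_cv = rt_cv),
                step)
}

#' Simulate and score sessions across severity levels
#'
#' Runs `n_reps` independent sessions at each severity level with otherwise
#' identical responder parameters, scores each with [score_session()], and
#' returns one row per session. Fully reproducible from `seed`: session i
#' uses seed `seed + i`.
#'
#' @param levels Numeric vector of severity values in \[0, 1\].
#' @param config Session configuration (its `rng_seed` is overridden
#'   per session).
#' @param n_reps Sessions per level.
#' @param seed Base integer seed.
#' @param params Base [responder_params()]; its `severity` is replaced by
#'   each level in turn.
#' @return A data frame with columns `severity`, `rep`, and all
#'   [score_session()] fields.
#' @export
severity_sweep <- function(levels, config = session_config(), n_reps = 50L,
                           seed = 1L, params = responder_params()) {
  if (length(levels) == 0L) stop("`levels` must be nonempty", call. = FALSE)
  if (any(levels < 0 | levels > 1)) stop("severity levels must be in [0, 1]", call. = FALSE)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  base <- unclass(params)
  rows <- vector("list", length(levels) * n_reps)
  i <- 0L
  for (lv in levels) {
    pl <- base; pl$severity <- lv
    plv <- do.call(responder_params, pl[setdiff(names(pl), character(0))])
    for (rep in seq_len(n_reps)) {
      i <- i + 1L
      cfg <- config
      cfg$rng_seed <- as.integer(seed + i)
      log <- run_session(cfg, markov_responder(plv))
      m <- score_session(log)
      rows[[i]] <- cbind(data.frame(severity = lv, rep = rep), as.data.frame(m))
    }
  }
  do.call(rbind, rows)
}
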