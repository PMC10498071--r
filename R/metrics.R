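#' @name metrics
#' @title Mind-wandering measures from a session log
#' @description
#' The scoring layer turns a trial log into the paradigm's mind-wandering
#' measures: commission/omission error rates, the mean and coefficient of
#' variation of reaction times over the 4 go trials preceding each no-go
#' stimulus, signal-detection d-prime, the deepest mode reached with its
#' mild/moderate/severe classification, consecutive-error run lengths, and
#' 5-minute time-window summaries.
NULL

trials_of <- function(log) {
  tr <- if (inherits(log, "msart_log")) log$trials else log
  if (!is.data.frame(tr) || nrow(tr) == 0L) {
    stop("expected a nonempty session log or trial data frame", call. = FALSE)
  }
  tr
}

#' Commission and omission error rates
#'
#' The no-go error rate is the fraction of no-go stimuli answered with a
#' key press (commissions); the go error rate is the fraction of go stimuli
#' left unanswered (omissions). Corrected errors still count: the
#' correction key affects the mode machine, not the error bookkeeping.
#' A rate whose denominator is zero is reported as `NA`, not 0.
#'
#' @param log An `msart_log` or its trial data frame.
#' @return Named list with `nogo_error_rate` and `go_error_rate`.
#' @export
error_rates <- function(log) {
  tr <- trials_of(log)
  n_nogo <- sum(tr$stim_class == "nogo")
  n_go <- sum(tr$stim_class == "go")
  list(
    nogo_error_rate = if (n_nogo > 0L) sum(tr$outcome == "nogo_commission") / n_nogo else NA_real_,
    go_error_rate = if (n_go > 0L) sum(tr$outcome == "go_omission") / n_go else NA_real_
  )
}

#' Extract the retained 4-RT sets preceding no-go stimuli
#'
#' For every no-go stimulus the candidate set is the reaction times of the
#' 4 go trials immediately before it. Sets are excluded when (a) they
#' precede the first or second no-go of the session, (b) fewer than 4 go
#' trials separate the no-go from the previous one, or (c) any of the 4 go
#' trials is an omission, leaving no reaction time to use.
#'
#' @param log An `msart_log` or trial data frame.
#' @return A list of numeric length-4 RT vectors (possibly empty), with
#'   attributes `anchor_index` and `anchor_onset` giving, per retained set,
#'   the trial index and onset of its no-go anchor.
#' @export
extract_pre_nogo_sets <- function(log) {
  tr <- trials_of(log)
  nogo_idx <- which(tr$stim_class == "nogo")
  sets <- list()
  anchor_index <- integer(0)
  anchor_onset <- numeric(0)
  for (k in seq_along(nogo_idx)) {
    if (k <= 2L) next                       # rule (a)
    i <- nogo_idx[k]
    n_between <- i - nogo_idx[k - 1L] - 1L  # all trials between no-gos are go
    if (n_between < 4L) next                # rule (b)
    rts <- tr$rt_ms[(i - 4L):(i - 1L)]
    if (anyNA(rts)) next                    # rule (c): omission in the window
    sets[[length(sets) + 1L]] <- rts
    anchor_index <- c(anchor_index, i)
    anchor_onset <- c(anchor_onset, tr$onset_s[i])
  }
  attr(sets, "anchor_index") <- anchor_index
  attr(sets, "anchor_onset") <- anchor_onset
  sets
}

#' Mean RT and RT coefficient of variation over retained sets
#'
#' Each retained 4-RT set yields a mean and a coefficient of variation
#' (sample SD divided by the mean); under the default `"per_set"` method
#' both are then averaged across sets, the set being the unit of analysis.
#' `"pooled"` instead pools all retained RTs and computes a single mean and
#' SD/mean.
#'
#' @param sets A list of RT vectors as returned by
#'   [extract_pre_nogo_sets()].
#' @param method `"per_set"` (default) or `"pooled"`.
#' @return Named list with `mean_rt` (ms), `rt_cv` and `n_sets`. Both
#'   metrics are `NA` when no set was retained.
#' @export
mean_rt_and_cv <- function(sets, method = c("per_set", "pooled")) {
  method <- match.arg(method)
  if (length(sets) == 0L) {
    return(list(mean_rt = NA_real_, rt_cv = NA_real_, n_sets = 0L))
  }
  if (method == "per_set") {
    means <- vapply(sets, mean, numeric(1))
    cvs <- vapply(sets, function(x) stats::sd(x) / mean(x), numeric(1))
    list(mean_rt = mean(means), rt_cv = mean(cvs), n_sets = length(sets))
  } else {
    all_rt <- unlist(sets, use.names = FALSE)
    list(mean_rt = mean(all_rt), rt_cv = stats::sd(all_rt) / mean(all_rt),
         n_sets = length(sets))
  }
}

#' Signal-detection sensitivity from hit and false-alarm rates
#'
#' d' = Z(hit) - Z(false alarm) with Z the standard-normal quantile. In
#' this paradigm the hit rate is the proportion of correctly withheld
#' no-go trials and the false-alarm rate the proportion of omitted go
#' trials. Extreme proportions 0 and 1 are replaced by 1/(2N) and
#' 1 - 1/(2N), N being the relevant trial count, so d' stays finite.
#'
#' @param hit,fa Proportions in \[0, 1\].
#' @param n_hit,n_fa Trial counts backing each proportion; needed only to
#'   correct extreme proportions.
#' @return d' (unitless scalar).
#' @export
dprime_from_rates <- function(hit, fa, n_hit = NULL, n_fa = NULL) {
  clamp <- function(p, n) {
    if (p <= 0 || p >= 1) {
      if (is.null(n)) stop("extreme proportion needs its trial count for the 1/(2N) correction",
                           call. = FALSE)
      p <- min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    }
    p
  }
  stats::qnorm(clamp(hit, n_hit)) - stats::qnorm(clamp(fa, n_fa))
}

#' @describeIn dprime_from_rates d' of a whole session log; `NA` when a
#'   stimulus class is absent.
#' @param log An `msart_log` or trial data frame.
#' @export
d_prime <- function(log) {
  tr <- trials_of(log)
  n_nogo <- sum(tr$stim_class == "nogo")
  n_go <- sum(tr$stim_class == "go")
  if (n_nogo == 0L || n_go == 0L) return(NA_real_)
  dprime_from_rates(sum(tr$outcome == "nogo_correct") / n_nogo,
                    sum(tr$outcome == "go_omission") / n_go,
                    n_hit = n_nogo, n_fa = n_go)
}

#' Deepest mode, mind-wandering class and longest error run
#'
#' The deepest mode is the maximum mode at which a stimulus was presented.
#' Sessions whose deepest mode lies in 1--3, 4--6 or 7--9 are classified as
#' mild, moderate or severe mind-wandering respectively. The longest run of
#' consecutive uncorrected no-go commissions is reported alongside; the
#' canonical trace -- five consecutive commissions then a correct withhold
#' -- yields deepest mode 6 with a run of 5.
#'
#' @param log An `msart_log` or trial data frame.
#' @return Named list with `deepest_mode`, `mw_class` and
#'   `max_consecutive_errors`.
#' @export
deepest_mode_and_class <- function(log) {
  tr <- trials_of(log)
  deepest <- if (inherits(log, "msart_log") && log$config$deepest == "entered") {
    log$final_state$deepest_mode
  } else {
    max(tr$mode)
  }
  runs <- consecutive_runs(tr)
  list(
    deepest_mode = as.integer(deepest),
    mw_class = mw_class_of(deepest),
    max_consecutive_errors = if (length(runs)) max(runs) else 0L
  )
}

mw_class_of <- function(deepest) {
  if (deepest <= 3L) "mild" else if (deepest <= 6L) "moderate" else "severe"
}

#' Lengths of consecutive no-go commission runs
#'
#' A run grows with every no-go commission and ends at a correct no-go
#' withhold or at an effective correction keypress (which also ends the run
#' after a corrected commission or omission).
#'
#' @param log An `msart_log` or trial data frame.
#' @return Integer vector of maximal run lengths (possibly empty).
#' @export
consecutive_runs <- function(log) {
  tr <- trials_of(log)
  runs <- integer(0)
  run <- 0L
  for (i in seq_len(nrow(tr))) {
    out <- tr$outcome[i]
    if (out == "nogo_commission") {
      run <- run + 1L
      if (tr$corrected[i]) { runs <- c(runs, run); run <- 0L }
    } else if (out == "nogo_correct" ||
               (out == "go_omission" && tr$corrected[i])) {
      if (run > 0L) { runs <- c(runs, run); run <- 0L }
    }
  }
  if (run > 0L) runs <- c(runs, run)
  runs
}

#' Score a session into its mind-wandering summary
#'
#' @param log An `msart_log` or trial data frame.
#' @param cv_method Passed to [mean_rt_and_cv()].
#' @return An object of class `msart_metrics`: a named list with
#'   `nogo_error_rate`, `go_error_rate`, `mean_rt`, `rt_cv`, `d_prime`,
#'   `deepest_mode`, `mw_class`, `max_consecutive_errors`,
#'   `n_retained_rt_sets`.
#' @examples
#' log <- run_session(session_config(session_duration = 300, rng_seed = 11),
#'                    markov_responder(responder_preset("moderate")))
#' score_session(log)
#' @export
score_session <- function(log, cv_method = c("per_set", "pooled")) {
  cv_method <- match.arg(cv_method)
  er <- error_rates(log)
  sets <- extract_pre_nogo_sets(log)
  rt <- mean_rt_and_cv(sets, method = cv_method)
  dm <- deepest_mode_and_class(log)
  structure(
    list(nogo_error_rate = er$nogo_error_rate,
         go_error_rate = er$go_error_rate,
         mean_rt = rt$mean_rt, rt_cv = rt$rt_cv,
         d_prime = d_prime(log),
         deepest_mode = dm$deepest_mode, mw_class = dm$mw_class,
         max_consecutive_errors = dm$max_consecutive_errors,
         n_retained_rt_sets = rt$n_sets),
    class = "msart_metrics"
  )
}

#' @export
print.msart_metrics <- function(x, ...) {
  cat("mSART session metrics\n")
  cat(sprintf("  no-go error rate %.3f, go error rate %.3f\n",
              x$nogo_error_rate, x$go_error_rate))
  cat(sprintf("  mean RT %.1f ms, RT CV %.3f (over %d retained sets)\n",
              x$mean_rt, x$rt_cv, x$n_retained_rt_sets))
  cat(sprintf("  d' %.3f; deepest mode %d (%s), longest error run %d\n",
              x$d_prime, x$deepest_mode, x$mw_class, x$max_consecutive_errors))
  invisible(x)
}

#' @export
as.data.frame.msart_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Per-time-window metrics
#'
#' Splits the session into consecutive half-open windows
#' `[w*(k-1), w*k)` seconds (5 minutes each by default, giving six windows
#' for a 30-minute session) and computes the error rates, pre-no-go mean
#' RT / RT CV, and d-prime within each. Pre-no-go RT sets are assigned to
#' the window containing their no-go anchor; the exclusion rules are
#' applied on the whole session, not per window. Metrics undefined in a
#' window (no trials of the required class, no retained set) are `NA`.
#'
#' @param log An `msart_log` or trial data frame.
#' @param window_s Window length in seconds (default 300).
#' @param cv_method Passed to [mean_rt_and_cv()].
#' @return A data frame with one row per window: `window`, `n_go`,
#'   `n_nogo`, `nogo_error_rate`, `go_error_rate`, `mean_rt`, `rt_cv`,
#'   `d_prime`.
#' @export
window_metrics <- function(log, window_s = 300, cv_method = c("per_set", "pooled")) {
  cv_method <- match.arg(cv_method)
  tr <- trials_of(log)
  # onsets are strictly below session_duration; for a bare table the last
  # onset itself must still fall inside the final half-open window
  n_win <- if (inherits(log, "msart_log")) {
    max(1L, ceiling(log$config$session_duration / window_s))
  } else {
    floor(max(tr$onset_s) / window_s) + 1L
  }
  win_of <- pmin(floor(tr$onset_s / window_s) + 1L, n_win)
  sets <- extract_pre_nogo_sets(tr)
  set_win <- if (length(sets)) {
    pmin(floor(attr(sets, "anchor_onset") / window_s) + 1L, n_win)
  } else integer(0)

  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    sub <- tr[win_of == w, , drop = FALSE]
    n_go <- sum(sub$stim_class == "go")
    n_nogo <- sum(sub$stim_class == "nogo")
    rt <- mean_rt_and_cv(sets[set_win == w], method = cv_method)
    dp <- if (n_go > 0L && n_nogo > 0L) {
      dprime_from_rates(sum(sub$outcome == "nogo_correct") / n_nogo,
                        sum(sub$outcome == "go_omission") / n_go,
                        n_hit = n_nogo, n_fa = n_go)
    } else NA_real_
    out[[w]] <- data.frame(
      window = w, n_go = n_go, n_nogo = n_nogo,
      nogo_error_rate = if (n_nogo > 0L) sum(sub$outcome == "nogo_commission") / n_nogo else NA_real_,
      go_error_rate = if (n_go > 0L) sum(sub$outcome == "go_omission") / n_go else NA_real_,
      mean_rt = rt$mean_rt, rt_cv = rt$rt_cv, d_prime = dp
    )
  }
  do.call(rbind, out)
}
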