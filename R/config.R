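#' Task configuration for an adaptive go/no-go session
#'
#' Bundles every paradigm constant of the modified SART: session length,
#' trial timing, the nine-mode no-go probability table, the digit sets, the
#' practice-block composition and the RNG seed. The defaults reproduce the
#' published paradigm: a 30-minute session, fixation jitter of 900--1200 ms,
#' a 500 ms stimulus, digits 1--9 with digit 3 as the no-go stimulus, and
#' no-go probabilities 1/9, 1/9, 2/9, ..., 8/9 across modes 1--9 (modes 1
#' and 2 share 1/9 so that a single, possibly random, slip does not change
#' the stimulus statistics).
#'
#' @param session_duration Session length in seconds. Default 1800 (30 min).
#' @param fixation_range Two-element integer vector, inclusive bounds of the
#'   uniform fixation jitter in milliseconds. Default `c(900, 1200)`.
#' @param stimulus_duration Stimulus presentation time in ms. Default 500.
#' @param response_deadline Response deadline in ms measured from stimulus
#'   onset. `NA` (the default) means the response window extends to the next
#'   stimulus onset, i.e. stimulus duration plus the following fixation.
#' @param mode_probs Ordered no-go probabilities for modes 1--9. Must be
#'   nondecreasing and lie in (0, 1).
#' @param go_digits Integer vector of go digits.
#' @param nogo_digit The single no-go digit; must not appear in `go_digits`.
#' @param practice_n_trials,practice_n_nogo Practice-block composition
#'   (default 18 trials containing exactly 2 no-go stimuli).
#' @param deepest Either `"presented"` (default) or `"entered"`. Under
#'   `"presented"`, the deepest mode of a session is the maximum mode at
#'   which a stimulus was actually shown, so a correction keypress made
#'   before the next stimulus annuls the mode credit of the corrected error;
#'   under `"entered"` every mode the state machine passed through counts.
#' @param rng_seed Integer seed making the whole session reproducible.
#'
#' @return An object of class `msart_config` (a named list).
#' @seealso [run_session()], [responder_params()]
#' @examples
#' cfg <- session_config(rng_seed = 42)
#' cfg$mode_probs
#' @export
session_config <- function(session_duration = 1800,
                           fixation_range = c(900L, 1200L),
                           stimulus_duration = 500,
                           response_deadline = NA_real_,
                           mode_probs = c(1, 1, 2, 3, 4, 5, 6, 7, 8) / 9,
                           go_digits = c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L),
                           nogo_digit = 3L,
                           practice_n_trials = 18L,
                           practice_n_nogo = 2L,
                           deepest = c("presented", "entered"),
                           rng_seed = 1L) {
  deepest <- match.arg(deepest)
  # an absent deadline (NULL from a JSON/YAML round trip) means onset-to-onset
  if (is.null(response_deadline) || length(response_deadline) == 0L) {
    response_deadline <- NA_real_
  }
  cfg <- structure(
    list(
      session_duration = as.numeric(session_duration),
      fixation_range = as.integer(fixation_range),
      stimulus_duration = as.numeric(stimulus_duration),
      response_deadline = as.numeric(response_deadline),
      mode_probs = as.numeric(mode_probs),
      go_digits = as.integer(go_digits),
      nogo_digit = as.integer(nogo_digit),
      practice_n_trials = as.integer(practice_n_trials),
      practice_n_nogo = as.integer(practice_n_nogo),
      deepest = deepest,
      rng_seed = as.integer(rng_seed)
    ),
    class = "msart_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "msart_config"))
  if (!is.finite(cfg$session_duration) || cfg$session_duration <= 0) {
    stop("`session_duration` must be a positive number of seconds", call. = FALSE)
  }
  if (length(cfg$fixation_range) != 2L ||
      any(cfg$fixation_range < 0) ||
      cfg$fixation_range[1L] > cfg$fixation_range[2L]) {
    stop("`fixation_range` must be an ordered pair of nonnegative ms values",
         call. = FALSE)
  }
  if (length(cfg$mode_probs) != 9L) {
    stop("`mode_probs` must list exactly 9 no-go probabilities", call. = FALSE)
  }
  if (any(diff(cfg$mode_probs) < 0)) {
    stop("`mode_probs` must be nondecreasing across modes", call. = FALSE)
  }
  if (any(cfg$mode_probs <= 0 | cfg$mode_probs >= 1)) {
    stop("`mode_probs` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$nogo_digit %in% cfg$go_digits) {
    stop("`nogo_digit` must not be one of `go_digits`", call. = FALSE)
  }
  if (cfg$practice_n_nogo > cfg$practice_n_trials ||
      cfg$practice_n_nogo < 0L || cfg$practice_n_trials < 0L) {
    stop("practice block needs 0 <= practice_n_nogo <= practice_n_trials",
         call. = FALSE)
  }
  if (is.na(cfg$rng_seed)) stop("`rng_seed` must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.msart_config <- function(x, ...) {
  cat("mSART session configuration\n")
  cat(sprintf("  duration: %g s  stimulus: %g ms  fixation: [%d, %d] ms\n",
              x$session_duration, x$stimulus_duration,
              x$fixation_range[1L], x$fixation_range[2L]))
  cat(sprintf("  no-go digit %d vs go digits {%s}\n",
              x$nogo_digit, paste(x$go_digits, collapse = ",")))
  cat(sprintf("  mode no-go probabilities: %s\n",
              paste(sprintf("%.3f", x$mode_probs), collapse = " ")))
  cat(sprintf("  deepest-mode accounting: %s   seed: %d\n",
              x$deepest, x$rng_seed))
  invisible(x)
}
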