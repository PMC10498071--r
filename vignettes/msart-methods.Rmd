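---
title: "Models and methods behind msart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msart)
```

## The task model

The simulator implements an adaptive go/no-go sustained-attention paradigm.
Each trial is a fixation cross with uniform integer jitter on
900–1200 ms followed by a 500 ms digit; digits 1, 2, 4–9 require a keypress
("go"), digit 3 requires withholding ("no-go"). The no-go probability is
set by the current *mode*, one of nine states with probabilities
1/9, 1/9, 2/9, …, 8/9. A commission error on a no-go stimulus escalates the
mode by one (capped at 9 — the table has no tenth entry); a correct no-go
withhold resets to mode 1; a correction keypress ("b") after a noticed slip
also resets to mode 1. Modes 1 and 2 share the 1/9 probability because a
single slip may be a random error rather than mind-wandering; escalation
1→2 still happens on the first error, only the stimulus statistics do not
change. Sessions run for a fixed 30 minutes: no trial starts if its
stimulus onset would fall at or beyond the configured duration.

Within a trial the engine samples the fixation jitter, samples the stimulus
class by a per-trial Bernoulli draw at the current mode's no-go probability
(no block balancing — the mode can change on any trial), queries the
responder, adjudicates the outcome and updates the mode machine. Go digits
are uniform over the eight go digits; the paradigm leaves that
distribution open and uniformity is the natural choice. A press is
accepted from stimulus onset until the next stimulus onset (the stimulus
duration plus the next fixation); a configurable fixed deadline can replace
that default. Reaction time is measured from stimulus onset.

### Correction-key semantics and deepest mode

A "b" press is effective only when the immediately preceding trial was an
error and no stimulus has been shown since. It resets the mode and the
consecutive-error count, and flags the trial as `corrected`. Corrected
errors still count in the raw error rates: the correction key informs the
*mode machine* (its purpose is to keep non-mind-wandering slips from
inflating mode depth), not the error bookkeeping, and usage of the key is a
measure of its own.

Deepest mode is defined, by default, as the maximum mode at which a
stimulus was actually *presented* (`deepest = "presented"`). Under this
definition a correction made before the next stimulus annuls the depth
credit of the corrected error, consistent with the correction key's stated
purpose. The alternative reading — every mode the machine passed through
counts — is available as `deepest = "entered"`. Sessions with deepest mode
1–3, 4–6 and 7–9 are classified mild, moderate and severe respectively.
Go omissions never advance the mode (consecutive errors are defined on
no-go stimuli only), but a "b" press after a go omission still resets the
consecutive-error count like any correction.

### Randomness

A session is driven by one seeded RNG stream (`rng_seed` in the
configuration); jitter, stimulus class, go digit and responder draws are
interleaved on that stream. Identical configuration, responder parameters
and seed give a byte-identical log. We use a single stream rather than
per-component substreams because the reproducibility contract is at the
whole-session level and base R's RNG offers no cheap substream API; the
property suite verifies determinism directly.

## The synthetic responder

The responder is a two-state hidden Markov process over trials: attention
is either *on-task* or *off-task*, with per-trial transition probabilities
`p_off` (on→off) and `p_on` (off→on). This is the minimal generator of the
alternating in-and-out-of-mind-wandering dynamics the paradigm targets;
graded-depth attention models are deliberately out of scope. Conditional
on the state, the responder commits on a no-go with probability
`commit_on` / `commit_off`, omits a go with `omit_on` / `omit_off`, and
draws its RT from a lognormal with state-specific mean and CV (lognormal
for positive support and directly controllable CV; the paradigm itself
says nothing about RT distributions). After an error committed while
on-task — a noticed slip — it presses the correction key with probability
`p_correct_b` (default 0.5); off-task errors are never corrected, which is
exactly the distinction the correction key is meant to draw.

A scalar `severity` ∈ [0, 1] moves the chain toward the off-task state by
linear interpolation: `p_off` rises toward `p_off_max` and `p_on` falls
toward `p_on_min`. Defaults (`p_off` 0.02→0.32, `p_on` 0.32→0.02,
`commit_on` = 0.15, `commit_off` = 0.85, `omit_on` = 0.02,
`omit_off` = 0.12, RT 330 ms/CV 0.12 on-task vs 290 ms/CV 0.25 off-task)
were chosen once so that a mid-severity responder (severity 0.5, stationary
off-task occupancy 0.5) produces a no-go error rate near 0.5, a go error
rate near 0.08 and d′ near 1.5 — the magnitudes typical of this paradigm —
and so that the monotone signatures hold by construction: with rising
severity, mean RT falls, RT CV rises, d′ falls and deeper modes are
reached. These are calibration anchors for realistic magnitudes, not a fit
to any participant; no individual-level generative claim is implied.

What the generator does *not* emulate: practice effects and fatigue drifts
within a session (the chain is time-homogeneous), graded depths of
mind-wandering, intentional versus unintentional mind-wandering (not
separable in this paradigm), response-time autocorrelation beyond what
state switching induces, and anticipatory or post-error slowing dynamics.
Passing tests therefore show that the *pipeline* recovers the designed
signatures from logs with realistic statistics, not that the model captures
human attention.

## Scoring rules

- **Error rates.** Commissions / no-go count and omissions / go count. A
  rate with a zero denominator is reported `NA`, never 0. Corrected errors
  count.
- **Pre-no-go RT sets.** For each no-go stimulus, the candidate set is the
  RTs of the 4 immediately preceding go trials. Sets are excluded when the
  anchor is the session's first or second no-go, when fewer than 4 go
  trials separate the anchor from the previous no-go, or when the window
  contains an omission (an RT cannot be imputed). Go RTs outside these
  sets are logged but unused: go responding is highly predictable and the
  4-trial window before the no-go is the analysis unit.
- **Mean RT and RT CV.** Per set, the mean and the sample-SD/mean
  (n−1 SD; the population/sample choice is a convention we fix explicitly);
  by default both are then averaged across sets, the set being the unit of
  analysis. A `pooled` option pools all retained RTs first; both
  reductions are available because the aggregation is genuinely ambiguous
  in common usage.
- **d′.** Z(hit) − Z(FA) with hit = correct no-go proportion and FA = go
  omission proportion. Extreme proportions are clamped to 1/(2N) and
  1 − 1/(2N) with N the relevant trial count — the standard correction
  when perfect sub-scores occur.
- **Time windows.** Half-open bins [300(k−1), 300k) s. The half-open
  convention partitions the session exactly (labels like "0–5 min" leave
  the boundary minute ambiguous). RT sets belong to the window of their
  no-go anchor; exclusion rules are applied session-wide first.

## The inferential layer

Classical one-way ANOVA is computed from the sums of squares with partial
η² = SS_between/(SS_between + SS_within); Welch's ANOVA uses
`stats::oneway.test` (Welch–Satterthwaite fractional df2) and reports the
same descriptive η². With equal group sizes and variances the Welch
numerator equals the classical F exactly, but Welch's denominator
correction exceeds 1 at small n, so the two statistics agree only
asymptotically — the test suite checks the exact numerator identity and
the large-n agreement.

The Scheirer–Ray–Hare test ranks all observations together (mid-ranks for
ties), partitions the rank sums of squares over the A + B + A×B layout,
and refers H = SS_effect / MS_total to χ² with the effect's df, where
MS_total is the variance of the (tied) ranks — which is how ties are
absorbed. With a single-level second factor it reduces exactly to
Kruskal–Wallis. Results are reported in the H(df, N) style; the second
number is the total observation count, not a denominator df.

Post hoc defaults follow variance assumptions: Tukey HSD after classical
ANOVA, Games–Howell (per-pair Welch SE and df against the studentized
range) after Welch; Bonferroni-corrected Welch t tests are also available.
The paradigm's reporting does not name its post hoc method, so the
conventional pairings are used.

Sample size: the smallest total N (equal allocation, searched in steps of
k so groups stay whole; a per-unit search is available) whose noncentral-F
power reaches the target, with λ = f²N and df (k−1, N−k). For f = 0.25,
α = .05, power = .80, k = 3 this gives N = 159 (achieved power 0.805); the
per-unit search gives 158. This is the between-groups fixed-effects
computation — the computation that produces 159 — even though such designs
are sometimes loosely labeled within-subject. Analysis of covariance is
not implemented: no covariate is defined anywhere in the paradigm's
analysis plan.

All p-values are carried exactly; "p < .001" styling is left to the
caller. Null calibration of the ANOVA p-values is verified by simulation
(1,000 replicates, Kolmogorov–Smirnov at α = .01).

## Numerical and degenerate-input choices

- F is defined as 0 when all observations are identical; perfect
  separation yields F = ∞ with η² = 1.
- Welch's ANOVA rejects zero-variance groups with a diagnostic naming
  them.
- The mode machine caps at 9; `next_mode` rejects unknown event labels.
- An empty retained-set list yields `NA` mean RT and RT CV, not 0; empty
  windows yield `NA` metrics.
- Logs are CSV with a JSON sidecar (schema-versioned; readers reject
  unknown major versions) for human inspectability; readers validate the
  exact column set and strictly increasing onsets with row-level
  diagnostics.

## Problem sizes used in the checks

The shipped verification uses desk-scale problems chosen as the smallest
sizes that exercise each property cleanly: trace and brute-force oracle
equivalence on ~50-trial logs, stimulus-frequency checks with 10⁵ draws
against a 99.9% binomial interval, null calibration with 1,000 replicates
of 3×20 observations, and a severity sweep of 3 levels × 50 full-length
(30-minute, ~1,160-trial) sessions for the parameter-recovery ordering.

## Known limitations

- The responder is a construct; parameter recovery shows internal
  consistency of engine + metrics, not validity for human data.
- Full-length sessions nearly always contain at least one long off-task
  run at moderate severity and above, so the deepest-mode classification
  saturates toward severe over 30 minutes; the sweep's monotone ordering,
  not the absolute class distribution, is the meaningful recovery target.
- The Scheirer–Ray–Hare partition uses the sequential rank ANOVA on the
  A + B + A×B layout; for unbalanced layouts the partition (like the test
  itself, which predates modern unbalanced-rank theory) is order-dependent.
- Repeated-measures/mixed models are out of scope; the grouping factors
  are treated as between-session.
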