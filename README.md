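# msart

Headless simulator and analysis toolkit for a **modified Sustained Attention
to Response Task (mSART)** — an adaptive go/no-go paradigm designed to
quantify mind-wandering from behavior alone.

## The paradigm and who this is for

In the classic SART, participants press a key for every digit 1–9 except the
rare no-go digit 3. The modified paradigm makes the task *adaptive*: it has
nine difficulty **modes** with no-go probabilities

```
mode:        1    2    3    4    5    6    7    8    9
P(no-go):   1/9  1/9  2/9  3/9  4/9  5/9  6/9  7/9  8/9
```

Every commission error on a no-go stimulus escalates the task to the next
mode; a correct withhold returns it to mode 1; a "b" keypress lets the
participant retract a noticed slip, also returning to mode 1 so that
non-mind-wandering errors do not inflate the depth. The **deepest mode
reached** over a fixed 30-minute session classifies mind-wandering as mild
(modes 1–3), moderate (4–6) or severe (7–9). Behavioral measures of
mind-wandering are computed from the trial log:

- no-go and go **error rates**;
- **mean RT** over the 4 go trials preceding each no-go stimulus (excluding
  the first two no-go anchors, anchors with fewer than 4 intervening go
  trials, and windows containing an omission);
- **RT CV** = SD/mean over those same 4-RT sets;
- **d′** = Z(hit) − Z(FA), with hits = correctly withheld no-go trials and
  false alarms = omitted go trials, extreme proportions corrected by
  1/(2N);
- **consecutive-error runs** and the deepest mode;
- all of the above per 5-minute **time window** (six windows per session).

The package is for researchers who want to exercise this paradigm and its
analysis pipeline end-to-end — scoring rules, classification, ANOVA layer,
power analysis — without collecting human data. Synthetic responders with a
two-state (on-task/off-task) Markov attention process generate the known
behavioral signatures of mind-wandering: off-task responding is faster, more
variable and far more error-prone, so increasing the responder's `severity`
lowers mean RT, raises RT CV, lowers d′ and deepens the modes reached.

The inferential layer mirrors the field's standard reporting: classical and
Welch one-way ANOVA with partial η², the Scheirer–Ray–Hare rank-based
two-way test, Tukey / Games–Howell / Bonferroni post hoc comparisons, and
a-priori sample-size computation from the noncentral F distribution
(λ = f²·N).

## Worked example

```r
library(msart)

cfg <- session_config(rng_seed = 42)                       # 30-min session
log <- run_session(cfg, markov_responder(responder_preset("moderate")))
log
#> mSART session log: 1161 trials over 1799.9 s (seed 42)
#>   responder: markov
#>   terminal mode 1, deepest credited mode 9

score_session(log)
#> mSART session metrics
#>   no-go error rate 0.523, go error rate 0.072
#>   mean RT 308.5 ms, RT CV 0.185 (over 59 retained sets)
#>   d' 1.404; deepest mode 9 (severe), longest error run 13
```

The no-go error rate near 0.5 and d′ near 1.4 are what a mid-severity
responder is calibrated to produce; the deepest mode of 9 classifies this
session as severe mind-wandering (a 30-minute session gives many chances
for one long off-task run). Per-window summaries track the dynamics:

```r
window_metrics(log)[, c("window", "nogo_error_rate", "mean_rt", "rt_cv", "d_prime")]
#>   window nogo_error_rate mean_rt rt_cv d_prime
#> 1      1           0.636 305.070 0.194   0.898
#> 2      2           0.462 316.141 0.153   1.604
#> ...
```

The a-priori design computation:

```r
required_sample_size(effect_size_f = 0.25, alpha = 0.05, power = 0.80, k_groups = 3)
#> [1] 159
```

i.e. 159 participants are needed to detect a medium effect (f = 0.25) at
α = .05 with power .80 across three groups.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "msart", package = "msart"))')
$CLI power --f 0.25 --alpha 0.05 --power 0.80 --k 3     # prints 159
$CLI simulate --seed 7 --out session.csv                # CSV + JSON sidecar
$CLI analyze --log session.csv --windows
$CLI sweep --levels 0.1,0.5,0.9 --reps 50 --seed 1 --out sweep.csv
```

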