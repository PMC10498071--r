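test_that("error rates are simple ratios and undefined without a denominator", {
  tr <- trial_table(
    stim_class = c(rep("nogo", 10), rep("go", 100)),
    outcome = c(rep("nogo_commission", 5), rep("nogo_correct", 5),
                rep("go_omission", 8), rep("go_correct", 92))
  )
  er <- error_rates(tr)
  expect_equal(er$nogo_error_rate, 0.5)
  expect_equal(er$go_error_rate, 0.08)

  all_go <- trial_table(rep("go", 5), rep("go_correct", 5))
  expect_true(is.na(error_rates(all_go)$nogo_error_rate))
  expect_equal(error_rates(all_go)$go_error_rate, 0)
  expect_error(error_rates(all_go[0, ]), "nonempty")
})

test_that("pre-no-go set extraction applies all three exclusion rules", {
  log <- toy_exclusion_log()
  sets <- extract_pre_nogo_sets(log)
  expect_length(sets, 2)
  expect_equal(sets[[1]], c(310, 320, 330, 340))
  expect_equal(sets[[2]], c(610, 620, 630, 640))

  # all-go session has no anchors
  expect_length(extract_pre_nogo_sets(trial_table(rep("go", 8), rep("go_correct", 8))), 0)

  # first two no-gos excluded even when their windows are clean
  tr <- trial_table(
    stim_class = rep(c(rep("go", 4), "nogo"), 3),
    outcome = rep(c(rep("go_correct", 4), "nogo_correct"), 3),
    rt_ms = c(1:4 * 10, NA, 5:8 * 10, NA, 9:12 * 10, NA)
  )
  sets2 <- extract_pre_nogo_sets(tr)
  expect_length(sets2, 1)
  expect_equal(sets2[[1]], c(90, 100, 110, 120))
})

test_that("mean RT and RT CV summarize retained sets per set by default", {
  one <- list(c(300, 300, 300, 300))
  expect_equal(mean_rt_and_cv(one), list(mean_rt = 300, rt_cv = 0, n_sets = 1L))

  set <- c(250, 300, 350, 400)
  got <- mean_rt_and_cv(list(set))
  expect_equal(got$mean_rt, 325)
  expect_equal(got$rt_cv, sd(set) / mean(set))
  expect_equal(got$rt_cv, 0.1986, tolerance = 1e-3)

  # averaging over identical sets changes nothing
  expect_equal(mean_rt_and_cv(list(set, set))[1:2], got[1:2])

  # pooled aggregation pools every RT before one SD/mean
  two <- list(c(250, 300, 350, 400), c(260, 310, 360, 410))
  pooled <- unlist(two)
  expect_equal(mean_rt_and_cv(two, method = "pooled")$rt_cv,
               sd(pooled) / mean(pooled))

  empty <- mean_rt_and_cv(list())
  expect_true(is.na(empty$mean_rt) && is.na(empty$rt_cv))
})

test_that("d-prime follows Z(hit) - Z(FA) with the 1/(2N) extreme correction", {
  expect_equal(dprime_from_rates(0.5, 0.5), 0)
  expect_equal(dprime_from_rates(0.84, 0.16), qnorm(0.84) - qnorm(0.16))
  expect_equal(dprime_from_rates(0.84, 0.16), 1.9890, tolerance = 1e-4)

  # 30 no-go all withheld, 100 go none omitted
  tr <- trial_table(
    stim_class = c(rep("nogo", 30), rep("go", 100)),
    outcome = c(rep("nogo_correct", 30), rep("go_correct", 100))
  )
  expect_equal(d_prime(tr), qnorm(1 - 1 / 60) - qnorm(1 / 200))

  # antisymmetry: swapping hit and false-alarm rates negates d'
  set.seed(15)
  for (i in 1:25) {
    h <- runif(1); f <- runif(1)
    expect_equal(dprime_from_rates(h, f), -dprime_from_rates(f, h))
  }

  one_class <- trial_table(rep("go", 5), rep("go_correct", 5))
  expect_true(is.na(d_prime(one_class)))
})

test_that("deepest mode, classification and error runs follow the worked rules", {
  # E E E E E C: run of 5, deepest presented mode 6
  tr <- trial_table(
    stim_class = rep("nogo", 6),
    outcome = c(rep("nogo_commission", 5), "nogo_correct"),
    mode = 1:6
  )
  dm <- deepest_mode_and_class(tr)
  expect_identical(dm$deepest_mode, 6L)
  expect_identical(dm$mw_class, "moderate")
  expect_identical(dm$max_consecutive_errors, 5L)
  expect_identical(consecutive_runs(tr), 5L)

  # E C E C resets between errors
  ecec <- trial_table(
    stim_class = rep("nogo", 4),
    outcome = rep(c("nogo_commission", "nogo_correct"), 2),
    mode = c(1, 2, 1, 2)
  )
  expect_identical(consecutive_runs(ecec), c(1L, 1L))

  # a corrected commission ends its run
  ebe <- trial_table(
    stim_class = rep("nogo", 3),
    outcome = c("nogo_commission", "nogo_commission", "nogo_commission"),
    corrected = c(FALSE, TRUE, FALSE),
    mode = c(1, 2, 1)
  )
  expect_identical(consecutive_runs(ebe), c(2L, 1L))

  clean <- trial_table(rep("nogo", 3), rep("nogo_correct", 3))
  expect_identical(consecutive_runs(clean), integer(0))
  expect_identical(deepest_mode_and_class(clean)$mw_class, "mild")
  expect_identical(deepest_mode_and_class(trial_table("nogo", "nogo_correct", mode = 7L))$mw_class, "severe")
})

test_that("time windows are half-open 300 s bins covering the session", {
  tr <- trial_table(
    stim_class = rep("go", 3),
    outcome = rep("go_correct", 3),
    onset_s = c(0, 299.9, 300.0)
  )
  wm <- window_metrics(tr, window_s = 300)
  expect_equal(wm$n_go[1:2], c(2, 1))

  log <- run_session(session_config(rng_seed = 61),
                     markov_responder(responder_preset("moderate")))
  wm6 <- window_metrics(log)
  expect_identical(nrow(wm6), 6L)
  # pooled counts across windows equal session totals
  expect_equal(sum(wm6$n_go) + sum(wm6$n_nogo), nrow(log$trials))
  expect_equal(sum(wm6$n_nogo), sum(log$trials$stim_class == "nogo"))
  # anchored set counts: windowed mean RTs average back to the session value
  sets <- extract_pre_nogo_sets(log)
  expect_gt(length(sets), 0)
})

test_that("session scoring matches a brute-force recomputation on short logs", {
  for (seed in c(11, 22, 33, 44, 55)) {
    log <- short_markov_log(seed, n_trials = 50)
    got <- score_session(log)
    want <- oracle_score(log$trials)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], info = paste(seed, f))
  }
})

test_that("adding commissions while go behavior is fixed never raises d-prime", {
  log <- short_markov_log(99, n_trials = 60)
  tr <- log$trials
  correct_idx <- which(tr$outcome == "nogo_correct")
  dp <- d_prime(tr)
  for (i in correct_idx) {
    tr$outcome[i] <- "nogo_commission"
    tr$response[i] <- "press"
    tr$rt_ms[i] <- 300
    dp_new <- d_prime(tr)
    expect_lte(dp_new, dp + 1e-12)
    dp <- dp_new
  }
})
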