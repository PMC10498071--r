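test_that("classical one-way ANOVA matches the sums-of-squares definition", {
  # perfect separation: all variance between groups
  sep <- oneway_anova(list(c(0, 0), c(1, 1)))
  expect_identical(sep$statistic, Inf)
  expect_equal(sep$eta_p_sq, 1)

  # identical groups: no between-group variance
  same <- oneway_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$eta_p_sq, 0)

  # fully degenerate input
  flat <- oneway_anova(list(c(3, 3), c(3, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(71)
  for (i in 1:5) {
    groups <- lapply(c(8, 12, 10), function(n) rnorm(n, mean = runif(1, 0, 2)))
    got <- oneway_anova(groups)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ref <- anova(lm(y ~ g))
    expect_equal(got$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(got$eta_p_sq, ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-10)
    expect_equal(got$df1, length(groups) - 1)
    expect_equal(got$df2, length(y) - length(groups))
  }
})

test_that("Welch's ANOVA matches the textbook formulas and degrades gracefully", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 10))
  got <- welch_anova(g)
  want <- oracle_welch(g)
  expect_equal(got$statistic, want$f, tolerance = 1e-10)
  expect_equal(got$df1, want$df1)
  expect_equal(got$df2, want$df2, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_false(got$df2 %% 1 == 0)  # fractional denominator df

  near_null <- welch_anova(list(c(1, 2, 3), c(1.0001, 2, 3)))
  expect_lt(near_null$statistic, 0.01)

  expect_error(welch_anova(list(c(1, 1, 1), c(1, 2, 3))), "variance")
})

test_that("Welch and classical ANOVA agree for balanced homoscedastic groups", {
  # with equal n and equal sample variances the Welch numerator equals the
  # classical F exactly; the denominator correction shrinks to 1 as n grows
  set.seed(72)
  base <- rnorm(200)
  g <- list(base, base + 0.2, base + 0.4)   # identical variances by design
  cl <- oneway_anova(g)
  we <- welch_anova(g)
  expect_equal(we$statistic, cl$statistic, tolerance = 0.005)
  k <- 3; n <- 200
  correction <- 1 + (2 * (k - 2) / (k^2 - 1)) * k * (1 - 1 / k)^2 / (n - 1)
  expect_equal(we$statistic * correction, cl$statistic, tolerance = 1e-10)
})

test_that("Scheirer-Ray-Hare collapses to Kruskal-Wallis when one factor is constant", {
  set.seed(81)
  for (i in 1:4) {
    y <- rnorm(30) + rep(c(0, 1, 0.5), each = 10)
    a <- rep(c("x", "y", "z"), each = 10)
    srh <- scheirer_ray_hare(y, a, rep("only", 30))
    kw <- kruskal.test(y, factor(a))
    expect_equal(srh$A$statistic, unname(kw$statistic), tolerance = 1e-10)
    expect_equal(srh$A$p_value, kw$p.value, tolerance = 1e-10)
    expect_equal(srh$B$statistic, 0)
    expect_equal(srh$AB$statistic, 0)
  }
})

test_that("Scheirer-Ray-Hare partitions rank sums of squares over both factors", {
  set.seed(82)
  y <- rnorm(24, mean = rep(c(0, 1), each = 12) + rep(rep(c(0, 0.5, 1), each = 4), 2))
  a <- rep(c("a1", "a2"), each = 12)
  b <- rep(rep(c("b1", "b2", "b3"), each = 4), 2)
  got <- scheirer_ray_hare(y, a, b)
  want <- oracle_srh_balanced(y, a, b)
  expect_equal(got$A$statistic, want$H_a, tolerance = 1e-10)
  expect_equal(got$B$statistic, want$H_b, tolerance = 1e-10)
  expect_equal(got$AB$statistic, want$H_ab, tolerance = 1e-10)
  expect_equal(got$A$df1, 1L)
  expect_equal(got$B$df1, 2L)
  expect_equal(got$AB$df1, 2L)
  expect_identical(got$A$df2, 24L)  # reported alongside H in the H(df, N) style

  # rank-based, hence invariant to strictly monotone transforms
  tr <- scheirer_ray_hare(exp(y), a, b)
  expect_equal(tr$A$statistic, got$A$statistic)
  expect_equal(tr$AB$statistic, got$AB$statistic)

  allsame <- scheirer_ray_hare(rep(2, 12), rep(c("a", "b"), 6), rep(c("u", "v"), each = 6))
  expect_equal(allsame$A$statistic, 0)
  expect_equal(allsame$AB$p_value, 1)

  expect_error(scheirer_ray_hare(1:4, c("a", "a", "a", "b"), c("u", "v", "u", "u")),
               "cell")
})

test_that("post hoc p-value matrices are symmetric and method-faithful", {
  set.seed(91)
  same <- replicate(2, rnorm(20, 5, 1), simplify = FALSE)
  for (m in c("tukey", "games_howell", "bonferroni")) {
    p <- pairwise_posthoc(same, method = m)
    expect_true(isSymmetric(p))
    expect_gt(p[1, 2], 0.2)
  }
  expect_error(pairwise_posthoc(same, method = "dunn"), "arg")

  hetero <- list(rnorm(15, 0, 1), rnorm(25, 0.8, 3), rnorm(10, 2, 0.5))
  gh <- pairwise_posthoc(hetero, method = "games_howell")
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(gh[i, j], oracle_games_howell_pair(hetero[[i]], hetero[[j]], 3),
                 tolerance = 1e-12)
  }

  # close mild/moderate pair vs a distant severe group mirrors the
  # Mild = Moderate > Severe post hoc pattern
  set.seed(92)
  dprimes <- list(mild = rnorm(40, 1.75, 0.3), moderate = rnorm(40, 1.70, 0.3),
                  severe = rnorm(40, 1.20, 0.3))
  p <- pairwise_posthoc(dprimes, method = "games_howell")
  expect_gt(p["mild", "moderate"], 0.05)
  expect_lt(p["mild", "severe"], 0.001)
  expect_lt(p["moderate", "severe"], 0.001)
})

test_that("noncentral-F sample size search reproduces the a-priori design value", {
  n <- required_sample_size(0.25, 0.05, 0.80, 3)
  expect_identical(as.integer(n), 159L)
  expect_gte(attr(n, "power"), 0.80)
  expect_gte(anova_power(159, 0.25, 0.05, 3), 0.80)
  expect_lt(anova_power(159 - 3, 0.25, 0.05, 3), 0.80)

  # per-unit search is allowed to land between multiples of k
  n_unit <- required_sample_size(0.25, 0.05, 0.80, 3, search = "unit")
  expect_identical(as.integer(n_unit), 158L)

  # a huge effect bottoms out where the direct power scan first passes
  n_big <- required_sample_size(2.0, 0.05, 0.80, 2)
  scan <- seq(4, 40, by = 2)
  first <- scan[which(vapply(scan, anova_power, numeric(1),
                             effect_size_f = 2.0, alpha = 0.05, k_groups = 2) >= 0.80)[1]]
  expect_identical(as.integer(n_big), as.integer(first))

  expect_error(required_sample_size(0), "positive")
  expect_error(required_sample_size(0.25, alpha = 1.2), "alpha")
  expect_error(required_sample_size(0.25, k_groups = 1), "k_groups")
})

test_that("required sample size is monotone in effect size, alpha and power", {
  base <- required_sample_size(0.25, 0.05, 0.80, 3)
  expect_lte(required_sample_size(0.40, 0.05, 0.80, 3), base)
  expect_lte(required_sample_size(0.25, 0.10, 0.80, 3), base)
  expect_gte(required_sample_size(0.25, 0.05, 0.90, 3), base)
  expect_gte(required_sample_size(0.25, 0.01, 0.80, 3), base)
})
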