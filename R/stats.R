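#' @name inference
#' @title Inferential layer
#' @description
#' The statistics used to compare mind-wandering groups and time windows:
#' classical and Welch one-way ANOVA with partial eta squared, the
#' Scheirer--Ray--Hare rank-based two-way test, pairwise post hoc
#' comparisons (Tukey HSD, Games--Howell, Bonferroni), and the a-priori
#' sample-size computation from the noncentral F distribution.
NULL

as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("`groups` must be a list of numeric vectors", call. = FALSE)
  if (!is.list(groups)) stop("`groups` must be a list of numeric vectors", call. = FALSE)
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  groups
}

new_stats_result <- function(name, statistic, df1, df2, p, eta = NA_real_,
                             note = NULL) {
  structure(
    list(statistic_name = name, statistic = statistic, df1 = df1, df2 = df2,
         p_value = p, eta_p_sq = eta, note = note),
    class = "msart_stats"
  )
}

#' @export
print.msart_stats <- function(x, ...) {
  df2 <- if (x$df2 %% 1 == 0) sprintf("%d", as.integer(x$df2)) else sprintf("%.2f", x$df2)
  cat(sprintf("%s(%g, %s) = %.4g, p = %.4g", x$statistic_name, x$df1, df2,
              x$statistic, x$p_value))
  if (!is.na(x$eta_p_sq)) cat(sprintf(", partial eta^2 = %.3f", x$eta_p_sq))
  cat("\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

sums_of_squares <- function(groups) {
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  m <- vapply(groups, mean, numeric(1))
  n <- vapply(groups, length, numeric(1))
  list(ssb = sum(n * (m - grand)^2),
       ssw = sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))),
       k = length(groups), N = length(all_x))
}

#' Classical one-way fixed-effects ANOVA
#'
#' F with degrees of freedom (k - 1, N - k); the effect size is partial eta
#' squared, SS_between / (SS_between + SS_within). When every observation
#' equals the grand mean (no between- and no within-variance) F is defined
#' as 0.
#'
#' @param groups List of numeric vectors, one per group (each length >= 2).
#' @return An `msart_stats` result with fields `statistic_name` ("F"),
#'   `statistic`, `df1`, `df2`, `p_value`, `eta_p_sq`.
#' @export
oneway_anova <- function(groups) {
  groups <- as_group_list(groups)
  ss <- sums_of_squares(groups)
  df1 <- ss$k - 1; df2 <- ss$N - ss$k
  if (ss$ssw == 0 && ss$ssb == 0) {
    return(new_stats_result("F", 0, df1, df2, 1, 0))
  }
  f <- if (ss$ssw == 0) Inf else (ss$ssb / df1) / (ss$ssw / df2)
  eta <- ss$ssb / (ss$ssb + ss$ssw)
  new_stats_result("F", f, df1, df2, stats::pf(f, df1, df2, lower.tail = FALSE), eta)
}

#' Welch's heteroscedasticity-robust one-way ANOVA
#'
#' Welch's F with the Welch--Satterthwaite fractional denominator degrees
#' of freedom, as used when group variances are unequal. The reported
#' effect size is the same descriptive partial eta squared as in
#' [oneway_anova()] (computed from the sums of squares), matching common
#' reporting practice alongside Welch's F.
#'
#' @inheritParams oneway_anova
#' @return An `msart_stats` result; `df2` is fractional.
#' @export
welch_anova <- function(groups) {
  groups <- as_group_list(groups)
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) {
    stop("Welch's ANOVA requires positive variance in every group; group(s) ",
         paste(which(v == 0), collapse = ", "), " are constant", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  wt <- stats::oneway.test(y ~ g, var.equal = FALSE)
  ss <- sums_of_squares(groups)
  new_stats_result("F", unname(wt$statistic), unname(wt$parameter[1L]),
                   unname(wt$parameter[2L]), wt$p.value,
                   ss$ssb / (ss$ssb + ss$ssw))
}

#' Scheirer--Ray--Hare rank-based two-factor test
#'
#' Nonparametric analogue of two-way ANOVA: all observations are ranked
#' together (mid-ranks for ties), the rank sums of squares are partitioned
#' by the A + B + A:B layout, and each effect's H statistic is its rank SS
#' divided by the total rank variance MS_total = Var(ranks). Ties are
#' handled implicitly because MS_total is computed on the tied ranks. Each
#' H is referred to a chi-square distribution with the effect's degrees of
#' freedom. With one level in one factor the other factor's H reduces to
#' the Kruskal--Wallis statistic.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercibles) of the same length.
#' @return A list of three `msart_stats` results named `A`, `B`, `AB`,
#'   each with `statistic_name` "H", degrees of freedom in `df1`, the total
#'   number of observations in `df2` (reported alongside H in the
#'   H(df, N) style; it is not a denominator df), and a chi-square p-value.
#'   All H are 0 by convention when every observation is identical.
#' @export
scheirer_ray_hare <- function(values, factor_a, factor_b) {
  values <- as.numeric(values)
  a <- factor(factor_a); b <- factor(factor_b)
  n <- length(values)
  if (length(a) != n || length(b) != n) {
    stop("`values`, `factor_a`, `factor_b` must have equal length", call. = FALSE)
  }
  if (any(table(a, b) == 0L)) {
    stop("every cell of the two-factor layout needs at least one observation",
         call. = FALSE)
  }
  df_a <- nlevels(a) - 1L
  df_b <- nlevels(b) - 1L
  df_ab <- df_a * df_b
  r <- rank(values)
  ms_total <- stats::var(r)
  if (ms_total == 0) {
    return(list(A = new_stats_result("H", 0, df_a, n, 1),
                B = new_stats_result("H", 0, df_b, n, 1),
                AB = new_stats_result("H", 0, df_ab, n, 1)))
  }
  h <- function(ss_effect, df) {
    if (df == 0L) return(new_stats_result("H", 0, 0, n, 1))
    H <- ss_effect / ms_total
    new_stats_result("H", H, df, n, stats::pchisq(H, df, lower.tail = FALSE))
  }
  ss_oneway <- function(f) {
    sum(tapply(r, f, function(x) length(x) * (mean(x) - mean(r))^2))
  }
  # a single-level factor degenerates to a one-way rank layout (Kruskal-Wallis)
  if (df_a == 0L || df_b == 0L) {
    return(list(A = h(if (df_a) ss_oneway(a) else 0, df_a),
                B = h(if (df_b) ss_oneway(b) else 0, df_b),
                AB = h(0, df_ab)))
  }
  tab <- stats::anova(stats::lm(r ~ a * b))
  ss <- tab[["Sum Sq"]]
  names(ss) <- rownames(tab)
  list(A = h(unname(ss[["a"]]), df_a), B = h(unname(ss[["b"]]), df_b),
       AB = h(unname(ss[["a:b"]]), df_ab))
}

#' Pairwise post hoc comparisons
#'
#' All pairwise group comparisons under one of three methods: Tukey's HSD
#' (equal-variance, the natural follow-up to [oneway_anova()]),
#' Games--Howell (per-pair Welch standard errors and Welch--Satterthwaite
#' degrees of freedom referred to the studentized range, the natural
#' follow-up to [welch_anova()]), or Welch pairwise t tests with Bonferroni
#' correction.
#'
#' @inheritParams oneway_anova
#' @param method `"tukey"`, `"games_howell"` or `"bonferroni"`.
#' @return A symmetric k x k matrix of p-values with `NA` on the diagonal.
#' @export
pairwise_posthoc <- function(groups, method = c("tukey", "games_howell", "bonferroni")) {
  method <- match.arg(method)
  groups <- as_group_list(groups)
  k <- length(groups)
  labs <- if (!is.null(names(groups))) names(groups) else paste0("g", seq_len(k))
  pmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), vapply(groups, length, integer(1))))

  if (method == "tukey") {
    tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
    for (row in rownames(tk)) {
      ij <- as.integer(strsplit(row, "-", fixed = TRUE)[[1L]])
      pmat[ij[1L], ij[2L]] <- pmat[ij[2L], ij[1L]] <- tk[row, "p adj"]
    }
  } else if (method == "games_howell") {
    m <- vapply(groups, mean, numeric(1))
    v <- vapply(groups, stats::var, numeric(1))
    n <- vapply(groups, length, numeric(1))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      se2 <- v[i] / n[i] + v[j] / n[j]
      if (se2 == 0) { p <- if (m[i] == m[j]) 1 else 0 }
      else {
        t_stat <- abs(m[i] - m[j]) / sqrt(se2)
        df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
        p <- stats::ptukey(t_stat * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  } else {
    pt <- stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                                 pool.sd = FALSE)$p.value
    for (rn in rownames(pt)) for (cn in colnames(pt)) {
      if (!is.na(pt[rn, cn])) {
        i <- as.integer(rn); j <- as.integer(cn)
        pmat[i, j] <- pmat[j, i] <- min(1, pt[rn, cn])
      }
    }
  }
  pmat
}

#' Noncentral-F power of a one-way fixed-effects ANOVA
#'
#' @param n_total Total sample size (equal allocation across `k_groups`).
#' @param effect_size_f Cohen's f.
#' @param alpha Type I error rate.
#' @param k_groups Number of groups.
#' @return Power in \[0, 1\], from the noncentral F distribution with
#'   noncentrality f^2 * N and df (k - 1, N - k).
#' @export
anova_power <- function(n_total, effect_size_f, alpha = 0.05, k_groups = 3L) {
  df1 <- k_groups - 1
  df2 <- n_total - k_groups
  if (df2 <= 0) return(0)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = effect_size_f^2 * n_total, lower.tail = FALSE)
}

#' A-priori sample size for a one-way fixed-effects ANOVA
#'
#' Smallest total sample size N (equal allocation) whose noncentral-F power
#' reaches the target, with noncentrality lambda = f^2 N and degrees of
#' freedom (k - 1, N - k) -- the computation behind the standard a-priori
#' G*Power result. By default N is searched in steps of k so groups stay
#' equal (f = 0.25, alpha = .05, power = .80, k = 3 gives N = 159);
#' `search = "unit"` searches every integer N instead.
#'
#' @param effect_size_f Cohen's f (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param k_groups Number of groups (>= 2).
#' @param search `"group"` (N in multiples of k, default) or `"unit"`.
#' @param n_max Search ceiling; exceeding it raises an error.
#' @return Integer total sample size, with the achieved power in attribute
#'   `"power"`.
#' @examples
#' required_sample_size(0.25, 0.05, 0.80, 3)  # 159
#' @export
required_sample_size <- function(effect_size_f, alpha = 0.05, power = 0.80,
                                 k_groups = 3L, search = c("group", "unit"),
                                 n_max = 1e6) {
  search <- match.arg(search)
  if (effect_size_f <= 0) stop("`effect_size_f` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("`alpha` and `power` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (k_groups < 2L) stop("`k_groups` must be >= 2", call. = FALSE)
  step <- if (search == "group") k_groups else 1L
  n <- if (search == "group") 2L * k_groups else k_groups + 1L
  repeat {
    pw <- anova_power(n, effect_size_f, alpha, k_groups)
    if (pw >= power) break
    n <- n + step
    if (n > n_max) {
      stop("target power unattainable within `n_max` observations", call. = FALSE)
    }
  }
  structure(as.integer(n), power = pw)
}
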