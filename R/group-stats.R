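#' Group summary statistics
#'
#' Printed cohort summaries (mean, SD, n) from which a two-sample t-test
#' can be reconstructed exactly.
#'
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return list of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(min(max(p, 0), 1)), method = method),
            class = "lungspan_test")
}

#' @export
print.lungspan_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, if (is.null(x$df)) NA else x$df, x$p))
  invisible(x)
}

#' Decide between t-test and Mann-Whitney for a two-group comparison
#'
#' Shapiro-Wilk normality on each sample, then a Variance Ratio test
#' (F = larger/smaller sample variance, two-sided p): both samples normal
#' leads to a t-test (pooled when variances are homogeneous, Welch
#' otherwise); any non-normal sample leads to Mann-Whitney. Constant
#' samples (Shapiro-Wilk undefined) fall back to Mann-Whitney with a
#' warning.
#'
#' @param x,y numeric samples (n >= 3 each).
#' @param alpha significance level for the assumption checks (default 0.05).
#' @return list: `recommendation` ("t_pooled", "t_welch" or
#'   "mann_whitney"), `shapiro_x`, `shapiro_y` (test results or NULL),
#'   `variance_ratio` (test result).
#' @export
check_assumptions <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  vr <- {
    v <- sort(c(var(x), var(y)), decreasing = TRUE)
    ns <- c(length(x), length(y))[order(c(var(x), var(y)), decreasing = TRUE)]
    if (v[2] == 0) {
      test_result(NA_real_, NA_real_, if (v[1] == 0) 1 else 0, "variance_ratio")
    } else {
      f <- v[1] / v[2]
      p <- min(1, 2 * (1 - pf(f, ns[1] - 1, ns[2] - 1)))
      test_result(f, c(ns[1] - 1, ns[2] - 1), p, "variance_ratio")
    }
  }
  sw <- function(s) {
    if (length(unique(s)) < 3 || sd(s) == 0) return(NULL)
    r <- shapiro.test(s)
    test_result(r$statistic, NA_real_, r$p.value, "shapiro_wilk")
  }
  sx <- sw(x); sy <- sw(y)
  if (is.null(sx) || is.null(sy)) {
    warning("constant sample: Shapiro-Wilk undefined, recommending Mann-Whitney")
    rec <- "mann_whitney"
  } else if (sx$p > alpha && sy$p > alpha) {
    rec <- if (vr$p > alpha) "t_pooled" else "t_welch"
  } else {
    rec <- "mann_whitney"
  }
  list(recommendation = rec, shapiro_x = sx, shapiro_y = sy,
       variance_ratio = vr)
}

#' Two-sample t-test from printed summaries
#'
#' Reconstructs the two-sided t-test from (mean, SD, n) pairs. Pooled:
#' `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2)`,
#' `t = (m1-m2)/(sp*sqrt(1/n1+1/n2))`, df = n1+n2-2. Welch uses per-group
#' standard errors with Satterthwaite df. Equals the raw-data t-test run
#' on any samples having those summaries.
#'
#' @param a,b [summary_stats()] for the two groups.
#' @param pooled logical; pooled-variance (TRUE, default) or Welch.
#' @return `lungspan_test` (statistic, df, two-sided p).
#' @export
two_sample_t_from_summary <- function(a, b, pooled = TRUE) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  d <- a$mean - b$mean
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "t_pooled"
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    method <- "t_welch"
  }
  if (se == 0) return(test_result(0, df, 1, method))
  t <- d / se
  test_result(t, df, 2 * pt(-abs(t), df), method)
}

#' Two-sided Mann-Whitney test
#'
#' Exact enumeration when both samples have at most 20 observations and no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric samples.
#' @return `lungspan_test` with the U statistic.
#' @export
mann_whitney_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  r <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  test_result(r$statistic, NA_real_, r$p.value,
              if (exact) "mann_whitney_exact" else "mann_whitney_normal")
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' `chi2 = n * (max(0, |ad - bc| - n/2))^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' df = 1 -- algebraically identical to summing `(|O-E|-0.5)^2/E` over the
#' four cells (with the correction capped so over-correction cannot flip
#' the sign). A zero marginal makes the statistic undefined; p = 1 is
#' returned with a warning.
#'
#' @param a,b,c,d non-negative integer cell counts, rows = groups,
#'   columns = outcome (`a b / c d`).
#' @return `lungspan_test`.
#' @export
yates_chi_square <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n <= 0) stop("empty table")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    warning("zero marginal: chi-square undefined, returning p = 1")
    return(test_result(NA_real_, 1, 1, "yates_chi_square"))
  }
  num <- max(0, abs(a * d - b * c) - n / 2)
  stat <- n * num^2 / prod(marg)
  test_result(stat, 1, pchisq(stat, df = 1, lower.tail = FALSE),
              "yates_chi_square")
}

#' One-way ANOVA with Monte-Carlo Dunnett many-to-one comparisons
#'
#' Classical one-way ANOVA F across all groups, then each non-control
#' group is compared to the control with the usual Dunnett t statistic
#' `t_j = (mean_j - mean_0) / (s * sqrt(1/n_j + 1/n_0))` (s = pooled
#' residual SD). Adjusted p-values come from the null distribution of
#' `max_j |T_j|`, simulated with `n_mc` seeded draws of the correlated t
#' statistics (group means ~ normal, pooled variance ~ scaled chi-square);
#' the Monte-Carlo standard error of each adjusted p is reported.
#' Adjusted p-values are never smaller than the unadjusted ones.
#'
#' @param groups list of numeric samples; each n >= 2.
#' @param control_index index of the control group (default 1).
#' @param n_mc Monte-Carlo draws (default 1e5).
#' @param seed RNG seed for the null draws.
#' @return list: `anova` (`lungspan_test` with the F statistic),
#'   `comparisons` (data.frame: group, t, p_unadjusted, p_adjusted,
#'   mc_se), `n_mc`.
#' @export
anova_dunnett <- function(groups, control_index = 1, n_mc = 1e5, seed = 1) {
  k <- length(groups)
  stopifnot(k >= 2, all(vapply(groups, length, integer(1)) >= 2))
  if (control_index < 1 || control_index > k) stop("control index out of range")
  ns <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  N <- sum(ns)
  df_res <- N - k
  ss_res <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  s2 <- ss_res / df_res
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  if (s2 == 0) {
    f_test <- test_result(0, c(k - 1, df_res), 1, "anova_F")
  } else {
    f <- (ss_between / (k - 1)) / s2
    f_test <- test_result(f, c(k - 1, df_res),
                          pf(f, k - 1, df_res, lower.tail = FALSE), "anova_F")
  }
  others <- setdiff(seq_len(k), control_index)
  n0 <- ns[control_index]
  se <- sqrt(s2 * (1 / ns[others] + 1 / n0))
  tobs <- if (s2 == 0) rep(0, length(others)) else
    (means[others] - means[control_index]) / se
  p_un <- 2 * pt(-abs(tobs), df_res)

  # null distribution of max_j |T_j| with the Dunnett correlation structure
  set.seed(seed)
  z0 <- rnorm(n_mc, sd = 1 / sqrt(n0))
  s_draw <- sqrt(rchisq(n_mc, df_res) / df_res)
  tmax <- rep(0, n_mc)
  for (j in seq_along(others)) {
    zj <- rnorm(n_mc, sd = 1 / sqrt(ns[others[j]]))
    tmax <- pmax(tmax, abs((zj - z0) / (s_draw * sqrt(1 / ns[others[j]] + 1 / n0))))
  }
  p_adj <- vapply(abs(tobs), function(t0) mean(tmax >= t0), numeric(1))
  p_adj <- pmax(p_adj, p_un)         # adjustment cannot help
  mc_se <- sqrt(p_adj * (1 - p_adj) / n_mc)
  comparisons <- data.frame(group = others, t = tobs, df = df_res,
                            p_unadjusted = p_un, p_adjusted = pmin(p_adj, 1),
                            mc_se = mc_se, stringsAsFactors = FALSE)
  list(anova = f_test, comparisons = comparisons, n_mc = n_mc)
}
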