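test_that("summary t-test equals the raw-data t-test on matching samples", {
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    res_p <- two_sample_t_from_summary(summary_stats(mean(x), sd(x), length(x)),
                                       summary_stats(mean(y), sd(y), length(y)),
                                       pooled = TRUE)
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(res_p$statistic, unname(ref_p$statistic), tolerance = 1e-10)
    expect_equal(res_p$p, ref_p$p.value, tolerance = 1e-10)
    res_w <- two_sample_t_from_summary(summary_stats(mean(x), sd(x), length(x)),
                                       summary_stats(mean(y), sd(y), length(y)),
                                       pooled = FALSE)
    ref_w <- t.test(x, y)
    expect_equal(res_w$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(res_w$p, ref_w$p.value, tolerance = 1e-10)
  }
  # equal means -> t = 0, p = 1
  eq <- two_sample_t_from_summary(summary_stats(1, 1, 10), summary_stats(1, 2, 12))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
})

test_that("assumption checks route normal data to t and skewed data to Mann-Whitney", {
  rec_norm <- vapply(1:100, function(s) {
    set.seed(s)
    check_assumptions(rnorm(50), rnorm(50))$recommendation
  }, character(1))
  expect_gte(mean(rec_norm %in% c("t_pooled", "t_welch")), 0.85)

  rec_exp <- vapply(1:100, function(s) {
    set.seed(s + 1000)
    check_assumptions(rexp(50), rexp(50))$recommendation
  }, character(1))
  expect_gte(mean(rec_exp == "mann_whitney"), 0.9)

  # identical variances -> F = 1 and p = 1 at the boundary
  x <- c(1, 2, 3, 4, 5)
  vr <- check_assumptions(x, x + 10)$variance_ratio
  expect_equal(vr$statistic, 1)
  expect_equal(vr$p, 1)
  expect_warning(check_assumptions(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("Mann-Whitney: exact enumeration for small samples, correct null behavior", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)    # 2/20 orderings as extreme
  expect_identical(r$method, "mann_whitney_exact")
  same <- mann_whitney_test(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(same$p, 1, tolerance = 1e-9)
  expect_error(mann_whitney_test(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney has power against a one-SD shift", {
  rej <- vapply(1:200, function(s) {
    set.seed(s)
    mann_whitney_test(rnorm(50), rnorm(50) + 1)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.9)
})

test_that("Yates chi-square matches the cell-wise oracle and handles boundaries", {
  # independent oracle: sum over cells of (|O-E|-0.5)^2/E with capping
  yates_cellwise <- function(a, b, c, d) {
    o <- c(a, b, c, d)
    n <- sum(o)
    e <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / n
    sum((pmax(abs(o - e) - 0.5, 0))^2 / e)
  }
  set.seed(33)
  for (i in 1:1000) {
    t4 <- rpois(4, sample(3:40, 1)) + 1    # +1 keeps marginals positive
    ours <- yates_chi_square(t4[1], t4[2], t4[3], t4[4])
    expect_equal(ours$statistic, yates_cellwise(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
  }
  # and against the standard implementation on one table
  ref <- chisq.test(matrix(c(3, 8, 15, 8), 2), correct = TRUE)
  ours <- yates_chi_square(3, 15, 8, 8)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  bal <- yates_chi_square(5, 5, 5, 5)
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  expect_warning(z <- yates_chi_square(0, 0, 3, 5), "zero marginal")
  expect_equal(z$p, 1)
})

test_that("ANOVA-Dunnett handles degenerate inputs and bounds adjusted p-values", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- anova_dunnett(g, n_mc = 1e4, seed = 2)
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$comparisons$p_adjusted, c(1, 1))

  # two groups: adjusted equals the plain two-sample pooled t within MC error
  set.seed(6)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  res2 <- anova_dunnett(list(x, y), n_mc = 2e5, seed = 3)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(res2$comparisons$p_adjusted, ref$p.value, tolerance = 0.01)

  expect_error(anova_dunnett(list(x, y), control_index = 5), "out of range")
  # adjusted never below unadjusted
  set.seed(9)
  g3 <- lapply(1:4, function(i) rnorm(8))
  res3 <- anova_dunnett(g3, n_mc = 2e4, seed = 4)
  expect_true(all(res3$comparisons$p_adjusted >= res3$comparisons$p_unadjusted))
})

test_that("Monte-Carlo Dunnett agrees with the multivariate-t implementation", {
  skip_if_not_installed("multcomp")
  set.seed(12)
  g <- lapply(c(0, 0.5, 1, 1.5), function(m) rnorm(10, m))
  res <- anova_dunnett(g, n_mc = 2e5, seed = 7)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(paste0("g", 1:4), each = 10)))
  fit <- multcomp::glht(stats::aov(y ~ grp, df),
                        linfct = multcomp::mcp(grp = "Dunnett"))
  ref <- summary(fit, test = multcomp::adjusted("single-step"))
  expect_equal(res$comparisons$p_adjusted,
               as.numeric(ref$test$pvalues), tolerance = 0.01)
})
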