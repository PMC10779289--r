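# brute-force pooled-variance Student t from the textbook formulae
brute_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mean(x) - mean(y)) / se
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       ci = mean(x) - mean(y) + c(-1, 1) * qt(0.975, df) * se)
}

test_that("identical groups give statistic 0, difference 0, p = 1", {
  r <- group_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$mean_difference, 0)
  expect_equal(r$p, 1)
})

test_that("the unpaired Student t matches the brute-force formula", {
  r <- group_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  b <- brute_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(r$statistic, b$t, tolerance = 1e-12)
  expect_equal(r$df, b$df)
  expect_equal(r$p, b$p, tolerance = 1e-12)
  expect_equal(c(r$ci95_low, r$ci95_high), b$ci, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), 0.5)
    r <- group_t_test(x, y); b <- brute_t(x, y)
    expect_equal(r$statistic, b$t, tolerance = 1e-10)
    expect_equal(r$p, b$p, tolerance = 1e-10)
  }
})

test_that("a constant paired shift gives a degenerate CI and p -> 0", {
  x <- c(3, 1, 4, 1, 5)
  r <- group_t_test(x + 1, x, paired = TRUE)
  expect_equal(r$mean_difference, 1)
  expect_equal(c(r$ci95_low, r$ci95_high), c(1, 1))
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$statistic))
})

test_that("Welch and paired modes are available", {
  set.seed(1)
  x <- rnorm(8); y <- rnorm(8, 1, 3)
  rw <- group_t_test(x, y, var_equal = FALSE)
  expect_equal(rw$p, t.test(x, y)$p.value)
  rp <- group_t_test(x, y, paired = TRUE)
  expect_equal(rp$p, t.test(x, y, paired = TRUE)$p.value)
  expect_error(group_t_test(1:3, 1:4, paired = TRUE), "equal group sizes")
})

test_that("all-identical groups give F = 0 and adjusted p = 1", {
  r <- anova_dunnett(rep(5, 9), rep(c("ctl", "a", "b"), each = 3), "ctl")
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_anova, 1)
  expect_true(all(r$comparisons$p_adjusted == 1))
})

test_that("with two groups Dunnett reduces to the unadjusted t-test", {
  set.seed(7)
  x <- rnorm(6); y <- rnorm(5, 1)
  r <- anova_dunnett(c(x, y), rep(c("ctl", "trt"), c(6, 5)), "ctl")
  tt <- group_t_test(y, x)
  expect_equal(r$comparisons$p_adjusted, tt$p, tolerance = 1e-9)
  expect_equal(r$comparisons$estimate, tt$mean_difference, tolerance = 1e-12)
})

test_that("Dunnett agrees with the reference implementation (multcomp)", {
  skip_if_not_installed("multcomp")
  set.seed(12)
  d <- data.frame(g = factor(rep(c("ctl", "a", "b", "c"), times = c(6, 4, 5, 4)),
                             levels = c("ctl", "a", "b", "c")),
                  y = rnorm(19) + rep(c(0, 0.5, 1, 0), times = c(6, 4, 5, 4)))
  r <- anova_dunnett(d$y, as.character(d$g), "ctl")
  gl <- summary(multcomp::glht(stats::aov(y ~ g, d),
                               linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(unname(r$comparisons$t[match(c("a", "b", "c"),
                                            r$comparisons$group)]),
               unname(gl$test$tstat), tolerance = 1e-9)
  expect_equal(unname(r$comparisons$p_adjusted[match(c("a", "b", "c"),
                                                     r$comparisons$group)]),
               unname(as.numeric(gl$test$pvalues)), tolerance = 2e-3)
})

test_that("Dunnett-adjusted p never falls below the unadjusted p", {
  set.seed(9)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    g <- rep(paste0("g", seq_len(k)), each = 4)
    r <- anova_dunnett(rnorm(length(g)), g, "g1", ci = FALSE)
    expect_true(all(r$comparisons$p_adjusted >= r$comparisons$p_unadjusted))
  }
})

test_that("a missing control group is an error", {
  expect_error(anova_dunnett(rnorm(8), rep(c("a", "b"), 4), "ctl"),
               "control group")
})

test_that("a proportional 2x2 table gives X^2 = 0 and p = 1", {
  r <- chi_squared_2x2(matrix(c(10, 1, 20, 2), 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("chi-squared matches the sum((O-E)^2/E) brute force", {
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 10) + 1, 2, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - e)^2 / e)
    r <- chi_squared_2x2(tab)
    expect_equal(r$statistic, x2, tolerance = 1e-10)
    expect_equal(r$p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
  expect_error(chi_squared_2x2(matrix(c(1, 1, -1, 1), 2, 2)), "non-negative")
  expect_error(chi_squared_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
})

test_that("cohort percentages use the conventional rounding", {
  expect_equal(percent_of(8, 14), 57.1)
  expect_equal(percent_of(9, 14), 64.3)
  expect_equal(percent_of(13, 28), 46.4)
})

test_that("a noiseless 4PL is recovered to 0.1%", {
  doses <- 10^seq(0, 3, length.out = 7)
  y <- four_param_logistic(doses, top = 100, bottom = 0, ic50 = 100,
                           hill = 1)
  fit <- fit_4pl(doses, y)
  expect_true(fit$converged)
  expect_equal(fit$ic50_nM, 100, tolerance = 1e-3)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-3)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 1e-2)
})

test_that("the 4PL fit recovers IC50 under 5% replicate noise", {
  doses <- rep(10^seq(0, 3, length.out = 7), each = 3)
  set.seed(41)
  fits <- lapply(1:50, function(i) {
    mu <- four_param_logistic(doses, 100, 0, 100, 1)
    fit_4pl(doses, mu * (1 + rnorm(length(doses), 0, 0.05)))
  })
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  est <- vapply(fits, `[[`, 0, "ic50_nM")
  expect_gte(mean(abs(est - 100) / 100 < 0.2), 0.9)
  expect_lt(abs(mean(est) - 100) / 100, 0.05)   # bias of the estimator
})

test_that("monotone-increasing responses flip the Hill sign and are flagged", {
  doses <- 10^seq(0, 3, length.out = 6)
  y <- four_param_logistic(doses, top = 10, bottom = 90, ic50 = 50, hill = 1)
  fit <- fit_4pl(doses, y)   # rising curve, reduction expected by default
  expect_true(fit$converged)
  expect_lt(fit$hill_slope, 0)
  expect_true("hill_sign_inverted" %in% fit$flags)
})

test_that("degenerate dose designs are rejected", {
  expect_error(fit_4pl(c(1, 1, 2, 2), c(1, 2, 3, 4)), "4 distinct doses")
  expect_error(fit_4pl(c(-1, 1, 2, 3), 1:4), "positive")
})
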