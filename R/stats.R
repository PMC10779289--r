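#' Two-group Student t-test with mean difference and CI
#'
#' Classical Student t-test: pooled variance for the unpaired case (Welch is
#' available by flag), paired differences otherwise. The reported
#' `mean_difference` is `mean(x) - mean(y)` on whatever scale the inputs are
#' on (percent, RFU/ug, ...), with its 95% confidence interval.
#'
#' Degenerate inputs are resolved rather than erroring: identical constant
#' groups give statistic 0, difference 0, p = 1; a constant non-zero
#' (paired) shift gives a degenerate CI at the shift and p -> 0.
#'
#' @param x,y Numeric vectors (n >= 2 each; equal lengths when paired).
#' @param paired Paired-samples test.
#' @param var_equal Pooled-variance Student t (default); `FALSE` for Welch.
#' @param conf_level Confidence level of the interval.
#' @return A list of class `stat_test_result`: `test`, `statistic`, `df`,
#'   `p`, `mean_difference`, `ci95_low`, `ci95_high`, `n`.
#' @export
group_t_test <- function(x, y, paired = FALSE, var_equal = TRUE,
                         conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 2, length(y) >= 2)
  if (paired && length(x) != length(y))
    stop("paired test requires equal group sizes", call. = FALSE)
  nm <- if (paired) "paired t-test"
        else if (var_equal) "unpaired Student t-test" else "Welch t-test"
  diff <- if (paired) mean(x - y) else mean(x) - mean(y)
  degenerate <- if (paired) stats::sd(x - y) == 0
                else stats::sd(x) == 0 && stats::sd(y) == 0
  if (degenerate) {
    res <- list(test = nm,
                statistic = if (diff == 0) 0 else sign(diff) * Inf,
                df = if (paired) length(x) - 1 else length(x) + length(y) - 2,
                p = if (diff == 0) 1 else 0,
                mean_difference = diff, ci95_low = diff, ci95_high = diff,
                n = c(length(x), length(y)))
    return(structure(res, class = "stat_test_result"))
  }
  ht <- stats::t.test(x, y, paired = paired, var.equal = var_equal,
                      conf.level = conf_level)
  structure(list(test = nm, statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 mean_difference = diff,
                 ci95_low = ht$conf.int[1], ci95_high = ht$conf.int[2],
                 n = c(length(x), length(y))),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %.4g, p %.4g\n",
              x$test, x$statistic, x$df, x$p))
  if (is.finite(x$mean_difference))
    cat(sprintf("  mean difference %.4g (CI: %.4g to %.4g), n = %s\n",
                x$mean_difference, x$ci95_low, x$ci95_high,
                paste(x$n, collapse = "/")))
  invisible(x)
}

# evaluate fn with a locally fixed RNG stream, restoring global state
with_fixed_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits a one-way ANOVA and compares every group with the designated
#' control, adjusting for multiplicity with Dunnett's procedure: adjusted
#' p-values and simultaneous confidence intervals come from the
#' max-|t| multivariate-t distribution with the correlation structure
#' implied by the group sizes (`rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j +
#' n0)))`, which reduces to the equal-correlation case when balanced). The
#' multivariate-t probabilities are evaluated with a deterministic
#' quasi-Monte-Carlo integration (fixed internal seed, global RNG state
#' untouched).
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length; each group needs n >= 2.
#' @param control Control group label.
#' @param conf_level Simultaneous confidence level.
#' @param ci Compute simultaneous CIs (skippable for speed in simulations).
#' @return A list of class `dunnett_result`: `f_statistic`, `df`, `p_anova`,
#'   and a `comparisons` data frame (group, estimate, se, t, p_unadjusted,
#'   p_adjusted, ci_low, ci_high).
#' @export
anova_dunnett <- function(values, groups, control, conf_level = 0.95,
                          ci = TRUE) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups)
    stop("control group '", control, "' missing", call. = FALSE)
  ns <- table(groups)
  if (length(ns) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)

  if (stats::sd(values) == 0) {
    others <- setdiff(names(ns), control)
    comp <- data.frame(group = others, estimate = 0, se = 0, t = 0,
                       p_unadjusted = 1, p_adjusted = 1,
                       ci_low = 0, ci_high = 0, stringsAsFactors = FALSE)
    return(structure(list(f_statistic = 0,
                          df = c(length(ns) - 1, length(values) - length(ns)),
                          p_anova = 1, comparisons = comp),
                     class = "dunnett_result"))
  }

  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  ftab <- summary(fit)[[1]]
  fstat <- ftab[["F value"]][1]
  p_anova <- ftab[["Pr(>F)"]][1]

  k <- nlevels(g)
  means <- tapply(values, g, mean)
  vars <- tapply(values, g, stats::var)
  n <- as.numeric(table(g))
  names(n) <- levels(g)
  df_err <- length(values) - k
  mse <- sum((n - 1) * vars) / df_err

  others <- setdiff(levels(g), control)
  n0 <- n[[control]]
  est <- means[others] - means[[control]]
  se <- sqrt(mse * (1 / n[others] + 1 / n0))
  tstat <- est / se
  m <- length(others)
  lam <- sqrt(n[others] / (n[others] + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1

  pmax_abs_t <- function(q) {
    # P(max_i |T_i| <= q), T ~ multivariate t(df_err, corr)
    if (m == 1) return(stats::pt(q, df_err) - stats::pt(-q, df_err))
    with_fixed_seed(20231219, function()
      as.numeric(mvtnorm::pmvt(lower = rep(-q, m), upper = rep(q, m),
                               df = df_err, corr = corr,
                               algorithm = mvtnorm::GenzBretz(
                                 abseps = 1e-4, maxpts = 5000))))
  }
  p_adj <- vapply(abs(tstat), function(a) max(0, 1 - pmax_abs_t(a)), 0)
  p_un <- 2 * stats::pt(-abs(tstat), df_err)
  p_adj <- pmax(p_adj, p_un)  # adjusted never below unadjusted

  ci_low <- ci_high <- rep(NA_real_, m)
  if (ci) {
    qcrit <- stats::uniroot(function(q) pmax_abs_t(q) - conf_level,
                            lower = 1e-6, upper = 50, tol = 1e-6)$root
    ci_low <- est - qcrit * se
    ci_high <- est + qcrit * se
  }
  comp <- data.frame(group = others, estimate = as.numeric(est),
                     se = as.numeric(se), t = as.numeric(tstat),
                     p_unadjusted = as.numeric(p_un),
                     p_adjusted = as.numeric(p_adj),
                     ci_low = as.numeric(ci_low),
                     ci_high = as.numeric(ci_high),
                     stringsAsFactors = FALSE)
  structure(list(f_statistic = fstat, df = c(k - 1, df_err),
                 p_anova = p_anova, comparisons = comp),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_anova))
  cat("Dunnett comparisons vs control:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Uncorrected Pearson X^2 (no Yates continuity correction), df = 1. The
#' uncorrected statistic is the compatibility choice: on cohort-table counts
#' it reproduces the conventional printed p-values that the corrected
#' statistic does not.
#'
#' Small expected counts are allowed without complaint — the asymptotic
#' p-value is what cohort tables conventionally report — but the usual
#' caution about expected counts below 5 applies.
#'
#' @param table 2x2 matrix of non-negative integer counts, all margins > 0.
#' @return A `stat_test_result` (statistic = X^2, df = 1, p two-sided;
#'   `mean_difference` is the difference in row-1 proportions between the
#'   two columns, with its Wald 95% CI).
#' @export
chi_squared_2x2 <- function(table) {
  stopifnot(is.matrix(table), identical(dim(table), c(2L, 2L)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  p1 <- table[1, 1] / sum(table[, 1])
  p2 <- table[1, 2] / sum(table[, 2])
  se <- sqrt(p1 * (1 - p1) / sum(table[, 1]) +
             p2 * (1 - p2) / sum(table[, 2]))
  structure(list(test = "Pearson chi-squared (uncorrected)",
                 statistic = unname(ht$statistic), df = 1,
                 p = ht$p.value, mean_difference = p1 - p2,
                 ci95_low = p1 - p2 - 1.96 * se,
                 ci95_high = p1 - p2 + 1.96 * se,
                 n = colSums(table)),
            class = "stat_test_result")
}

#' Count as a percentage of a group
#'
#' Cohort-table convenience: `100 * k / n`, rounded to the conventional one
#' decimal (8 of 14 -> 57.1).
#'
#' @param k Count.
#' @param n Group size (> 0).
#' @param digits Decimals to round to.
#' @return Percentage.
#' @export
percent_of <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  round(100 * k / n, digits)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x / IC50)^h)`,
#' parameterised in log-dose (`logIC50`) for stable optimisation
#' (Levenberg-Marquardt). Standard errors come from the Jacobian at the
#' optimum; the IC50 standard error is delta-method transformed from the
#' log scale, reported in dose units to match the conventional
#' "IC50 = value +/- SE" format.
#'
#' @param dose Positive doses (nM), at least 4 distinct values.
#' @param response Responses (e.g. percent of control), same length.
#' @param expected_direction The pharmacological expectation: with
#'   `"decreasing"` (an inhibitor) a fitted Hill slope < 0 (i.e. a
#'   monotone-increasing response) is flagged `"hill_sign_inverted"` in the
#'   diagnostics; `"any"` disables the check.
#' @return A list of class `dose_response_fit`: `ic50_nM`, `ic50_se_nM`,
#'   `hill_slope`, `top`, `bottom`, `rss`, `converged`, `flags`, `n`,
#'   and the underlying `fit` object.
#' @export
fit_4pl <- function(dose, response,
                    expected_direction = c("decreasing", "increasing",
                                           "any")) {
  expected_direction <- match.arg(expected_direction)
  stopifnot(is.numeric(dose), is.numeric(response),
            length(dose) == length(response))
  if (any(dose <= 0)) stop("doses must be positive", call. = FALSE)
  if (length(unique(dose)) < 4)
    stop("need at least 4 distinct doses", call. = FALSE)
  ld <- log(dose)
  dm <- tapply(response, ld, mean)
  lds <- as.numeric(names(dm))
  slope_sign <- if (dm[[length(dm)]] <= dm[[1]]) 1 else -1
  mid <- (max(dm) + min(dm)) / 2
  start <- list(top = max(dm), bottom = min(dm),
                logIC50 = lds[which.min(abs(dm - mid))],
                h = slope_sign)
  fit <- try(minpack.lm::nlsLM(
    response ~ bottom + (top - bottom) / (1 + exp(h * (ld - logIC50))),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(ic50_nM = NA_real_, ic50_se_nM = NA_real_,
                          hill_slope = NA_real_, top = NA_real_,
                          bottom = NA_real_, rss = NA_real_,
                          converged = FALSE,
                          flags = paste("optimizer error:",
                                        attr(fit, "condition")$message),
                          n = length(dose), fit = NULL),
                     class = "dose_response_fit"))
  }
  co <- summary(fit)$coefficients
  ic50 <- exp(co["logIC50", "Estimate"])
  ic50_se <- ic50 * co["logIC50", "Std. Error"]
  h <- co["h", "Estimate"]
  flags <- character(0)
  if (expected_direction == "decreasing" && h < 0)
    flags <- c(flags, "hill_sign_inverted")
  if (expected_direction == "increasing" && h > 0)
    flags <- c(flags, "hill_sign_inverted")
  structure(list(ic50_nM = ic50, ic50_se_nM = ic50_se, hill_slope = h,
                 top = co["top", "Estimate"],
                 bottom = co["bottom", "Estimate"],
                 rss = sum(stats::residuals(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 flags = flags, n = length(dose), fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) cat("4PL fit: NOT converged\n")
  cat(sprintf(
    "4PL fit: IC50 = %.2f nM ± %.2f nM, Hill %.3g, top %.4g, bottom %.4g\n",
    x$ic50_nM, x$ic50_se_nM, x$hill_slope, x$top, x$bottom))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
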