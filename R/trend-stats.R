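#' Poisson log-linear quarterly trend
#'
#' Maximum-likelihood fit of `log E[count] = beta0 + beta1 * quarter_index`
#' (quarter index 0..n-1, no offset) by iteratively reweighted least squares,
#' with a Wald test of `beta1 = 0`. The per-quarter percent change is
#' `100 * (1 - exp(beta1))` — positive for a declining series, so a quarterly
#' rate ratio of 0.984 reads as a 1.6% reduction per quarter.
#'
#' @param counts Per-quarter prescription counts (length >= 3, all >= 0, not
#'   all zero). Non-integer totals are accepted (quasi-counts).
#' @return A `trend_result` list: `beta0`, `beta1`, `se_beta1`,
#'   `pct_change_per_quarter`, `p_value`, `n_quarters`, `fitted`.
#' @export
poisson_trend <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 3) abort_fatal("poisson_trend: need at least 3 quarters")
  if (any(is.na(counts) | counts < 0)) abort_fatal("poisson_trend: counts must be >= 0")
  if (all(counts == 0)) abort_fatal("poisson_trend: all-zero series")
  idx <- seq_along(counts) - 1
  fit <- suppressWarnings(
    glm(counts ~ idx, family = poisson(link = "log"),
        control = glm.control(epsilon = 1e-10, maxit = 50))
  )
  if (!fit$converged) {
    abort_fatal(sprintf("poisson_trend: IRLS did not converge in %d iterations (deviance %.6g)",
                        fit$iter, fit$deviance))
  }
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[["idx"]]
  z <- b[["idx"]] / se
  structure(list(
    beta0 = unname(b[["(Intercept)"]]),
    beta1 = unname(b[["idx"]]),
    se_beta1 = se,
    pct_change_per_quarter = 100 * (1 - exp(b[["idx"]])),
    p_value = 2 * pnorm(-abs(z)),
    n_quarters = length(counts),
    fitted = unname(fit$fitted.values)
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Poisson trend over %d quarters: rate ratio %.4f/quarter (%.2f%% %s per quarter), p = %.3g\n",
    x$n_quarters, exp(x$beta1), abs(x$pct_change_per_quarter),
    if (x$beta1 < 0) "reduction" else "increase", x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with 1 degree of
#' freedom on the table `rbind(c(a, b), c(c, d))`; the p-value is the upper
#' tail of the chi-square distribution.
#'
#' @param a,b,c,d Cell counts (first row `a, b`; second row `c, d`).
#' @return List with `chi2_stat` and `p_value`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells) | cells < 0)) abort_fatal("chisq_2x2: counts must be >= 0")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort_fatal("chisq_2x2: zero row or column margin")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2_stat = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Wilson score confidence interval for a proportion, in percent
#'
#' @param numerator,denominator Counts with `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)` in percent; always contains the point
#'   proportion.
#' @export
proportion_ci <- function(numerator, denominator, level = 0.95) {
  if (denominator <= 0) abort_fatal("proportion_ci: denominator must be > 0")
  if (numerator < 0 || numerator > denominator) {
    abort_fatal("proportion_ci: need 0 <= numerator <= denominator")
  }
  ht <- suppressWarnings(prop.test(numerator, denominator, conf.level = level,
                                   correct = FALSE))
  c(low = 100 * ht$conf.int[1], high = 100 * ht$conf.int[2])
}

#' Pre/post comparison of a guideline-exceedance proportion
#'
#' Compares the exceedance proportion in a baseline period (the quarter before
#' any scorecard was released) against the pooled subsequent quarters: pools
#' the post-period numerators and denominators, computes per-period proportions
#' with Wilson confidence intervals, and tests homogeneity with the
#' uncorrected Pearson chi-square.
#'
#' @param pre,post Each a list or data frame with elements/columns `numerator`
#'   and `denominator`; `post` may span several quarters (pooled before
#'   testing), `pre` is typically one.
#' @param level Confidence level for the interval (default 0.95).
#' @return A `prepost_comparison` list with the pooled counts, proportions and
#'   CIs in percent, `chi2_stat`, and `p_value`.
#' @export
prepost_compare <- function(pre, post, level = 0.95) {
  pre_num <- sum(pre$numerator); pre_den <- sum(pre$denominator)
  post_num <- sum(post$numerator); post_den <- sum(post$denominator)
  if (post_den <= 0 || pre_den <= 0) abort_fatal("prepost_compare: empty period")
  test <- chisq_2x2(pre_num, pre_den - pre_num, post_num, post_den - post_num)
  pre_ci <- proportion_ci(pre_num, pre_den, level)
  post_ci <- proportion_ci(post_num, post_den, level)
  structure(list(
    pre_numerator = pre_num, pre_denominator = pre_den,
    post_numerator = post_num, post_denominator = post_den,
    pre_proportion = 100 * pre_num / pre_den,
    post_proportion = 100 * post_num / post_den,
    pre_ci_low = unname(pre_ci["low"]), pre_ci_high = unname(pre_ci["high"]),
    post_ci_low = unname(post_ci["low"]), post_ci_high = unname(post_ci["high"]),
    chi2_stat = test$chi2_stat, p_value = test$p_value
  ), class = "prepost_comparison")
}

#' @export
print.prepost_comparison <- function(x, ...) {
  fmt <- function(p, lo, hi) sprintf("%.2f%% (95%% CI %.2f-%.2f)", p, lo, hi)
  cat("Pre: ", fmt(x$pre_proportion, x$pre_ci_low, x$pre_ci_high), "\n",
      "Post:", fmt(x$post_proportion, x$post_ci_low, x$post_ci_high), "\n",
      sprintf("chi-square = %.4f, p = %.3g\n", x$chi2_stat, x$p_value), sep = "")
  invisible(x)
}
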