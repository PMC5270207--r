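# Two-sample inference for the with-bone vs without-bone endpoint
# temperatures: pooled t (from raw data or printed summaries), Mann-Whitney
# U with exact small-sample p, Lilliefors-corrected normality screening, and
# the prospective sample-size calculation.

new_test_result <- function(method, estimate = NA_real_, statistic, df = NA_real_,
                            p_value, conf_low = NA_real_, conf_high = NA_real_,
                            degenerate = FALSE) {
  tibble::tibble(
    method = method, estimate = estimate, statistic = statistic, df = df,
    p_value = p_value, conf_low = conf_low, conf_high = conf_high,
    degenerate = degenerate
  )
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's pooled-variance t test for a difference in means computed from
#' `(mean, sd, n)` summaries alone, with the two-sided p value and the 95%
#' confidence interval for `mean_a - mean_b` from the pooled standard error
#' and the t quantile on `n_a + n_b - 2` degrees of freedom.  This is the
#' test identified by a reported `t(38)` for two arms of 20.
#'
#' @param mean_a,sd_a,n_a First group's mean, SD and size (`n_a >= 2`).
#' @param mean_b,sd_b,n_b Second group's summaries.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `method`, `estimate` (mean_a - mean_b),
#'   `statistic`, `df`, `p_value`, `conf_low`, `conf_high`, `degenerate`.
#' @export
#' @examples
#' # central 10 mm thermocouple, without vs with bone:
#' pooled_t_from_summaries(42.01, 0.47, 20, 42.37, 0.96, 20)
pooled_t_from_summaries <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                    conf_level = 0.95) {
  if (n_a < 2 || n_b < 2) abort("both groups need n >= 2")
  if (sd_a < 0 || sd_b < 0) abort("standard deviations must be non-negative")
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  est <- mean_a - mean_b
  if (se == 0) {
    stat <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
    return(new_test_result("pooled t", est, stat, df, p, est, est,
                           degenerate = TRUE))
  }
  stat <- est / se
  tq <- qt(1 - (1 - conf_level) / 2, df)
  new_test_result("pooled t", est, stat, df,
                  2 * pt(-abs(stat), df),
                  est - tq * se, est + tq * se)
}

#' Pooled two-sample t test from raw data
#'
#' Identical to [pooled_t_from_summaries()] applied to the two vectors'
#' sample means and SDs.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row result tibble, see [pooled_t_from_summaries()].
#' @export
pooled_t_test <- function(x, y, conf_level = 0.95) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("both groups need n >= 2")
  pooled_t_from_summaries(mean(x), sd(x), length(x),
                          mean(y), sd(y), length(y), conf_level)
}

# U statistic of the first sample from midranks.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exact two-sided p by complete enumeration of group assignments (handles
# ties through midranks); feasible for small groups only.
mw_exact_enumeration_p <- function(x, y) {
  n_x <- length(x)
  pool <- c(x, y)
  combs <- utils::combn(length(pool), n_x)
  u_obs <- u_statistic(x, y)
  mu <- n_x * length(y) / 2
  us <- apply(combs, 2, function(ix) u_statistic(pool[ix], pool[-ix]))
  # two-sided: arrangements at least as extreme about the null mean
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney rank-sum test
#'
#' The U statistic of the first sample (count form, midranks for ties) with
#' a two-sided p value computed, in order of preference: by the exact null
#' distribution when the sample sizes are small (`n_x * n_y <= 400`) and,
#' if ties are present, the exact distribution is replaced by complete
#' enumeration of group assignments when that is feasible
#' (`choose(n_x + n_y, n_x) <= 2e5`); otherwise by the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (non-empty).
#' @return A one-row result tibble; `statistic` is `U` for `x`, `df` is `NA`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  n_x <- length(x)
  n_y <- length(y)
  u <- u_statistic(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  small <- n_x * n_y <= 400

  p <- if (small && !ties) {
    # exact distribution of U (equivalent to enumerating all assignments)
    lo <- pwilcox(u, n_x, n_y)
    hi <- 1 - pwilcox(u - 1, n_x, n_y)
    min(1, 2 * min(lo, hi))
  } else if (small && choose(n_x + n_y, n_x) <= 2e5) {
    mw_exact_enumeration_p(x, y)
  } else {
    mu <- n_x * n_y / 2
    n <- n_x + n_y
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_x * n_y / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(new_test_result("Mann-Whitney U", NA_real_, u,
                                            NA_real_, 1, degenerate = TRUE))
    zc <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(zc)))
  }
  new_test_result("Mann-Whitney U", statistic = u, p_value = p)
}

#' Kolmogorov-Smirnov normality screening
#'
#' Distance between the sample's empirical CDF and a normal distribution
#' with the sample's own mean and SD.  Because the parameters are estimated
#' from the sample, the p value uses the Lilliefors correction by default;
#' `corrected = FALSE` gives the plain (anti-conservative) KS p value
#' instead.  A degenerate sample (zero SD) is flagged with distance 1.
#'
#' @param x Numeric vector, length >= 4.
#' @param corrected Use the Lilliefors p value (default `TRUE`).
#' @return A one-row result tibble; `statistic` is the KS distance.
#' @export
ks_normality <- function(x, corrected = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 4) abort("normality screening needs at least 4 values")
  if (sd(x) == 0) {
    return(new_test_result("Lilliefors", statistic = 1, p_value = 0,
                           degenerate = TRUE))
  }
  if (corrected) {
    ks <- nortest::lillie.test(x)
    new_test_result("Lilliefors", statistic = unname(ks$statistic),
                    p_value = unname(ks$p.value))
  } else {
    ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    new_test_result("KS (plain)", statistic = unname(ks$statistic),
                    p_value = unname(ks$p.value))
  }
}

#' Prospective sample size for a two-sided pooled t test
#'
#' Smallest per-group `n` such that the two-sided pooled t test at level
#' `alpha` attains the requested power for a true mean difference `delta`
#' and common SD `sigma` (noncentral-t iteration via [stats::power.t.test()];
#' the normal-approximation starting value
#' `2 (z_{1-alpha/2} + z_{power})^2 (sigma/delta)^2` is available with
#' `method = "normal"`).  With the planning values alpha 0.05, power 0.80
#' and delta = sigma = 0.5 this gives 17 per group.
#'
#' @param alpha Two-sided significance level, in (0, 1).
#' @param power Target power, in (alpha, 1).
#' @param delta True difference in means (> 0), degC.
#' @param sigma Common SD (> 0), degC.
#' @param method `"t"` (noncentral-t, default) or `"normal"`.
#' @return Integer sample size per group (at least 2).
#' @export
#' @examples
#' required_sample_size(0.05, 0.80, 0.5, 0.5) # 17
required_sample_size <- function(alpha = 0.05, power = 0.80, delta, sigma,
                                 method = c("t", "normal")) {
  method <- match.arg(method)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  if (!is.finite(power) || power <= alpha || power >= 1) {
    abort("power must lie in (alpha, 1)")
  }
  if (!is.finite(delta) || delta <= 0 || !is.finite(sigma) || sigma <= 0) {
    abort("delta and sigma must be positive")
  }
  n_norm <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * (sigma / delta)^2
  if (method == "normal") return(max(2L, as.integer(ceiling(n_norm - 1e-9))))
  n <- tryCatch(
    power.t.test(delta = delta, sd = sigma, sig.level = alpha, power = power,
                 type = "two.sample", alternative = "two.sided")$n,
    error = function(e) n_norm
  )
  max(2L, as.integer(ceiling(n - 1e-9)))
}

#' Compare the two study arms thermocouple by thermocouple
#'
#' Applies the study's decision rule at each thermocouple: screen both arms
#' with the Lilliefors-corrected KS normality test at level `alpha`; if both
#' pass, compare the arms with the pooled t test, otherwise with the
#' Mann-Whitney U test.  No multiplicity correction is applied.
#'
#' @param a,b Measurement tibbles (columns `probe`, `temp_c`; e.g.
#'   [simulate_measurements()] output), one arm each, with matching probe
#'   labels.  `a` is the first sample for the U convention and the first
#'   group of the t test.
#' @param alpha Significance level used both for the normality screen and
#'   reported for the comparisons (default 0.05).
#' @return A tibble with one row per thermocouple: the chosen `method`, its
#'   `statistic`, `df`, `p_value`, confidence bounds (t only), the two
#'   normality p values, and `significant` at `alpha`.
#' @export
compare_arms <- function(a, b, alpha = 0.05) {
  for (m in list(a, b)) {
    if (!all(c("probe", "temp_c") %in% names(m))) {
      abort("measurement sets need columns probe, temp_c")
    }
  }
  pa <- sort(unique(a$probe))
  pb <- sort(unique(b$probe))
  if (!identical(pa, pb)) {
    abort("thermocouple labels differ between the arms")
  }
  purrr::map_dfr(pa, function(p) {
    x <- a$temp_c[a$probe == p]
    y <- b$temp_c[b$probe == p]
    ka <- ks_normality(x)
    kb <- ks_normality(y)
    normal_ok <- ka$p_value > alpha && kb$p_value > alpha
    res <- if (normal_ok) pooled_t_test(x, y) else mann_whitney_u(x, y)
    dplyr::mutate(res,
      probe = p, normality_p_a = ka$p_value, normality_p_b = kb$p_value,
      significant = .data$p_value < alpha, .before = 1
    )
  })
}
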