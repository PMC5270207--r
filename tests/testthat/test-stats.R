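test_that("pooled t from summaries reproduces the reported TP2 comparison", {
  r <- pooled_t_from_summaries(42.01, 0.47, 20, 42.37, 0.96, 20)
  expect_equal(r$df, 38)
  expect_equal(r$statistic, -1.52, tolerance = 0.015)
  expect_equal(r$conf_low, -0.85, tolerance = 0.01)
  expect_equal(r$conf_high, 0.12, tolerance = 0.04)
  expect_gt(r$p_value, 0.05) # the one thermocouple without a difference
  expect_equal(r$p_value, 0.14, tolerance = 0.05)
})

test_that("pooled t matches hand computation and degenerates sanely", {
  r <- pooled_t_from_summaries(1, 1, 5, 0, 1, 5)
  expect_equal(r$statistic, 1 / sqrt(2 / 5))
  expect_equal(r$df, 8)
  same <- pooled_t_from_summaries(3, 1, 10, 3, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$conf_low, -same$conf_high)
  expect_error(pooled_t_from_summaries(1, 1, 1, 0, 1, 5), "n >= 2")
})

test_that("pooled t is antisymmetric under swapping the groups", {
  withr::with_seed(21, {
    x <- rnorm(12, 1, 2)
    y <- rnorm(15, 0, 1.5)
  })
  ab <- pooled_t_test(x, y)
  ba <- pooled_t_test(y, x)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$conf_low, -ba$conf_high)
  expect_equal(ab$conf_high, -ba$conf_low)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("data path agrees with the summary path and with stats::t.test", {
  withr::with_seed(8, {
    x <- rnorm(20, 42, 0.5)
    y <- rnorm(20, 42.4, 1)
  })
  a <- pooled_t_test(x, y)
  b <- pooled_t_from_summaries(mean(x), sd(x), 20, mean(y), sd(y), 20)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$conf_low, b$conf_low, tolerance = 1e-12)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(a$statistic, unname(ref$statistic))
  expect_equal(a$p_value, unname(ref$p.value))
  expect_equal(c(a$conf_low, a$conf_high), as.numeric(ref$conf.int))
  expect_equal(a$df, unname(ref$parameter))
})

test_that("x = y gives t = 0", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  r <- pooled_t_test(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("pooled t holds its nominal type-I error under the null", {
  nrep <- 10000
  n <- 20
  withr::with_seed(1234, {
    x <- matrix(rnorm(nrep * n), n)
    y <- matrix(rnorm(nrep * n), n)
  })
  p <- vapply(seq_len(nrep), function(i) {
    pooled_t_test(x[, i], y[, i])$p_value
  }, numeric(1))
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.12) # 0.05 +- 0.006
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.006)
})

test_that("Mann-Whitney U matches the small-sample enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3) # 2 of 6 assignments as extreme
  expect_true(is.na(r$df))
})

test_that("U statistics of the two samples sum to nx * ny without ties", {
  withr::with_seed(31, {
    for (i in 1:20) {
      nx <- sample(2:8, 1)
      ny <- sample(2:8, 1)
      x <- rnorm(nx)
      y <- rnorm(ny)
      ux <- mann_whitney_u(x, y)$statistic
      uy <- mann_whitney_u(y, x)$statistic
      expect_equal(ux + uy, nx * ny)
    }
  })
})

test_that("fully tied samples give U = n^2/2 and p = 1", {
  r <- mann_whitney_u(rep(2, 5), rep(2, 5))
  expect_equal(r$statistic, 25 / 2)
  expect_equal(r$p_value, 1)
})

test_that("exact p equals full enumeration for all group sizes up to 6", {
  withr::with_seed(99, {
    for (nx in 2:6) {
      for (ny in 2:6) {
        x <- rnorm(nx)
        y <- rnorm(ny, 0.8)
        expect_equal(mann_whitney_u(x, y)$p_value, mw_enumeration_p(x, y),
                     tolerance = 1e-12,
                     label = sprintf("nx=%d ny=%d", nx, ny))
        # with ties present the enumeration route is used directly
        xt <- round(rnorm(nx) * 2) / 2
        yt <- round(rnorm(ny, 0.8) * 2) / 2
        expect_equal(mann_whitney_u(xt, yt)$p_value,
                     mw_enumeration_p(xt, yt), tolerance = 1e-12)
      }
    }
  })
})

test_that("tie-free exact p agrees with stats::wilcox.test", {
  withr::with_seed(17, {
    x <- rnorm(9)
    y <- rnorm(11, 0.5)
  })
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  withr::with_seed(5, {
    x <- round(rnorm(25), 1)
    y <- round(rnorm(25, 0.7), 1)
  })
  got <- mann_whitney_u(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("normality screening is calibrated and flags degenerate input", {
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  deg <- ks_normality(rep(5, 10))
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 1)
  # a smooth normal-quantile grid is as normal as a sample can look
  grid <- qnorm(seq(0.5 / 20, 1 - 0.5 / 20, length.out = 20))
  expect_lt(ks_normality(grid)$statistic, 0.05)
  expect_gt(ks_normality(grid)$p_value, 0.9)
  # Lilliefors keeps ~95% of true-normal samples at alpha = 0.05
  withr::with_seed(2024, {
    keep <- vapply(1:1000, function(i) {
      ks_normality(rnorm(20))$p_value > 0.05
    }, logical(1))
  })
  expect_gte(mean(keep), 0.94)
  # the plain-KS variant is anti-conservative less often (higher p)
  withr::with_seed(3, x <- rnorm(20))
  expect_gte(ks_normality(x, corrected = FALSE)$p_value,
             ks_normality(x)$p_value)
})

test_that("prospective sample size reproduces the planning calculation", {
  # alpha 0.05, power 80%, delta = sigma = 0.5
  expect_equal(required_sample_size(0.05, 0.80, 0.5, 0.5), 17L)
  expect_equal(required_sample_size(0.05, 0.80, 0.5, 0.5, method = "normal"),
               16L)
  # enormous effect needs only the minimum group size
  expect_equal(required_sample_size(0.05, 0.80, delta = 1e6, sigma = 0.5), 2L)
  # doubling sigma at fixed delta quadruples the normal-approximation n
  n1 <- required_sample_size(0.05, 0.80, 0.5, 0.5, method = "normal")
  n2 <- required_sample_size(0.05, 0.80, 0.5, 1.0, method = "normal")
  expect_gte(n2, 4 * (n1 - 1))
  expect_lte(n2, 4 * n1)
  # monotone: larger delta, fewer samples; more power, more samples
  expect_lte(required_sample_size(0.05, 0.80, 1.0, 0.5),
             required_sample_size(0.05, 0.80, 0.5, 0.5))
  expect_gte(required_sample_size(0.05, 0.90, 0.5, 0.5),
             required_sample_size(0.05, 0.80, 0.5, 0.5))
  expect_error(required_sample_size(0.05, 0.04, 0.5, 0.5), "power")
  expect_error(required_sample_size(0.05, 0.80, -1, 0.5), "delta")
})

test_that("compare_arms applies the normality-gated decision rule", {
  s <- calorimeter_summaries()
  m <- simulate_measurements(s, seed = 1)
  arms <- split(m, m$arm)
  res <- compare_arms(arms$without_bone, arms$with_bone)
  expect_equal(nrow(res), 6)
  expect_true(all(res$method %in% c("pooled t", "Mann-Whitney U")))
  # the rule: t iff both arms pass the screen
  both_normal <- res$normality_p_a > 0.05 & res$normality_p_b > 0.05
  expect_equal(res$method == "pooled t", both_normal)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # separated near-constant arms always reject
  tight <- dplyr::mutate(s, sd_c = 1e-6,
                         mean_c = mean_c + ifelse(arm == "with_bone", 5, 0))
  mt <- simulate_measurements(tight, seed = 2)
  at <- split(mt, mt$arm)
  rt <- compare_arms(at$without_bone, at$with_bone)
  expect_true(all(rt$significant))

  bad <- dplyr::mutate(arms$with_bone, probe = sub("TP1", "TP9", probe))
  expect_error(compare_arms(arms$without_bone, bad), "labels differ")
})

test_that("identical generating distributions reject at the nominal rate", {
  null_summary <- tibble::tibble(
    arm = "a", probe = paste0("TP", 1:2), mean_c = 40, sd_c = 0.5, n = 20L
  )
  hits <- vapply(1:300, function(seed) {
    a <- simulate_measurements(null_summary, seed = 2 * seed)
    b <- simulate_measurements(dplyr::mutate(null_summary, arm = "b"),
                               seed = 2 * seed + 1)
    mean(compare_arms(a, b)$significant)
  }, numeric(1))
  # 600 probe-level null comparisons in total; rate near alpha = 0.05
  # (binomial 3 sigma ~ 0.027)
  expect_lt(abs(mean(hits) - 0.05), 0.03)
})
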