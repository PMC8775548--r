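test_that("dist_spec validates parameters and round-trips through lists", {
  d <- dist_spec("lognormal10", 0.321, 0.426, unit = "ug/m3")
  expect_s3_class(d, "dist_spec")
  expect_error(dist_spec("lognormal10", 0.3, -0.1), ">= 0")
  expect_error(dist_spec("gamma", 1, 1))
  rt <- dist_from_list(dist_to_list(d))
  expect_identical(rt$family, d$family)
  expect_identical(rt$a, d$a)
  expect_identical(rt$b, d$b)
  expect_identical(rt$unit, d$unit)
})

test_that("quantile fit recovers a normal exactly from its true quantiles", {
  # quartiles of a normal are analytically mu -/+ 0.6744898 * sigma
  m <- 61.04; s <- 12.26
  fit <- fit_normal_quantiles(c(0.25, 0.5, 0.75),
                              m + s * qnorm(c(0.25, 0.5, 0.75)))
  expect_equal(fit$a, m, tolerance = 1e-12)
  expect_equal(fit$b, s, tolerance = 1e-12)
  expect_identical(fit$provenance, "fitted")

  # 5/25/50/75/95% quantiles of N(53.72, 11.08)
  p <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  fit2 <- fit_normal_quantiles(p, 53.72 + 11.08 * qnorm(p))
  expect_equal(fit2$a, 53.72, tolerance = 1e-6)
  expect_equal(fit2$b, 11.08, tolerance = 1e-6)

  # two-point system solved by hand: sigma = 1 / qnorm(0.8414)
  fit3 <- fit_normal_quantiles(c(0.5, 0.8414), c(10, 11))
  expect_equal(fit3$a, 10, tolerance = 1e-9)
  expect_equal(fit3$b, 1 / qnorm(0.8414), tolerance = 1e-9)
  expect_equal(fit3$b, 1, tolerance = 1e-3)
})

test_that("quantile fit rejects bad input and decreasing quantiles", {
  expect_error(fit_normal_quantiles(0.5, 10), "at least 2")
  expect_error(fit_normal_quantiles(c(0.5, 0.5), c(1, 2)), "distinct")
  expect_error(fit_normal_quantiles(c(0, 0.5), c(1, 2)), "strictly between")
  # clearly decreasing quantiles cannot come from any distribution
  expect_error(fit_normal_quantiles(c(0.25, 0.75), c(5, 1)), "negative")
})

test_that("lognormal10 fit matches the log10 mean/sd definition", {
  f <- fit_lognormal10(c(1, 10, 100))
  expect_equal(f$a, 1)
  expect_equal(f$b, 1)
  f0 <- fit_lognormal10(c(10, 10, 10))
  expect_equal(f0$a, 1)
  expect_equal(f0$b, 0)
  expect_error(fit_lognormal10(c(1, -2, 3)), "positive")
  expect_error(fit_lognormal10(5), "at least 2")
})

test_that("lognormal10 fit recovers generating parameters from samples", {
  truth <- dist_spec("lognormal10", 0.321, 0.426)
  x <- dist_sample(truth, 5000, seed = 101)
  f <- fit_lognormal10(as.numeric(x))
  expect_lt(abs(f$a - 0.321), 0.02)
  expect_lt(abs(f$b - 0.426), 0.02)
})

test_that("dist_mean matches the closed forms", {
  # closed form computed independently: 10^a * exp((ln10 * b)^2 / 2)
  expect_equal(dist_mean(dist_spec("lognormal10", 0.321, 0.426)),
               10^0.321 * exp((log(10) * 0.426)^2 / 2), tolerance = 1e-12)
  expect_equal(dist_mean(dist_spec("lognormal10", 0.321, 0.426)), 3.390,
               tolerance = 1e-3)
  expect_equal(dist_mean(dist_spec("lognormal10", 0.7, 0)), 10^0.7)
  expect_equal(dist_mean(dist_spec("normal", 61.04, 12.26)), 61.04)
})

test_that("analytic exceedance reproduces the published tail probabilities", {
  # benzene above its reference concentration
  expect_equal(dist_exceedance(dist_spec("lognormal10", 0.321, 0.426), 30),
               0.0033, tolerance = 0.03)
  # urinary T,T-MA above the BEI
  expect_equal(dist_exceedance(dist_spec("lognormal10", 2.102, 0.392), 500),
               0.064, tolerance = 0.005)
  # threshold at the median of a symmetric-in-log variate
  expect_equal(dist_exceedance(dist_spec("lognormal10", 2.102, 0.392),
                               10^2.102), 0.5)
  expect_equal(dist_exceedance(dist_spec("normal", 5, 2), 5), 0.5)
})

test_that("exceedance handles degenerate scale and is monotone in threshold", {
  d0 <- dist_spec("normal", 10, 0)
  expect_equal(dist_exceedance(d0, 5), 1)
  expect_equal(dist_exceedance(d0, 15), 0)
  expect_error(dist_exceedance(dist_spec("lognormal10", 0, 1), -1), "> 0")
  for (d in list(dist_spec("lognormal10", 0.321, 0.426),
                 dist_spec("normal", 61, 12))) {
    ts <- if (d$family == "lognormal10") 10^seq(-3, 3, length.out = 50)
          else seq(-20, 140, length.out = 50)
    p <- vapply(ts, function(t) dist_exceedance(d, t), numeric(1))
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("sampling is reproducible, truncated, and matches the analytic law", {
  d <- dist_spec("lognormal10", 0.321, 0.426)
  x1 <- dist_sample(d, 100, seed = 7)
  x2 <- dist_sample(d, 100, seed = 7)
  expect_identical(x1, x2)

  n <- dist_sample(dist_spec("normal", 61.04, 12.26), 10000, seed = 8,
                   truncate_positive = TRUE)
  expect_gt(min(n), 0)

  # sample mean within 3 SE of the closed-form mean
  x <- as.numeric(dist_sample(d, 10000, seed = 9))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - dist_mean(d)), 3 * se)

  # empirical exceedance agrees with the analytic tail at n = 1e5
  x <- as.numeric(dist_sample(d, 1e5, seed = 10))
  for (t in c(1, 5, 30)) {
    p <- dist_exceedance(d, t)
    expect_lt(abs(mean(x > t) - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("KS statistic matches brute force, edge cases and stats::ks.test", {
  d <- dist_spec("normal", 0, 1)
  # single observation at the median: |F_n - F| jumps to 0.5
  expect_equal(ks_statistic(0, d)$statistic, 0.5)

  # values at the k/(n+1) quantiles: D cannot exceed 1/(n+1) by more than eps
  n <- 99
  q <- qnorm(seq_len(n) / (n + 1))
  expect_lte(ks_statistic(q, d)$statistic, 1 / (n + 1) + 1e-9)

  # cross-check against the established implementation on random data
  set.seed(42)
  x <- rnorm(200, 1, 2)
  mine <- ks_statistic(x, dist_spec("normal", 1, 2))$statistic
  ref <- unname(stats::ks.test(x, "pnorm", 1, 2)$statistic)
  expect_equal(mine, ref, tolerance = 1e-12)

  # draws from the model itself pass at alpha = 0.05
  dl <- dist_spec("lognormal10", 0.321, 0.426)
  y <- as.numeric(dist_sample(dl, 5000, seed = 11))
  ks <- ks_statistic(y, dl, p_value = TRUE)
  expect_gt(ks$p_value, 0.05)
  expect_lt(ks$statistic, 1.358 / sqrt(5000))
})
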