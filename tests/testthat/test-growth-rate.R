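test_that("log-linear fit matches the closed-form OLS slope", {
  s <- make_series(c(0, 1, 2, 3), c(0, 0.5, 1.0, 1.5))
  fit <- fit_log_linear(s)
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$r_squared, 1)

  s2 <- make_series(c(0, 1, 2, 3), c(0, 0.2, 0.5, 0.8))
  expect_equal(fit_log_linear(s2)$slope, 0.27)

  flat <- make_series(c(0, 1, 2, 3), rep(0, 4))
  expect_equal(fit_log_linear(flat)$slope, 0)

  # independent oracle on noisy data: lm()
  set.seed(11)
  t <- rep(c(0, 1, 2, 3), each = 3)
  y <- 0.1 + 0.3 * t + rnorm(12, 0, 0.1)
  noisy <- make_series(t, y)
  fit3 <- fit_log_linear(noisy)
  ref <- lm(y ~ t)
  expect_equal(fit3$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit3$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit3$r_squared, summary(ref)$r.squared, tolerance = 1e-10)

  expect_error(fit_log_linear(make_series(c(1, 1, 1), c(0, 1, 2))),
               "times identical")
})

test_that("bootstrap collapses to the OLS slope on noise-free data", {
  s <- make_series(rep(c(0, 1, 2, 3), each = 3),
                   rep(c(0, 0.31, 0.62, 0.93), each = 3))
  for (m in c("paired", "residual")) {
    est <- bootstrap_rate(s, method = m, n_boot = 200, seed = 4)
    expect_equal(est$rate_mean, 0.31, tolerance = 1e-9)
    expect_lt(est$rate_se, 1e-9)
  }
})

test_that("bootstrap is reproducible for a fixed seed", {
  set.seed(99)
  t <- rep(c(0, 1, 2, 3), each = 3)
  s <- make_series(t, 0.3 * t + rnorm(12, 0, 0.08))
  for (m in c("paired", "residual")) {
    a <- bootstrap_rate(s, method = m, n_boot = 500, seed = 123)
    b <- bootstrap_rate(s, method = m, n_boot = 500, seed = 123)
    expect_identical(a$bootstrap_slopes, b$bootstrap_slopes)
    c <- bootstrap_rate(s, method = m, n_boot = 500, seed = 124)
    expect_false(identical(a$bootstrap_slopes, c$bootstrap_slopes))
  }
})

test_that("shifting all log-values moves the intercept, not the slopes", {
  set.seed(7)
  t <- rep(c(0, 1, 2, 3), each = 3)
  y <- 0.3 * t + rnorm(12, 0, 0.08)
  a <- bootstrap_rate(make_series(t, y), n_boot = 400, seed = 55)
  b <- bootstrap_rate(make_series(t, y + 2.5), n_boot = 400, seed = 55)
  expect_equal(b$bootstrap_slopes, a$bootstrap_slopes, tolerance = 1e-12)
  expect_equal(b$intercept_mean - a$intercept_mean, 2.5, tolerance = 1e-10)
})

test_that("rate estimates recover the generating rate across its range", {
  # true rate within 2 SE in at least 85% of seeded repeats
  for (r_true in c(-0.44, 0, 0.30)) {
    hits <- 0L
    n_rep <- 40L
    for (i in seq_len(n_rep)) {
      t <- rep(c(0, 1, 2, 3), times = 9)
      set.seed(6000 + i)
      y <- r_true * t + rnorm(length(t), 0, 0.08)
      est <- bootstrap_rate(make_series(t, y), n_boot = 400, seed = 7000 + i)
      if (abs(est$rate_mean - r_true) < 2 * est$rate_se) hits <- hits + 1L
    }
    expect_gte(hits / n_rep, 0.85)
  }
})

test_that("exponentiality check separates exponential from saturating growth", {
  expo <- make_series(rep(c(0, 1, 2, 3), each = 3),
                      rep(c(0, 0.3, 0.6, 0.9), each = 3))
  expect_true(check_exponential(expo)$exponential_ok)

  logi <- logistic_series(capacity_fold = 1.5)
  chk <- check_exponential(logi, r2_threshold = 0.95)
  expect_false(chk$exponential_ok)
  expect_lt(chk$r_squared, 0.95)
  expect_false(check_exponential(logi)$exponential_ok)  # default threshold too
})

test_that("flat noisy series are not rejected for low R-squared", {
  set.seed(3)
  t <- rep(c(0, 1, 2, 3), each = 9)
  y <- rnorm(length(t), 0, 0.08)   # true slope 0: R2 is uninformative
  chk <- check_exponential(make_series(t, y))
  expect_true(chk$exponential_ok)
  expect_lt(chk$r_squared, 0.5)
})

test_that("normality check responds to skewness as designed", {
  set.seed(21)
  expect_true(check_normality(rnorm(1000)))
  expect_false(check_normality(rexp(1000)))   # skewness 2
  expect_error(check_normality(rnorm(50)), "at least 100")

  # bootstrap slopes from a control-like synthetic series look Gaussian
  spec <- synthetic_spec(seed = 31)
  s <- normalize_to_t0(generate_assay(spec), 0)
  est <- bootstrap_rate(s, n_boot = 1000, seed = 32)
  expect_true(est$normality_ok)
})

test_that("per-assay rate table is seed-reproducible and honors exclude_t0", {
  spec <- synthetic_spec(concentrations = c(0, 1, 5, 20), noise_sigma = 0.05,
                         seed = 8)
  assay <- generate_assay(spec)
  r1 <- estimate_growth_rates(assay, n_boot = 200, seed = 17)
  r2 <- estimate_growth_rates(assay, n_boot = 200, seed = 17)
  expect_identical(r1, r2)
  expect_equal(r1$concentration, c(0, 1, 5, 20))

  r3 <- estimate_growth_rates(assay, n_boot = 200, seed = 17, exclude_t0 = TRUE)
  expect_false(identical(r3$rate_mean, r1$rate_mean))
  # noise-free: with or without t0, any two points give the same slope
  a0 <- generate_assay(synthetic_spec(concentrations = c(0, 1, 5, 20),
                                      noise_sigma = 0, seed = 9))
  e_all <- estimate_growth_rates(a0, n_boot = 100, seed = 1)
  e_not0 <- estimate_growth_rates(a0, n_boot = 100, seed = 1, exclude_t0 = TRUE)
  expect_equal(e_not0$rate_mean, e_all$rate_mean, tolerance = 1e-9)
})
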