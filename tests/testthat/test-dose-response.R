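oxa_doses <- c(0, 0.1, 0.2, 0.4, 0.8, 1.6, 3.13, 6.25, 12.5, 25, 50)

test_that("noise-free model data identify (A, alpha, r_inf) exactly", {
  A <- 0.85; al <- 0.06; rinf <- 0.55
  rates <- A * exp(-al * oxa_doses) - rinf
  fit <- fit_shifted_exponential(oxa_doses, rates)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, A, tolerance = 1e-6)
  expect_equal(fit$decay, al, tolerance = 1e-6)
  expect_equal(fit$floor, rinf, tolerance = 1e-6)
  expect_equal(predict_rate(fit, 0), A - rinf, tolerance = 1e-8)
})

test_that("degenerate and non-decreasing inputs are flagged, not fitted", {
  expect_false(fit_shifted_exponential(c(0, 1, 2, 5), rep(0.3, 4))$converged)
  # increasing rates: no decreasing exponential beats the flat model
  expect_false(fit_shifted_exponential(c(0, 1, 2, 5, 10),
                                       c(-0.2, -0.1, 0, 0.15, 0.3))$converged)
  expect_error(fit_shifted_exponential(c(0, 1, 2), c(0.3, 0.2, 0.1)),
               "at least 4")
  expect_error(fit_shifted_exponential(c(1, 2, 5, 10), c(0.3, 0.2, 0.1, 0)),
               "control")
})

test_that("inversion matches the closed form and its boundary", {
  fit <- structure(list(amplitude = 0.8, decay = 0.1, floor = 0.5,
                        rss = 0, converged = TRUE),
                   class = "dose_response_fit")
  expect_equal(invert_concentration(fit, 0.3), 0)           # rate at C = 0
  expect_equal(invert_concentration(fit, 0), 10 * log(1.6)) # ~ 4.7004
  expect_equal(predict_rate(fit, 10 * log(1.6)), 0, tolerance = 1e-12)
  expect_error(invert_concentration(fit, -0.5), "below asymptotic floor")
  expect_error(invert_concentration(fit, 0.35), "not reached")
  bad <- fit; bad$converged <- FALSE
  expect_error(invert_concentration(bad, 0), "non-converged")
})

test_that("inversion round-trips and is strictly decreasing in the target", {
  set.seed(19)
  for (i in 1:20) {
    A <- runif(1, 0.3, 1.5); al <- runif(1, 0.02, 0.5); rinf <- runif(1, 0.1, 1)
    fit <- structure(list(amplitude = A, decay = al, floor = rinf,
                          rss = 0, converged = TRUE),
                     class = "dose_response_fit")
    targets <- sort(runif(5, -rinf + 1e-3, A - rinf))
    cc <- vapply(targets, function(tr) invert_concentration(fit, tr), numeric(1))
    expect_equal(vapply(cc, function(x) predict_rate(fit, x), numeric(1)),
                 targets, tolerance = 1e-9)
    expect_true(all(diff(cc) < 0))   # higher target rate -> lower dose
  }
})

test_that("viability-to-rate conversion follows the exponential model", {
  expect_equal(rate_for_viability(0.30, 1, 3), 0.30)
  expect_equal(rate_for_viability(0.30, 0.5, 3), 0.30 + log(0.5) / 3)
  expect_equal(rate_for_viability(0.30, 0.5, 3) - 0.30, -0.2310, tolerance = 5e-4)
  expect_equal(rate_for_viability(0.2, 0.25, 2), 0.2 + log(0.25) / 2)
  expect_equal(rate_for_viability(0.2, 0.25, 2), -0.49315, tolerance = 1e-4)
  # unequal seeding shifts the target by log(n0_ratio)/t
  expect_equal(rate_for_viability(0.3, 0.5, 3, n0_ratio = 2),
               rate_for_viability(0.3, 1, 3) + log(0.5 * 2) / 3)
  expect_error(rate_for_viability(0.3, 0, 3), "viability")
  expect_error(rate_for_viability(0.3, 0.5, -1), "time")
})

test_that("zero rate uncertainty collapses the Monte-Carlo to the point fit", {
  A <- 0.85; al <- 0.06; rinf <- 0.55
  re <- data.frame(concentration = oxa_doses,
                   rate_mean = A * exp(-al * oxa_doses) - rinf,
                   rate_se = 0)
  idx <- monte_carlo_indices(re, n_sims = 200, seed = 2)
  fit <- fit_shifted_exponential(re$concentration, re$rate_mean)
  r0 <- re$rate_mean[1]
  expected <- c(IC50 = invert_concentration(fit, r0 + log(0.5) / 3),
                ICr0 = invert_concentration(fit, 0),
                ICrmed = invert_concentration(fit, r0 / 2))
  expect_equal(setNames(idx$mean, idx$index_name), expected, tolerance = 1e-6)
  expect_equal(idx$ci_high - idx$ci_low, rep(0, 3), tolerance = 1e-9)
  expect_equal(idx$n_failed, rep(0L, 3))
})

test_that("Monte-Carlo indices keep the ICrmed < IC50 < ICr0 ordering", {
  # holds whenever the control rate is below 2 ln 2 / t = 0.462 days^-1
  idx <- monte_carlo_indices(hct116_rates(), n_sims = 500, seed = 14)
  m <- setNames(idx$mean, idx$index_name)
  expect_lt(m["ICrmed"], m["IC50"])
  expect_lt(m["IC50"], m["ICr0"])
  expect_true(all(idx$valid))
  expect_true(all(idx$ci_low <= idx$mean & idx$mean <= idx$ci_high))
})

test_that("indices are seed-reproducible and expose per-draw diagnostics", {
  re <- hct116_rates()
  a <- monte_carlo_indices(re, n_sims = 300, seed = 5, keep_draws = TRUE)
  b <- monte_carlo_indices(re, n_sims = 300, seed = 5)
  expect_equal(a$mean, b$mean)
  expect_identical(a$mc_values, b$mc_values)
  draws <- attr(a, "draws")
  expect_equal(nrow(draws), 300)
  expect_true(all(c("amplitude", "decay", "floor", "converged") %in% names(draws)))
})

test_that("overwhelming rate uncertainty flags the estimates invalid", {
  re <- data.frame(concentration = c(0, 1, 2, 5, 10),
                   rate_mean = c(0.3, 0.25, 0.2, 0.05, -0.2),
                   rate_se = 0.5)
  warns <- testthat::capture_warnings(
    idx <- monte_carlo_indices(re, n_sims = 200, seed = 3))
  expect_true(any(grepl("flagged invalid", warns)))
  expect_true(any(!idx$valid))
  expect_true(any(idx$n_failed / idx$n_sims >= 0.2))
})

test_that("reduced endpoints reproduce full-design indices on exact data", {
  spec <- synthetic_spec(noise_sigma = 0, seed = 5)
  assay <- generate_assay(spec)
  i_all <- compute_indices(assay, n_boot = 100, n_sims = 100, seed = 11)
  i_red <- reduced_endpoint_indices(assay, c(0, 72), n_boot = 100,
                                    n_sims = 100, seed = 13)
  expect_equal(i_red$mean, i_all$mean, tolerance = 1e-8)
  expect_equal(i_all$mean,
               unname(unlist(ground_truth_indices(spec))), tolerance = 1e-6)
  expect_error(reduced_endpoint_indices(assay, 24), "include t = 0")
  expect_error(reduced_endpoint_indices(assay, c(0, 36)), "not observed")
})

test_that("dropping interior time points widens the index intervals", {
  wider <- 0L
  n_rep <- 12L
  for (i in seq_len(n_rep)) {
    assay <- generate_assay(synthetic_spec(noise_sigma = 0.08, seed = 400 + i))
    i_all <- compute_indices(assay, n_boot = 500, n_sims = 500, seed = 600 + i,
                             indices = "ICr0")
    i_red <- reduced_endpoint_indices(assay, c(0, 72), n_boot = 500,
                                      n_sims = 500, seed = 600 + i,
                                      indices = "ICr0")
    if ((i_red$ci_high - i_red$ci_low) >= (i_all$ci_high - i_all$ci_low)) {
      wider <- wider + 1L
    }
  }
  expect_gt(wider / n_rep, 0.5)
})
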