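#' Log-linear fit of a normalized series
#'
#' Ordinary least squares of log-normalized absorbance against time; the
#' slope is the effective growth rate (days^-1) of the Malthusian model
#' N(t) = N0 * exp(r t).
#'
#' @param series a `normalized_series` from [normalize_to_t0()].
#' @return list with `slope` (days^-1), `intercept`, `r_squared`.
#' @export
fit_log_linear <- function(series) {
  x <- series$times
  y <- series$log_values
  if (length(unique(x)) < 2) stop("all times identical; slope undefined", call. = FALSE)
  if (length(y) < 3) stop("need at least 3 observations", call. = FALSE)
  ols_slope(x, y)
}

# Closed-form simple OLS; returns slope, intercept, r_squared. A constant
# response (zero total and residual sum of squares) is a perfect flat fit.
ols_slope <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  sst <- sum((y - yb)^2)
  ssr <- sum((y - intercept - slope * x)^2)
  r2 <- if (sst == 0) 1 else 1 - ssr / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Bootstrap the effective growth rate of one series
#'
#' Refits the log-linear regression on `n_boot` bootstrap resamples. Two
#' resampling schemes are available: `"paired"` (empirical/nonparametric:
#' resample (time, log-value) pairs with replacement; a resample with fewer
#' than two distinct times is redrawn, up to 10 * `n_boot` redraws in total)
#' and `"residual"` (fixed design: resample residuals of the point fit and
#' add them back to the fitted values). The rate estimate is the mean of the
#' bootstrap slope distribution, its standard error the bootstrap standard
#' deviation, and the default confidence interval the normal approximation
#' rbar +/- z SE with z the two-sided standard-normal quantile.
#'
#' @param series a `normalized_series`.
#' @param method `"paired"` (default) or `"residual"`.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; the whole resampling stream is reproducible.
#' @param conf_level two-sided confidence level (default 0.90, for which
#'   `z = 1.6449`).
#' @param ci_type `"normal"` (default) or `"percentile"`.
#' @param r2_threshold passed to [check_exponential()].
#' @return a `growth_rate_estimate`: list with `concentration`, `rate_mean`,
#'   `rate_se`, `ci_low`, `ci_high`, `bootstrap_slopes`, `intercept_mean`,
#'   `r_squared`, `exponential_ok`, `normality_ok`, plus the settings used.
#' @export
bootstrap_rate <- function(series, method = c("paired", "residual"),
                           n_boot = 1000, seed = 1, conf_level = 0.90,
                           ci_type = c("normal", "percentile"),
                           r2_threshold = 0.90) {
  method <- match.arg(method)
  ci_type <- match.arg(ci_type)
  stopifnot(n_boot >= 1)
  point <- fit_log_linear(series)
  x <- series$times
  y <- series$log_values
  n <- length(x)

  set.seed(as.integer(seed))
  if (method == "paired") {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    redraws <- 0L
    repeat {
      tmat <- matrix(x[idx], nrow = n_boot)
      degenerate <- which(matrixStats_rowMax(tmat) == matrixStats_rowMin(tmat))
      if (length(degenerate) == 0) break
      redraws <- redraws + length(degenerate)
      if (redraws > 10L * n_boot) {
        stop("could not draw non-degenerate bootstrap samples after ",
             10L * n_boot, " redraws", call. = FALSE)
      }
      idx[degenerate, ] <- sample.int(n, n * length(degenerate), replace = TRUE)
    }
    xm <- matrix(x[idx], nrow = n_boot)
    ym <- matrix(y[idx], nrow = n_boot)
  } else {
    fitted <- point$intercept + point$slope * x
    resid <- y - fitted
    eb <- matrix(sample(resid, n * n_boot, replace = TRUE), nrow = n_boot)
    xm <- matrix(x, nrow = n_boot, ncol = n, byrow = TRUE)
    ym <- matrix(fitted, nrow = n_boot, ncol = n, byrow = TRUE) + eb
  }
  sl <- row_ols(xm, ym)

  rate_mean <- mean(sl$slope)
  rate_se <- sd(sl$slope)
  if (ci_type == "normal") {
    z <- z_for_conf(conf_level)
    ci <- c(rate_mean - z * rate_se, rate_mean + z * rate_se)
  } else {
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(sl$slope, c(a, 1 - a)))
  }
  expo <- check_exponential(series, r2_threshold = r2_threshold)
  structure(list(
    concentration = series$concentration,
    rate_mean = rate_mean,
    rate_se = rate_se,
    ci_low = ci[1], ci_high = ci[2],
    bootstrap_slopes = sl$slope,
    intercept_mean = mean(sl$intercept),
    r_squared = point$r_squared,
    exponential_ok = expo$exponential_ok,
    normality_ok = if (n_boot >= 100) check_normality(sl$slope) else NA,
    n_boot = n_boot, method = method, conf_level = conf_level,
    ci_type = ci_type, seed = seed
  ), class = "growth_rate_estimate")
}

# Row-wise simple OLS over bootstrap resamples (one row = one resample).
row_ols <- function(xm, ym) {
  n <- ncol(xm)
  xb <- rowMeans(xm)
  yb <- rowMeans(ym)
  sxy <- rowSums(xm * ym) - n * xb * yb
  sxx <- rowSums(xm * xm) - n * xb * xb
  slope <- sxy / sxx
  list(slope = slope, intercept = yb - slope * xb)
}

matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))
matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<growth_rate_estimate> C = %g: r = %.4f +/- %.4f days^-1 [%.4f, %.4f] (%d%% %s CI, %s bootstrap, R2 = %.3f)\n",
    x$concentration, x$rate_mean, x$rate_se, x$ci_low, x$ci_high,
    round(100 * x$conf_level), x$ci_type, x$method, x$r_squared))
  invisible(x)
}

#' Verify that a series is consistent with exponential growth
#'
#' Exponential growth appears as a straight line in log space, so the check
#' is the R^2 of the log-linear fit. R^2 is uninformative when the true
#' slope is near zero (a flat series has no trend to explain), so when the
#' total log-change over the observation window is small
#' (`|slope| * (t_max - t_min) <= flatness_floor`) the series is judged by
#' the residual spread around the fit instead.
#'
#' @param series a `normalized_series`.
#' @param r2_threshold minimum R^2 for a growing/declining series
#'   (default 0.90).
#' @param flatness_floor total log-change below which the R^2 rule is
#'   replaced by the residual rule (default 0.1).
#' @param resid_sd_max maximal residual standard deviation (log units) for a
#'   flat series to pass (default 0.25).
#' @return list with `exponential_ok` and `r_squared`.
#' @export
check_exponential <- function(series, r2_threshold = 0.90,
                              flatness_floor = 0.1, resid_sd_max = 0.25) {
  fit <- fit_log_linear(series)
  span <- abs(fit$slope) * diff(range(series$times))
  if (span > flatness_floor) {
    ok <- fit$r_squared >= r2_threshold
  } else {
    resid <- series$log_values - fit$intercept - fit$slope * series$times
    ok <- sd(resid) <= resid_sd_max
  }
  list(exponential_ok = ok, r_squared = fit$r_squared)
}

#' Check approximate normality of a bootstrap slope distribution
#'
#' Moment-based rule: normal enough when |skewness| < 0.5 and
#' |excess kurtosis| < 1. A formal test is deliberately not used: with 1000
#' bootstrap replicates even trivial deviations reach significance.
#'
#' @param bootstrap_slopes numeric vector, length >= 100.
#' @return logical.
#' @export
check_normality <- function(bootstrap_slopes) {
  if (length(bootstrap_slopes) < 100) {
    stop("need at least 100 bootstrap slopes to judge normality", call. = FALSE)
  }
  abs(moment_skewness(bootstrap_slopes)) < 0.5 &&
    abs(moment_excess_kurtosis(bootstrap_slopes)) < 1
}

#' Estimate effective growth rates for every concentration of an assay
#'
#' Runs [normalize_to_t0()] and [bootstrap_rate()] per concentration.
#' Per-concentration seeds are derived deterministically from `seed`, so a
#' master seed reproduces the full table.
#'
#' @inheritParams bootstrap_rate
#' @param assay an [assay_table].
#' @param exclude_t0 drop the seeding-time points from the fits (the
#'   alternative reading of the fitting window); default `FALSE`.
#' @return tibble with one row per concentration: `concentration`,
#'   `rate_mean`, `rate_se`, `ci_low`, `ci_high`, `r_squared`,
#'   `exponential_ok`, `normality_ok`, and list-column `bootstrap_slopes`.
#' @export
estimate_growth_rates <- function(assay, method = c("paired", "residual"),
                                  n_boot = 1000, seed = 1, conf_level = 0.90,
                                  ci_type = c("normal", "percentile"),
                                  r2_threshold = 0.90, exclude_t0 = FALSE) {
  method <- match.arg(method)
  ci_type <- match.arg(ci_type)
  concs <- assay_concentrations(assay)
  subseeds <- derive_subseeds(seed, length(concs))
  rows <- lapply(seq_along(concs), function(i) {
    series <- normalize_to_t0(assay, concs[i])
    if (exclude_t0) series <- drop_t0(series)
    est <- bootstrap_rate(series, method = method, n_boot = n_boot,
                          seed = subseeds[i], conf_level = conf_level,
                          ci_type = ci_type, r2_threshold = r2_threshold)
    tibble::tibble(
      concentration = est$concentration,
      rate_mean = est$rate_mean, rate_se = est$rate_se,
      ci_low = est$ci_low, ci_high = est$ci_high,
      r_squared = est$r_squared,
      exponential_ok = est$exponential_ok,
      normality_ok = est$normality_ok,
      bootstrap_slopes = list(est$bootstrap_slopes)
    )
  })
  dplyr::bind_rows(rows)
}
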