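#' Fit the shifted-exponential dose-response model
#'
#' Fits `r(C) = A * exp(-alpha * C) - r_inf` to per-concentration effective
#' growth rates by unweighted nonlinear least squares
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]). `A` (amplitude, days^-1)
#' and `alpha` (decay, per concentration unit) are the scale and steepness
#' of the decline; `r_inf` is the magnitude of the negative growth-rate
#' plateau reached at high dose. The rate at C = 0 is `A - r_inf`, and the
#' predicted rate is strictly decreasing in C whenever `A, alpha > 0`.
#'
#' Starting values: `r_inf` from the most negative observed rate plus a
#' spread-proportional margin; `A` anchored to the control rate; `alpha`
#' from an OLS fit of `log(rate + r_inf0)` against C (the semilog
#' linearization of the model), restricted to points where the shifted rate
#' is positive. `r_inf` is bounded below by `-min(rates) + 1e-6` so the
#' log in the inversion stays defined at every observed rate.
#'
#' @param concentrations non-negative concentrations; at least 4 distinct
#'   values including 0.
#' @param rates effective growth rates (days^-1), one per concentration.
#' @return a `dose_response_fit`: list with `amplitude`, `decay`, `floor`
#'   (r_inf), `rss`, `converged`. `converged` is `TRUE` only when the
#'   optimizer succeeded, the parameter invariants hold, and the model beats
#'   a flat (constant-rate) fit.
#' @export
fit_shifted_exponential <- function(concentrations, rates) {
  stopifnot(length(concentrations) == length(rates))
  if (length(unique(concentrations)) < 4) {
    stop("need at least 4 distinct concentrations to fit the model",
         call. = FALSE)
  }
  if (!any(concentrations == 0)) {
    stop("dose-response fit requires the zero-concentration control",
         call. = FALSE)
  }
  flat_rss <- sum((rates - mean(rates))^2)
  failed <- structure(list(amplitude = NA_real_, decay = NA_real_,
                           floor = NA_real_, rss = flat_rss,
                           converged = FALSE, n = length(rates)),
                      class = "dose_response_fit")
  if (flat_rss == 0) return(failed)  # constant rates: alpha unidentifiable

  spread <- diff(range(rates))
  floor0 <- max(-min(rates), 1e-3) + 0.1 * spread
  amp0 <- rates[concentrations == 0][1] + floor0
  shifted <- rates + floor0
  pos <- shifted > 0
  alpha0 <- NA_real_
  if (sum(pos) >= 2 && length(unique(concentrations[pos])) >= 2) {
    alpha0 <- -ols_slope(concentrations[pos], log(shifted[pos]))$slope
  }
  if (!is.finite(alpha0) || alpha0 <= 0) {
    alpha0 <- 1 / max(max(concentrations), 1)
  }
  dat <- data.frame(C = concentrations, r = rates)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ A * exp(-alpha * C) - rinf, data = dat,
      start = list(A = amp0, alpha = alpha0, rinf = floor0),
      lower = c(1e-8, 1e-8, -min(rates) + 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  p <- coef(fit)
  rss <- sum(residuals(fit)^2)
  ok <- is.finite(p[["A"]]) && is.finite(p[["alpha"]]) && is.finite(p[["rinf"]]) &&
    p[["A"]] > 0 && p[["alpha"]] > 0 && rss < flat_rss
  structure(list(amplitude = unname(p[["A"]]), decay = unname(p[["alpha"]]),
                 floor = unname(p[["rinf"]]), rss = rss, converged = ok,
                 n = length(rates)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> r(C) = %.4g * exp(-%.4g C) - %.4g  (rss %.4g, %s)\n",
    x$amplitude, x$decay, x$floor, x$rss,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Predicted effective growth rate at a concentration
#'
#' @param fit a `dose_response_fit`.
#' @param concentration non-negative concentration(s).
#' @return predicted rate(s), days^-1.
#' @export
predict_rate <- function(fit, concentration) {
  fit$amplitude * exp(-fit$decay * concentration) - fit$floor
}

#' Invert the dose-response model: concentration for a target growth rate
#'
#' Solves `r(C) = target_rate` for C:
#' `C(r) = -1/alpha * log((r + r_inf) / A)`.
#'
#' @param fit a converged `dose_response_fit`.
#' @param target_rate desired effective growth rate (days^-1); must lie in
#'   `(-r_inf, A - r_inf]` — above the high-dose floor and no higher than
#'   the control rate (equality gives C = 0).
#' @return the concentration, a non-negative scalar.
#' @export
invert_concentration <- function(fit, target_rate) {
  if (!isTRUE(fit$converged)) {
    stop("cannot invert a non-converged dose-response fit", call. = FALSE)
  }
  if (target_rate <= -fit$floor) {
    stop("rate below asymptotic floor, concentration undefined", call. = FALSE)
  }
  top <- fit$amplitude - fit$floor
  if (target_rate > top) {
    stop("rate not reached by any positive dose", call. = FALSE)
  }
  -1 / fit$decay * log((target_rate + fit$floor) / fit$amplitude)
}

# Vectorized, non-throwing inversion used inside the Monte-Carlo loop:
# out-of-domain targets give NA (a failed draw), never an error.
invert_safe <- function(amplitude, decay, floor_, target_rate) {
  shifted <- target_rate + floor_
  out <- rep(NA_real_, length(shifted))
  ok <- !is.na(shifted) & shifted > 0 & target_rate <= amplitude - floor_
  out[ok] <- -1 / decay[ok] * log(shifted[ok] / amplitude[ok])
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

#' Growth rate corresponding to a given endpoint viability
#'
#' From the exponential-growth viability relation
#' `V(t) = (N0C/N0*) * exp((rC - r0) t)`:
#' `rC = r0 + log(V * n0_ratio) / t`. With V = 0.5, t = 3 days and equal
#' seeding (`n0_ratio = 1`) this is `r0 - 0.2310`, the rate at which a
#' culture shows 50% viability on day 3.
#'
#' @param r0 control (untreated) effective growth rate, days^-1.
#' @param viability target viability as a fraction in (0, 1].
#' @param t endpoint time, days (> 0).
#' @param n0_ratio ratio of treated to control initial populations
#'   (default 1, equal seeding).
#' @return the target effective growth rate, days^-1.
#' @export
rate_for_viability <- function(r0, viability, t, n0_ratio = 1) {
  if (any(viability <= 0)) stop("viability must be positive", call. = FALSE)
  if (any(t <= 0)) stop("endpoint time must be positive", call. = FALSE)
  if (any(n0_ratio <= 0)) stop("n0_ratio must be positive", call. = FALSE)
  r0 + log(viability * n0_ratio) / t
}

#' Monte-Carlo estimation of the potency indices
#'
#' The mixed bootstrap / Monte-Carlo scheme: concentrations are held fixed;
#' in each of `n_sims` draws every concentration's rate is sampled from
#' `Normal(rate_mean, rate_se)`, the shifted-exponential model is refitted
#' to the drawn rates, and the fit is inverted at the draw's target rate:
#'
#' * `IC50`  — target `r0* + log(viability * n0_ratio) / duration`
#'   (defaults: V = 0.5, t = 3 days, equal seeding, i.e. `r0* - 0.2310`),
#' * `ICr0`  — target 0 (cytostasis),
#' * `ICrmed` — target `r0* / 2` (half the control rate),
#'
#' where `r0*` is the draw's sampled control rate, so control-rate
#' uncertainty propagates into every index. The per-draw fit is unweighted:
#' uncertainty enters the scheme only through the sampled rates. Draws whose
#' fit fails to converge or whose target falls outside the fitted model's
#' range are dropped and counted in `n_failed`; they are never resampled
#' (resampling would bias toward easy fits). An index with more than 20%
#' failed draws is flagged invalid.
#'
#' @param rate_estimates data frame with columns `concentration`,
#'   `rate_mean`, `rate_se` — e.g. the output of [estimate_growth_rates()],
#'   or a table of previously published rates. At least 4 concentrations
#'   including 0.
#' @param indices subset of `c("IC50", "ICr0", "ICrmed")`.
#' @param n_sims number of Monte-Carlo draws (1000-5000 recommended).
#' @param seed integer seed.
#' @param conf_level confidence level for the index CIs (default 0.90).
#' @param viability,duration,n0_ratio the viability convention defining the
#'   IC50 target rate.
#' @param ci_type `"percentile"` (default) or `"normal"`.
#' @param keep_draws attach the per-draw parameter table
#'   (`attr(result, "draws")`: sim, amplitude, decay, floor, converged) for
#'   diagnostics.
#' @return tibble with one row per index: `index_name`, `target_rate` (the
#'   point-estimate target), `mean`, `ci_low`, `ci_high`, `n_sims`,
#'   `n_failed`, `valid`, and list-column `mc_values` (the successful
#'   draws' concentrations).
#' @export
monte_carlo_indices <- function(rate_estimates,
                                indices = c("IC50", "ICr0", "ICrmed"),
                                n_sims = 1000, seed = 1, conf_level = 0.90,
                                viability = 0.5, duration = 3, n0_ratio = 1,
                                ci_type = c("percentile", "normal"),
                                keep_draws = FALSE) {
  ci_type <- match.arg(ci_type)
  indices <- match.arg(indices, several.ok = TRUE)
  stopifnot(n_sims >= 1)
  re <- tibble::as_tibble(rate_estimates)
  req <- c("concentration", "rate_mean", "rate_se")
  if (!all(req %in% names(re))) {
    stop("rate_estimates needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(re$concentration)) < 4 || !any(re$concentration == 0)) {
    stop("need rate estimates at >= 4 concentrations including the control",
         call. = FALSE)
  }
  re <- re[order(re$concentration), ]
  i0 <- which(re$concentration == 0)[1]

  set.seed(as.integer(seed))
  n_conc <- nrow(re)
  draws <- matrix(rnorm(n_sims * n_conc, mean = rep(re$rate_mean, each = n_sims),
                        sd = rep(re$rate_se, each = n_sims)),
                  nrow = n_sims)

  par_tab <- matrix(NA_real_, n_sims, 3,
                    dimnames = list(NULL, c("amplitude", "decay", "floor")))
  conv <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    f <- suppressWarnings(fit_shifted_exponential(re$concentration, draws[s, ]))
    conv[s] <- f$converged
    if (f$converged) par_tab[s, ] <- c(f$amplitude, f$decay, f$floor)
  }
  r0_draw <- draws[, i0]

  target_fun <- list(
    IC50 = function(r0) rate_for_viability(r0, viability, duration, n0_ratio),
    ICr0 = function(r0) rep(0, length(r0)),
    ICrmed = function(r0) r0 / 2
  )
  target_rule <- c(
    IC50 = sprintf("r0 + ln(%g * %g)/%g", viability, n0_ratio, duration),
    ICr0 = "0", ICrmed = "r0 / 2")

  point_fit <- fit_shifted_exponential(re$concentration, re$rate_mean)
  r0_point <- re$rate_mean[i0]

  rows <- lapply(indices, function(ix) {
    tr <- target_fun[[ix]](r0_draw)
    vals <- invert_safe(par_tab[, "amplitude"], par_tab[, "decay"],
                        par_tab[, "floor"], tr)
    vals[!conv] <- NA_real_
    ok <- !is.na(vals)
    n_failed <- sum(!ok)
    mc <- vals[ok]
    if (length(mc) == 0) {
      m <- NA_real_; ci <- c(NA_real_, NA_real_)
    } else if (ci_type == "percentile") {
      m <- mean(mc)
      a <- (1 - conf_level) / 2
      ci <- unname(quantile(mc, c(a, 1 - a)))
    } else {
      m <- mean(mc)
      z <- z_for_conf(conf_level)
      ci <- c(m - z * sd(mc), m + z * sd(mc))
    }
    valid <- n_failed / n_sims < 0.2 && length(mc) > 0
    if (!valid) {
      warning(sprintf("%s: %d/%d Monte-Carlo draws failed; estimate flagged invalid",
                      ix, n_failed, n_sims), call. = FALSE)
    }
    tibble::tibble(
      index_name = ix,
      target_rate_rule = unname(target_rule[ix]),
      target_rate = target_fun[[ix]](r0_point)[1],
      mean = m, ci_low = ci[1], ci_high = ci[2],
      n_sims = n_sims, n_failed = n_failed, valid = valid,
      mc_values = list(mc))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "point_fit") <- point_fit
  attr(out, "conf_level") <- conf_level
  if (keep_draws) {
    attr(out, "draws") <- tibble::tibble(
      sim = seq_len(n_sims),
      amplitude = par_tab[, "amplitude"], decay = par_tab[, "decay"],
      floor = par_tab[, "floor"], converged = conv)
  }
  out
}

#' Full pipeline: assay to potency indices
#'
#' Convenience wrapper: [estimate_growth_rates()] followed by
#' [monte_carlo_indices()]. The growth-rate and Monte-Carlo stages take
#' independent sub-seeds derived from `seed`.
#'
#' @inheritParams estimate_growth_rates
#' @inheritParams monte_carlo_indices
#' @param assay an [assay_table].
#' @return the index tibble of [monte_carlo_indices()], with the rates table
#'   attached as `attr(, "rates")`.
#' @export
compute_indices <- function(assay, indices = c("IC50", "ICr0", "ICrmed"),
                            method = c("paired", "residual"),
                            n_boot = 1000, n_sims = 1000, seed = 1,
                            conf_level = 0.90, viability = 0.5, duration = 3,
                            n0_ratio = 1, exclude_t0 = FALSE,
                            r2_threshold = 0.90, keep_draws = FALSE) {
  seeds <- derive_subseeds(seed, 2)
  rates <- estimate_growth_rates(assay, method = method, n_boot = n_boot,
                                 seed = seeds[1], conf_level = conf_level,
                                 r2_threshold = r2_threshold,
                                 exclude_t0 = exclude_t0)
  out <- monte_carlo_indices(rates, indices = indices, n_sims = n_sims,
                             seed = seeds[2], conf_level = conf_level,
                             viability = viability, duration = duration,
                             n0_ratio = n0_ratio, keep_draws = keep_draws)
  attr(out, "rates") <- rates
  out
}

#' Potency indices from a reduced set of time points
#'
#' Re-runs the whole pipeline using only the chosen endpoints (e.g. seeding
#' time and 72 h), mirroring the reduced-input variant of the assay design.
#' With only two time points the growth rate comes from a two-point fit per
#' replicate set, which for exponential data is exact and for noisy data
#' simply wider in uncertainty.
#'
#' @inheritParams compute_indices
#' @param endpoints time points to keep, in `endpoint_unit`; must be observed
#'   in the assay, include 0, and contain at least one later time.
#' @param endpoint_unit `"hours"` (default) or `"days"`.
#' @return as [compute_indices()].
#' @export
reduced_endpoint_indices <- function(assay, endpoints,
                                     endpoint_unit = c("hours", "days"), ...) {
  endpoint_unit <- match.arg(endpoint_unit)
  keep <- to_days(endpoints, endpoint_unit)
  compute_indices(filter_endpoints(assay, keep), ...)
}
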