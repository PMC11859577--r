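#' Build and validate a pipeline run configuration
#'
#' Shared configuration for the command-style entry points [run_rates()],
#' [run_indices()] and [run_viability()]. Values can come from a YAML file
#' (`config_file`) with individual arguments overriding it (flags win).
#'
#' @param input path of the input assay CSV (long or wide dialect).
#' @param dialect `"long"` or `"wide"`.
#' @param layout,times wide-dialect layout CSV and per-file time points.
#' @param time_unit unit of input times, `"hours"` (default) or `"days"`.
#' @param method bootstrap method, `"paired"` or `"residual"`.
#' @param n_boot bootstrap resamples per concentration (>= 100).
#' @param n_sims Monte-Carlo draws for the indices (>= 100).
#' @param conf_level confidence level in (0, 1).
#' @param viability,duration,n0_ratio IC50 target-rate convention
#'   (defaults: 50% viability at 3 days, equal seeding).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (created if absent).
#' @param force proceed past exponentiality-check failures instead of
#'   erroring.
#' @param rates_csv optional CSV of precomputed rates (columns
#'   `concentration`, `rate_mean` or `rate`, `rate_se` or `se`) that
#'   bypasses the growth-rate stage of [run_indices()].
#' @param endpoints optional subset of time points (hours) to use.
#' @param exclude_t0 drop seeding-time points from the growth-rate fits.
#' @param r2_threshold exponentiality-check threshold.
#' @param config_file optional YAML file holding any of the above.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input = NULL, dialect = "long", layout = NULL,
                       times = NULL, time_unit = "hours",
                       method = "paired", n_boot = 1000, n_sims = 1000,
                       conf_level = 0.90, viability = 0.5, duration = 3,
                       n0_ratio = 1, seed = 1, out_dir = ".", force = FALSE,
                       rates_csv = NULL, endpoints = NULL,
                       exclude_t0 = FALSE, r2_threshold = 0.90,
                       config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    supplied <- names(match.call())[-1]
    for (k in setdiff(names(file_cfg), supplied)) cfg[[k]] <- file_cfg[[k]]
  }
  cfg$dialect <- match.arg(cfg$dialect, c("long", "wide"))
  cfg$time_unit <- match.arg(cfg$time_unit, c("hours", "days"))
  cfg$method <- match.arg(cfg$method, c("paired", "residual"))
  if (cfg$n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (cfg$n_sims < 100) stop("n_sims must be >= 100", call. = FALSE)
  if (cfg$conf_level <= 0 || cfg$conf_level >= 1) {
    stop("conf_level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (cfg$viability <= 0 || cfg$duration <= 0 || cfg$n0_ratio <= 0) {
    stop("viability, duration and n0_ratio must be positive", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

read_config_assay <- function(config) {
  if (is.null(config$input)) stop("config has no input file", call. = FALSE)
  assay <- read_assay_csv(config$input, dialect = config$dialect,
                          layout = config$layout, times = config$times,
                          time_unit = config$time_unit)
  if (!is.null(config$endpoints)) {
    assay <- filter_endpoints(assay, to_days(config$endpoints, "hours"))
  }
  assay
}

write_manifest <- function(config, out_dir, command, inputs) {
  checksums <- if (length(inputs) > 0) {
    as.list(tools::md5sum(unlist(inputs)))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    package = "growthIC",
    version = as.character(utils::packageVersion("growthIC")),
    config = unclass(config),
    input_md5 = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

# Escalates exponentiality-flag failures to an error unless force is set.
enforce_exponential <- function(rates, force) {
  bad <- rates$concentration[!rates$exponential_ok]
  if (length(bad) > 0 && !force) {
    stop("data fail the exponential-growth check at concentration(s): ",
         paste(bad, collapse = ", "),
         " (rerun with force = TRUE to proceed anyway)", call. = FALSE)
  }
  if (length(bad) > 0) {
    message("warning: proceeding past exponentiality failures at: ",
            paste(bad, collapse = ", "))
  }
  invisible(rates)
}

#' Run the growth-rate stage and write the rates table
#'
#' Writes `rates.csv` (one row per concentration: the layout of a
#' per-concentration effective-growth-rate table), `rates.json`, and
#' `manifest.json` to `out_dir`. Errors if any concentration fails the
#' exponential-growth check and `force` is not set.
#'
#' @param config a [run_config()].
#' @return the rates tibble, invisibly.
#' @export
run_rates <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- read_config_assay(config)
  rates <- estimate_growth_rates(
    assay, method = config$method, n_boot = config$n_boot, seed = config$seed,
    conf_level = config$conf_level, r2_threshold = config$r2_threshold,
    exclude_t0 = config$exclude_t0)
  out <- rates[, setdiff(names(rates), "bootstrap_slopes")]
  readr::write_csv(out, file.path(config$out_dir, "rates.csv"))
  jsonlite::write_json(out, file.path(config$out_dir, "rates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, config$out_dir, "rates",
                 c(config$input, config$layout))
  message(sprintf("rates: %d concentrations, R2 %.3f-%.3f, %d exponentiality failure(s)",
                  nrow(out), min(out$r_squared), max(out$r_squared),
                  sum(!out$exponential_ok)))
  enforce_exponential(rates, config$force)
  invisible(rates)
}

#' Run the full index pipeline and write the indices tables
#'
#' Either computes growth rates from `config$input` or takes them from
#' `config$rates_csv`, then runs the Monte-Carlo index estimation. Writes
#' `indices.csv`, `indices.json`, the per-draw parameter dump `draws.csv`,
#' and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return the index tibble, invisibly.
#' @export
run_indices <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$rates_csv)) {
    rates <- readr::read_csv(config$rates_csv, show_col_types = FALSE,
                             progress = FALSE)
    if ("rate" %in% names(rates) && !"rate_mean" %in% names(rates)) {
      rates$rate_mean <- rates$rate
    }
    if ("se" %in% names(rates) && !"rate_se" %in% names(rates)) {
      rates$rate_se <- rates$se
    }
    seeds <- derive_subseeds(config$seed, 2)
    idx <- monte_carlo_indices(
      rates, n_sims = config$n_sims, seed = seeds[2],
      conf_level = config$conf_level, viability = config$viability,
      duration = config$duration, n0_ratio = config$n0_ratio,
      keep_draws = TRUE)
  } else {
    assay <- read_config_assay(config)
    idx <- compute_indices(
      assay, method = config$method, n_boot = config$n_boot,
      n_sims = config$n_sims, seed = config$seed,
      conf_level = config$conf_level, viability = config$viability,
      duration = config$duration, n0_ratio = config$n0_ratio,
      exclude_t0 = config$exclude_t0, r2_threshold = config$r2_threshold,
      keep_draws = TRUE)
    enforce_exponential(attr(idx, "rates"), config$force)
  }
  out <- idx[, c("index_name", "target_rate_rule", "target_rate", "mean",
                 "ci_low", "ci_high", "n_sims", "n_failed", "valid")]
  readr::write_csv(out, file.path(config$out_dir, "indices.csv"))
  jsonlite::write_json(out, file.path(config$out_dir, "indices.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(attr(idx, "draws"), file.path(config$out_dir, "draws.csv"))
  write_manifest(config, config$out_dir, "indices",
                 c(config$input, config$layout, config$rates_csv))
  message(paste(sprintf("%s = %.3g [%.3g, %.3g] (%d failed draws)",
                        out$index_name, out$mean, out$ci_low, out$ci_high,
                        out$n_failed), collapse = "; "))
  invisible(idx)
}

#' Run the conventional viability baseline and write its tables
#'
#' Computes same-time-control viability at each positive observed time
#' point, fits the 4PL sigmoid per time point, and writes `viability.csv`,
#' `four_pl.json` and `manifest.json`.
#'
#' @param config a [run_config()].
#' @return tibble of per-time 4PL summaries, invisibly.
#' @export
run_viability <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- read_config_assay(config)
  times <- setdiff(sort(unique(assay$time)), 0)
  via <- dplyr::bind_rows(lapply(times, function(t) compute_viability(assay, t)))
  readr::write_csv(via, file.path(config$out_dir, "viability.csv"))
  fits <- lapply(times, function(t) {
    f <- fit_four_pl(via[via$time == t, ])
    c(list(time = t), unclass(f))
  })
  jsonlite::write_json(fits, file.path(config$out_dir, "four_pl.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, config$out_dir, "viability",
                 c(config$input, config$layout))
  summary <- dplyr::bind_rows(lapply(fits, tibble::as_tibble))
  message(paste(sprintf("t = %g d: 4PL IC50 %.4g (%s)", summary$time,
                        summary$ic50,
                        ifelse(summary$converged, "converged", "not converged")),
                collapse = "; "))
  invisible(summary)
}

#' Generate a synthetic assay from a spec file and write it out
#'
#' Writes `assay.csv` (long dialect), `ground_truth.json` (the generating
#' parameters, true rates and analytic indices) and `manifest.json`.
#'
#' @param spec_file JSON or YAML file accepted by [read_synthetic_spec()],
#'   or a `synthetic_spec` object.
#' @param out_dir output directory.
#' @return the generated [assay_table], invisibly.
#' @export
run_simulate <- function(spec_file, out_dir = ".") {
  spec <- if (inherits(spec_file, "synthetic_spec")) spec_file
          else read_synthetic_spec(spec_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assay <- generate_assay(spec)
  write_assay_csv(assay, file.path(out_dir, "assay.csv"))
  truth <- list(
    spec = unclass(spec),
    true_rates = data.frame(concentration = spec$concentrations,
                            rate = true_rate(spec, spec$concentrations)),
    indices = tryCatch(ground_truth_indices(spec), error = function(e) NULL))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  cfg <- if (inherits(spec_file, "character")) spec_file else character(0)
  manifest <- list(command = "simulate", package = "growthIC",
                   version = as.character(utils::packageVersion("growthIC")),
                   config = unclass(spec),
                   input_md5 = if (length(cfg)) as.list(tools::md5sum(cfg)) else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(assay)
}
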