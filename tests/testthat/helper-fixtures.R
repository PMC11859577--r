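# Fixtures are built in code; nothing is read from disk except the
# HCT116/oxaliplatin example rates table shipped in extdata.

# A normalized series with given times (days) and log-values.
make_series <- function(times, log_values, concentration = 0,
                        experiment = rep("e1", length(times))) {
  ord <- order(times)
  structure(list(
    concentration = concentration,
    times = times[ord],
    log_values = log_values[ord],
    experiment = experiment[ord],
    n_replicates_per_time = as.integer(table(factor(times[ord],
                                                    levels = unique(times[ord]))))
  ), class = "normalized_series")
}

# Noise-free exponential assay at one or more rates (times in hours).
exact_assay_df <- function(rates, concentrations, times_h = c(0, 24, 48, 72),
                           n_replicates = 3, baseline = 0.2) {
  grid <- expand.grid(time = times_h, replicate = paste0("r", 1:n_replicates),
                      concentration = concentrations, stringsAsFactors = FALSE)
  r <- rates[match(grid$concentration, concentrations)]
  grid$experiment <- "e1"
  grid$absorbance <- baseline * exp(r * grid$time / 24)
  grid
}

# Noise-free logistic (saturating) growth over 0-3 days, carrying capacity
# capacity_fold times the seeding population: clearly not exponential.
logistic_series <- function(capacity_fold = 1.5, g = 4) {
  t <- rep(c(0, 1, 2, 3), each = 3)
  n0 <- 1
  k <- capacity_fold * n0
  n <- k * n0 / (n0 + (k - n0) * exp(-g * t))
  make_series(t, log(n / n0))
}

hct116_rates <- function() {
  readr::read_csv(system.file("extdata", "hct116_oxaliplatin_rates.csv",
                              package = "growthIC"),
                  show_col_types = FALSE, progress = FALSE)
}
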