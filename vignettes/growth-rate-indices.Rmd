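---
title: "Growth-rate-based potency indices: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-rate-based potency indices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(growthIC)
```

## The problem

The standard readout of an MTT-type viability assay is the endpoint ratio
of treated to control absorbance, and the standard potency summary is the
IC50 of a sigmoid fitted to that ratio. Both populations keep growing (or
dying) during the assay at different rates, so the ratio — and with it the
IC50 — depends on the endpoint chosen: running the same plate to 24 h or
72 h yields different numbers. growthIC instead summarizes each
concentration by its **effective growth rate**, the exponent of the
Malthusian model

$$N(t) = N_0\, e^{r t},$$

which over the short assay window (0–3 days, before density effects bite)
is a time-independent property of the culture. Viability connects to rates
through

$$V(t) = \frac{N_C(t)}{N^*(t)} = \frac{N_{0C}}{N_0^*}\, e^{(r_C - r_0) t},$$

with $r_C$ and $r_0$ the treated and control rates, so any viability
convention maps to a target rate $r_C = r_0 + \ln(V \cdot N_{0C}/N_0^*)/t$
(`rate_for_viability()`). With the usual convention — 50% viability at 3
days, equal seeding — the target is $r_0 + \ln(0.5)/3 = r_0 - 0.2310$.

## The pipeline

**1. Growth rates.** Each concentration series is normalized per
independent experiment to its seeding-time ($t_0$) absorbance and
log-transformed (`normalize_to_t0()`); the slope of the least-squares line
through (time, log value) is the effective growth rate
(`fit_log_linear()`). Uncertainty comes from the bootstrap
(`bootstrap_rate()`, default 1000 resamples): *paired* (resample
observation pairs with replacement — the default, robust to design
imbalance) or *residual* (resample residuals onto the fixed design). The
rate is reported as the bootstrap mean with the normal-approximation
interval $\bar r \pm z_{\alpha/2}\,\mathrm{SE}$ at 90% confidence
($z = 1.6449$); a percentile interval is available.

**2. Dose–response.** Rates decline with concentration following a shifted
exponential

$$r(C) + r_\infty = A\, e^{-\alpha C},$$

where $r_\infty > 0$ is the magnitude of the negative high-dose plateau
(`fit_shifted_exponential()`; Levenberg–Marquardt, unweighted). Inverting,

$$C(r) = -\frac{1}{\alpha} \ln\!\frac{r + r_\infty}{A},$$

gives the dose for any target rate (`invert_concentration()`).

**3. Indices.** `monte_carlo_indices()` implements the mixed
bootstrap/Monte-Carlo scheme: concentrations are held fixed, each draw
samples every rate from $\mathrm{Normal}(\bar r, \mathrm{SE})$, refits the
model, and inverts at the draw's target:

* **IC50** — $r_0^* - 0.2310$ (the 50%/3-day convention; configurable),
* **ICr0** — 0, the cytostasis dose (population neither grows nor dies),
* **ICrmed** — $r_0^*/2$, the dose halving the control growth rate,

with $r_0^*$ the *sampled* control rate, so control uncertainty propagates
into every index (ICrmed deliberately uses the per-draw $r_0^*/2$, not half
the point estimate). The per-draw fit is unweighted because uncertainty
already enters through the sampled rates; weighting by SE as well would
count it twice. Index means and 90% percentile intervals are read off the
distribution of 1000 draws (1000–5000 recommended).

```{r worked-example}
rates <- readr::read_csv(
  system.file("extdata", "hct116_oxaliplatin_rates.csv", package = "growthIC"),
  show_col_types = FALSE)
monte_carlo_indices(rates, n_sims = 1000, seed = 1)[, 1:6]
```

## Design choices

These were genuinely open; the package fixes them as follows.

* **Seeding-time points in the fit.** The $t_0$ log-values (≈ 0 after
  normalization) are *included* in the regression with a free intercept.
  They carry real replicate information and anchor the design matrix; the
  alternative reading — fit only the 24/48/72 h points — is available as
  `exclude_t0 = TRUE`. For exponential data the two agree exactly.
* **Normalization constant.** Each experiment is normalized by the
  *geometric* mean of its $t_0$ absorbances, so the $t_0$ log-values
  average to zero exactly. The arithmetic mean differs only by a
  per-experiment additive constant in log space (of order $\sigma^2/2$) and
  leaves the slope essentially unchanged; the geometric convention makes
  the invariant exact.
* **Pooling.** The three independent experiments are pooled into one fit
  after per-experiment normalization; per-experiment scale factors
  (plate-reader gain, seeding density) cancel in the normalization, which
  is also why no blank/edge correction is attempted here — inputs must be
  blank-corrected upstream.
* **Exponentiality gate.** The pipeline refuses (exit/error, unless
  `force`) series that fail the exponential-growth check: R² of the
  log-linear fit below `r2_threshold` (default 0.90). R² is meaningless
  when the true slope is near zero, so when the total log-change over the
  window is below 0.1 the series is judged by residual spread instead
  (pass if residual SD ≤ 0.25 log units). The 0.90 default is deliberately
  conservative: a genuinely exponential series with a modest rate
  (≈ 0.15 days⁻¹) and ≈ 8% multiplicative noise sits near R² ≈ 0.85 and
  will be flagged — the flag marks "this rate rests on little signal", and
  `r2_threshold` or `force` are the explicit overrides.
* **Normality gate.** The bootstrap slope distribution is declared normal
  enough when |skewness| < 0.5 and |excess kurtosis| < 1. Formal tests
  were rejected: at 1000 replicates they flag trivial deviations.
* **Monte-Carlo failures.** Draws whose refit does not converge or whose
  target rate leaves the fitted model's range are dropped and counted,
  never redrawn (redrawing conditions on an easy fit and biases the
  index). Above 20% failures the estimate is flagged invalid.
* **Inversion domain.** Targets at the control rate return dose 0; targets
  above it, or at/below $-r_\infty$, are errors — the model cannot reach
  them with a positive dose.
* **4PL baseline.** The conventional sigmoid
  $Y = Y_{min} + (Y_{max}-Y_{min})/(1+(X/\mathrm{IC50})^H)$ is fitted on
  the concentration scale with the control included at $X = 0$ (where the
  model evaluates to $Y_{max}$ for $H > 0$), so no log-dose placeholder
  for the control is needed. Its `ic50` is the *relative* IC50 — the
  midpoint dose. Note a subtlety the time-dependence demonstration
  exposes: at a late endpoint where viability falls well below 50%, the
  midpoint lies *above* 50% viability and the relative IC50 can sit
  slightly below the growth-rate IC50, while at early endpoints it sits
  far above it. The instability across endpoints, not the sign of the
  offset, is the robust phenomenon.

## The synthetic-assay generator

`synthetic_spec()`/`generate_assay()` emulate the targeted assay design:
readings at 0/24/48/72 h, 3 technical replicates × 3 independent
experiments, eleven doses (control plus ten two-fold dilutions from
50 µg/mL), exponential growth at $r(C) = A e^{-\alpha C} - r_\infty$, and
multiplicative log-normal noise on absorbance. Defaults
$(A, \alpha, r_\infty) = (0.85, 0.06, 0.55)$ give a control rate of
0.30 days⁻¹ and a high-dose decline of −0.55 days⁻¹, the magnitudes seen
in oxaliplatin assays on colorectal lines; the default noise
$\sigma = 0.08$ (≈ 8% CV per well) is a realistic per-well technical
error for MTT readings. Log-normal noise keeps absorbances positive and
makes log-space residuals homoscedastic — exactly the error model the
log-linear fit assumes; an additive-noise mode exists purely to
stress-test robustness. What the generator does **not** emulate: plate
position effects, shared per-experiment biases (its experiments differ
only by noise), density-dependent saturation, or drug degradation over
the assay. Passing recovery tests on these synthetics therefore
demonstrates correctness of the estimation machinery under the model's
own assumptions, not robustness to every failure mode of real plates —
the exponentiality gate exists to catch the latter.

`ground_truth_indices()` inverts the generating curve analytically and is
the oracle for the end-to-end tests: at noise σ = 0.05 the full pipeline
recovers all three indices within a few percent (tested: < 15% relative
error over 20 seeds with 1000 bootstrap/Monte-Carlo iterations).

## Problem sizes and numerics

The shipped tests and the reproduction script use 1000 bootstrap
resamples per concentration and 1000 Monte-Carlo draws — the
recommended working depth for this method — with 200-repeat coverage
simulations and 12–20-seed recovery studies; these sizes were chosen to
characterize the estimators well while keeping a full run in tens of
seconds. Bootstrap resampling is vectorized (closed-form row-wise OLS);
degenerate paired resamples (a single distinct time) are redrawn with a
hard cap of 10 × n_boot redraws. All stochastic steps take explicit
seeds; pipeline entry points derive per-stage sub-seeds deterministically
from one master seed, so every table and file is bit-reproducible.

## Limitations

Rates assume a constant exponential phase across the whole window;
density-limited or delayed-onset kinetics violate this and are only
*flagged*, not modeled (no logistic or mixed-effects growth fitting). The
dose–response form is the single shifted exponential — log-logistic or
Weibull alternatives, and multi-drug combination indices, are out of
scope. ICr0 is undefined for lines whose rate never reaches zero in the
tested range (positive plateau); ICrmed is the recommended index there.
The 4PL baseline replicates the model used by common IC50 calculators,
not any particular program's interpolation or CI machinery.
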