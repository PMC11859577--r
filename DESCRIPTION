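Package: growthIC
Title: Time-Independent Drug-Potency Indices from Effective Growth Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reanalysis of plate-reader cell-viability (MTT-type) assays via
    effective growth rates instead of endpoint viability ratios. Per-drug-
    concentration growth rates are estimated by log-linear least squares with
    paired or residual bootstrap uncertainty, the dependence of the rate on
    concentration is fitted with a shifted-exponential dose-response model
    r(C) + r_inf = A * exp(-alpha * C), and the fit is inverted to obtain the
    time-independent potency indices ICr0 (cytostasis concentration) and
    ICrmed (half-control-rate concentration) together with a growth-rate-
    derived IC50, each with Monte-Carlo confidence intervals. A conventional
    four-parameter logistic (4PL) relative IC50 baseline and a synthetic-assay
    generator with analytic ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
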