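Package: kcalmsm
Title: Simulating Calorie-Reduction Interventions on Childhood Obesity
    with Marginal Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the controlled direct effect of maternal
    education on childhood obesity with inverse-probability-weighted logistic
    marginal structural models, and for g-computation of counterfactual
    calorie-reduction intervention scenarios (universal, geographically
    targeted, indicated by prior obesity, and intake-capping). Includes a
    synthetic birth-cohort generator with known ground-truth coefficients,
    LMS-based BMI z-scores with epidemiological overweight/obesity cut-offs,
    estimated-average-requirement (EAR) energy constants, stabilized and
    percentile-truncated inverse probability weights, chained-equations
    multiple imputation with Rubin pooling, and a seeded end-to-end pipeline
    producing prevalence and inequality (risk ratio / risk difference)
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
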