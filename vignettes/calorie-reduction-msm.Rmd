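---
title: "Simulating calorie-reduction policies with a weighted marginal structural model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating calorie-reduction policies with a weighted marginal structural model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcalmsm)
library(dplyr)
```

## The question

Childhood obesity in the United Kingdom is common and socially patterned:
children of mothers with the least education are roughly twice as likely to
be living with obesity at school age as children of the most educated
mothers. Population trials of calorie-reduction policies are rarely
feasible, so their likely impact has to be estimated by causal simulation
from observational cohorts. `kcalmsm` implements such a simulation pipeline
end to end:

1. estimate the **controlled direct effect (CDE)** of maternal education on
   obesity at age 6–7 years, holding each child's daily energy intake at
   age 3 fixed at its observed value, using a logistic regression embedded
   in a **marginal structural model (MSM)** with stabilized
   inverse-probability weights (IPWs); then
2. **g-compute** the obesity prevalence that the fitted CDE model predicts
   under counterfactual reductions of energy intake — four policy-style
   scenarios differing in effectiveness, targeting and uptake — and compare
   prevalences and inequalities against the CDE reference.

Because the underlying survey microdata are not public, the package ships a
first-class synthetic-cohort generator whose defaults encode the published
marginal structure of the motivating cohort, with known ground-truth
coefficients so that every stage of the pipeline is testable.

## The causal model

Let $A$ be 3-level maternal education (disadvantage-coded high = 0,
mid = 1, low = 2), $C$ the baseline confounder (child ethnicity), $L$ the
intermediate confounders (birthweight category, general health, moderate
activity, TV time), $M$ daily energy intake in kcal at age 3, and $Y$
obesity at 6–7 years ($z_{BMI} > 1.6449$, the 95th centile). The assumed
ordering is $C \rightarrow A \rightarrow L \rightarrow M \rightarrow Y$
with direct arrows from $A$, $C$ and $L$ into $M$ and $Y$.

Two stabilized weights are constructed per child:

* exposure weight $P(A = a_i)\,/\,P(A = a_i \mid C_i)$, the denominator
  from a multinomial logistic regression of education on ethnicity;
* mediator weight $f(M_i \mid A_i)\,/\,f(M_i \mid A_i, C_i, L_i)$, both
  densities normal on the log-kcal scale, fitted by two linear regressions
  of log intake with maximum-likelihood residual variances. Sex is included
  in both intake models by default (`include_sex = TRUE`) because intakes
  are strongly sex-patterned; the toggle exists because the conceptual
  confounder set omits sex.

The product of the two weights is truncated at its empirical 1st and 99th
percentiles. Truncation uses inverse-empirical-CDF (type 1) quantiles, so
the bounds are order statistics of the weight vector itself; percentile —
rather than absolute-value — truncation is the standard MSM reading of
"truncated between 1% and 99%", and absolute truncation at 0.99 would
destroy weights centred at 1. The weighted logistic working model
$\text{logit}\, P(Y = 1) = \beta_0 + \beta_A A + \beta_M M$ is maximized by
iteratively reweighted least squares (deviance tolerance $10^{-8}$, at most
100 iterations) and reported with a robust (HC0 sandwich) covariance, as
appropriate when weights are estimated.

Prevalence reports average per-child fitted probabilities (overall and
within education groups). Inequalities are a **risk ratio** and a **risk
difference** comparing the lowest with the highest education group, with
education entered as a continuous linear term and group probabilities
g-computed at the extreme codes (2 and 0) over the sample's covariates, so
RR > 1 always means disadvantage-associated excess risk. Confidence
intervals come either from a nonparametric bootstrap over children
(children are resampled *before* weight estimation; 499 replicates by
default in the `estimate_*()` functions) or from the delta method, which is
the fast alternative used inside large simulation loops and as the
`run_pipeline()` default.

## The synthetic cohort and what it emulates

`cohort_params()` defaults encode the study conditions the analysis
assumes:

* 51.3% boys; education split 9.4 / 66.4 / 24.2% (low/mid/high); 96.1%
  white ethnicity; confounder category frequencies matching the published
  descriptive table.
* Energy intake at age 3 is log-normal (the observed distribution is
  right-skewed) with sex-specific medians 1311.5 (boys) and 1273.5 (girls)
  kcal. No education–intake association by default
  (`education_effect = 0`), matching the observed absence of social
  patterning of intake, and no confounder–intake effects by default for
  the same reason.
* The intake log-SDs are not published. They are calibrated so the
  proportion of children consuming at or below the estimated average
  requirement (EAR; 1171.0 kcal boys, 1076.0 kcal girls at age 3) matches
  the published 33.5% / 22.0%: $\sigma_m = \log(1311.5/1171)/(-\Phi^{-1}(0.335))
  = 0.26594$ and $\sigma_f = 0.21824$. This is a calibration choice, not a
  published value.
* Obesity at 6–7 years is a Bernoulli draw from a logistic structural
  model: education offsets (vs high) of 0.741 (mid) and 0.778 (low) — the
  logit differences implied by the published CDE group prevalences — an
  intake coefficient of 0.10 per 100 kcal, and modest confounder effects.
  The intake coefficient was back-solved from the published scenario
  arithmetic (mean reductions of roughly 126, 19 and 320 kcal for the
  universal, indicated and capping scenarios against reported relative
  prevalence changes of −11.9%, −1.9% and −22.5% all imply ≈ 0.10 on the
  logit per 100 kcal). The intercepts are frozen solutions of the marginal
  expectation of the structural model (`calibrate_logit_intercept()`)
  matching 8.3% obesity at 6–7 years and 6.7% at age 3.
* BMI z-scores are drawn from a standard normal truncated at 1.6449
  consistently with each obesity flag. Generating the flag first keeps the
  ground truth exactly logistic, which is what makes parameter-recovery
  tests meaningful; generating a Gaussian z-score and thresholding it
  would make the true model probit and the logit-scale truth undefined.
* Area deprivation is a standardized score (plus quintiles); the published
  deprivation index is external, so geographic targeting uses the score
  scale only.

What the generator does *not* emulate: diary measurement error and
reporting bias, within-family correlation, regional structure, non-random
diary return, and the real (licensed) national growth-reference
coefficients — `lms_reference()` is a synthetic table with the right shape
(median-BMI dip and rebound across ages 2–8). Passing tests therefore
demonstrate the statistical machinery under the assumed data-generating
law, not robustness to those real-data features.

## Recovery, estimands and the null experiment

With the default education→confounder links switched on, the marginal CDE
education gradient legitimately exceeds the generating direct coefficients:
fixing $M$ does not block the $A \rightarrow L \rightarrow Y$ pathway, so
that pathway is part of the controlled direct effect. Parameter-recovery
and null-calibration experiments therefore cut the education→confounder
links (keeping ethnicity confounding, which the exposure weights must
remove, and confounder→outcome effects), making the generating
coefficients the estimand. Under that design the package recovers the
education and intake coefficients with logit-scale bias well under 0.05 at
n = 20,000, and the CDE risk-ratio 95% CI covers 1 in ≈ 95% of null
replicates at n = 5,000 (delta-method CIs inside the loop).

## Intervention scenarios

`build_builtin_scenarios()` declares the four standard policies:

| | Reduction | Eligible | Uptake |
|---|---|---|---|
| S1 | sex-specific shift of the median to the EAR (−140.5 kcal boys, −197.5 girls; −13.0% overall) | all children | 75% |
| S2 | −21.3% | deprivation score ≥ mean + 1 SD | 75% |
| S3 | −21.3% | obese at age 3 | 100% |
| S4 | cap at the sex-specific EAR | intake > EAR | 100% |

Uptake is an independent Bernoulli draw per eligible child under the
scenario seed (the alternative — deterministically scaling effects by the
uptake — is not what a realized policy would do to individual children).
Variability "around the adjusted level" is a mean-preserving normal jitter;
no SD is published, so the default is 25% of the absolute reduction
(sex-specific for S1, the cohort-median-based reduction for S2/S3),
re-centred within treated children of each sex so the mean shift is exactly
the target. S4 is a hard cap with no jitter: its defining post-condition is
that *everyone* ends at or below the EAR. Two guarantees hold for every
scenario: no child's intake ever increases, and no child is moved below
the floor of 2 SD below the cohort's observed mean intake (children
already below the floor are untouched). The floor statistics are computed
on the pre-intervention analytic intake distribution.

Scenario impact is pure g-computation: the already-fitted CDE model is
evaluated at the modified intakes and averaged; the model is *not*
refitted, because the counterfactual question is what the fitted
intake–obesity relationship predicts under changed intakes. Percent
changes are relative to the CDE reference,
$100\,(p_{\text{scenario}} - p_{\text{CDE}})/p_{\text{CDE}}$.

The published eligible fraction for the deprivation-targeted scenario
(33.8%) is inconsistent with a 1-SD score rule on a roughly normal score
(≈ 16%); the score rule is implemented as stated and the 33.8% treated as
an empirical fact of the original survey, not a constraint.

## Missing data

`impose_missingness()` masks mediator/confounder columns under MCAR or
MAR-given-education (odds multiplied per disadvantage level); the exposure
and the outcome are never maskable because the analytic sample is defined
as complete on both. `chained_imputation()` is a lightweight
chained-equations imputer: log-scale normal regression for intake (with
posterior-style coefficient and variance draws), logistic regression for
binary columns, multinomial logistic for 3-category columns, plug-in
categorical draws, 10 cycles by default, one sub-seed per imputation. It
deliberately uses parametric predictive draws rather than predictive mean
matching — a documented simplification relative to typical
chained-equations software. `rubin_pool()` combines per-imputation
estimates with the usual total variance
$\bar W + (1 + 1/m)B$ and t-intervals on the Rubin degrees of freedom;
with $m = 1$ the between-imputation variance is undefined and the total
variance falls back to $\bar W$ with a warning. Prevalences and risk
differences are pooled on their own scales; risk ratios on the log scale.

## Numerical and design choices

* Centile cut-offs are fixed standard-normal quantiles on the z-scale
  (1.0364 and 1.6449), strictly "greater than", because classification is
  by percentile of the reference z-distribution; LMS (L, M, S) parameters
  are linearly interpolated in age within sex.
* The master seed of a pipeline run derives one sub-seed per stochastic
  stage through `derive_seed()` (a fixed counter scheme), so adding a stage
  never perturbs the streams of earlier stages and identical
  configurations give byte-identical reports.
* `run_pipeline()` defaults: n = 2001 children (the size of the motivating
  analytic sample), delta-method CIs, m = 5 imputations when missingness
  is configured (m = 50 is supported and exercised in the tests at smaller
  n), 199 bootstrap replicates when the bootstrap is requested. The
  acceptance script and the heavier tests use n = 20,000 cohorts, 16
  recovery replicates and 200 null replicates — sizes chosen so
  Monte-Carlo error is comfortably below the tolerances being asserted.
* Degenerate inputs fail loudly and early: non-positive intakes, unknown
  category labels, masked exposure/outcome, empty education cells,
  zero residual variance in the intake models, suspected separation
  (|coefficient| > 15), and empty weight vectors all raise classed errors.

## Limitations

The pipeline estimates effects under the stated DAG; unmeasured
confounding, measurement error in the mediator, and interference are
outside the model, exactly as in the motivating analysis. The synthetic
cohort is a stand-in: absolute prevalences reproduce published margins by
construction, so agreement there validates calibration, not the survey
itself. Scenario confidence intervals condition on the fitted CDE model
(delta method over its coefficients); they do not propagate scenario-seed
Monte-Carlo variation, which is negligible at the default cohort sizes.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(n_children = 20000, seed = 11))
res$model_table |>
  select(model_tag, overall, overall_chg, rr, rd)
```

The six-row table (unadjusted, CDE, S1–S4) mirrors the published layout:
overall and per-education prevalence with percent change versus the CDE,
proportions consuming at or below the EAR, and the risk ratio / risk
difference with CIs. `write_pipeline_report()` writes the same bundle as
delimited text with percentages to one decimal place.
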