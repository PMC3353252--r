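---
title: "Transporting and recalibrating diabetes risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transporting and recalibrating diabetes risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskrecal)
```

## The models and what transport breaks

The package works with logistic risk functions for incident type 2
diabetes over a fixed follow-up period,

$$p = \frac{1}{1 + e^{-y}}, \qquad y = \beta_0 + x'\beta,$$

in three published incarnations.  The SAHS and ARIC models are mostly
continuous (age in years, fasting plasma glucose, HDL and triglyceride on
the mg/dl scale, systolic blood pressure in mmHg, BMI in kg/m², waist and
height in cm, a family-history indicator, a dichotomous race term with
the lower-risk group as reference, and in SAHS a female indicator with
male as reference).  The Framingham model is all-categorical: impaired
fasting glucose, elevated blood pressure and triglyceride, low HDL,
overweight and obese indicators, plus family history.

A model derived elsewhere carries its derivation population inside
$\beta_0$: the baseline incidence and the mean risk-factor levels of that
population.  Applied to a different population the ordering of risks
(driven by $\beta$) usually survives, but absolute risks do not.
Moreover, the published intercepts are not part of the coefficient tables
these models are usually quoted from, so `load_published_models()`
deliberately stores `intercept = NA`: the package never fabricates a
constant, and absolute risks from published models are only available
through recalibration (which does not need the intercept) or a
user-supplied constant.  Rank-only scores for AUC work are available via
`linear_predictor(..., rank_only = TRUE)`.

## The recalibration formula

Recalibration keeps the external $\beta$ and replaces the anchor:

$$p(x) = 1 - S(m)^{\exp\{(x - m)'\beta\}},$$

where $m$ is the local mean covariate vector *on the model's encoding
scale* (so binary terms contribute their local prevalence, and mg/dl
terms their converted means) and $S(m)$ is the local probability that a
subject with average risk factors stays diabetes-free over the study
period.  A subject at the local average gets risk $1 - S(m)$; everyone
else is moved up or down by the external relative risks.  The curve is a
complementary-log-log (Gumbel) link in the score, which agrees closely
with the logistic curve at low risks — the regime these cohorts are in —
but diverges at high risks; this matters below.

### Estimating S(m)

The quantity is defined "from the local population" and there are two
natural estimators, both implemented in `estimate_context()`:

* `mean_plugin_incidence` (default of `estimate_context()`): $S(m) = 1 -
  \hat{q}$ with $\hat{q}$ the observed incidence.  Transparent, but the
  recalibration curve is convex in the score over most of its range, so
  the *mean* recalibrated risk exceeds the risk *at the mean*; with a
  right-skewed risk distribution the plug-in systematically over-predicts
  mean risk.
* `intercept_matched`: solves the one-dimensional monotone equation
  "mean recalibrated probability = observed incidence" for $S(m)$ by
  root-finding.  This is exact calibration-in-the-large by construction
  and is what `full_study()` uses for its headline tables; the
  transport experiment in the acceptance script uses it for the same
  reason.

Both estimators are reported side by side when contexts are printed, and
the package treats the choice as a first-class, documented parameter
precisely because the defining sources leave it open.

### Stratified variants

`two_step_race_recalibration()` implements the two-step procedure for
multi-ethnic populations: (1) remove the race terms from the external
model — their coefficients encode another population's ethnic contrasts
and an assumption of exactly two groups — and (2) recalibrate the
race-free model separately within each ethnic group, so each group is
anchored on its own $m$ and $S(m)$.  Within a group the risk ordering is
that of the race-free score; between groups the anchors restore the
absolute differences.  `stratified_recalibration_by_age()` does the same
with age bands (optionally dropping the linear age term), which absorbs
birth-cohort or nonlinear age effects that a single transported age
coefficient cannot represent.  Strata partition the cohort; an empty
stratum is an error, and a stratum with no events gets $S(m) = 1$ (all
recalibrated risks 0) with a warning rather than a crash, since small
strata genuinely occur.

## Local refits and model comparison

`fit_local_model()` is iteratively reweighted least squares (base R
`glm`) run to a relative log-likelihood change of 1e-10 with at most 100
iterations, so refits are deterministic given the data.  Separation and
rank deficiency are detected and reported with the offending terms named
rather than returned as garbage coefficients.  Wald 95% intervals
($\hat\beta \pm 1.96\,\mathrm{SE}$) back `compare_coefficients()`, which
flags published values falling outside the local interval — the working
definition of "effect sizes did not transport".

The race-coding choice (`choose_race_coding()`) fits the combined
non-reference dummy and the separate two-dummy coding and keeps the lower
AIC ($2k - 2\log L$), reporting both.  The heterogeneity screen
(`screen_ethnicity_interactions()`) adds one covariate-by-ethnicity
interaction at a time and keeps those with likelihood-ratio $p < 0.05$.
By default the interaction uses the dichotomous non-Chinese dummy (1 df
per term), matching the coding the local models use; a 3-level option (2
df) exists because the defining description does not say which was meant.

## Discrimination and calibration statistics

`auc()` is the Mann-Whitney estimator (ties one half) computed via
midranks, with the DeLong structural-component variance for confidence
intervals; `delong_compare()` builds the 2×2 component covariance for a
paired z-test of correlated AUCs.  The test suite cross-checks both
against an independent implementation (pROC) and against a
nonparametric bootstrap; the self-comparison degenerates to $p = 1$ by
convention rather than 0/0.

`nri()` uses the six categories bounded at 10/20/30/40/50%.  The printed
labels ("10.1–20%") are treated as half-open intervals $(0.10, 0.20]$: a
risk of exactly 0.10 stays in the lowest category.  Components follow the
events-up/non-events-down convention; standard errors use the asymptotic
multinomial form per component, and the total combines components as
independent (the cited methodology leaves the total's variance
unspecified; independence is the standard choice).
`nri_from_counts()` exposes the same arithmetic for already-tabulated
counts, which is how the published worked example is reproduced.

`hosmer_lemeshow()` ranks subjects by predicted probability (ties broken
by original position, a stable deterministic rule), splits them into
equal-size quintiles, and computes
$\sum_g (O_g - E_g)^2 / \{E_g(1 - E_g/n_g)\}$ against $\chi^2_{g-2}$ —
3 df for quintiles — flagging statistics above 11.5, the 1% critical
value.  A degenerate group ($E_g$ of 0 or $n_g$) is guarded with a small
$\varepsilon$ and logged instead of producing `NaN`.  One subtlety the
test design respects: the $g - 2$ reference describes *fitted*
probabilities.  Scoring *known* (generator-true) probabilities, nothing
is estimated and the statistic behaves like $\chi^2_g$, whose 11.5
rejection rate is about 4%, not 1%; the null-behaviour tests therefore
refit the generating structure each replicate before scoring.

## Missing follow-up data

Cohorts lose follow-up glucose to non-response.  `apply_mar_dropout()`
deletes follow-up fields with a logistic probability driven by *observed
baseline* fields only — a mechanism referencing follow-up values is
rejected, because that would be missing-not-at-random, which multiple
imputation cannot fix.  `fcs_impute()` is fully conditional
specification: each incomplete field is regressed on the other imputer
fields (the inclusive default list spans demographics, blood pressure,
adiposity, lipids, baseline glucose, family history, kidney function and
insulin resistance, including variables that are auxiliary only), cycled
10 times per chain, with M = 20 independent chains by default.
Continuous fields default to predictive-mean matching — a Bayesian
parameter draw followed by donor sampling among the five closest
predicted means — because the follow-up glucose marginal is bimodal
(events vs non-events) and a normal conditional visibly attenuates the
downstream threshold-derived coefficients; the normal posterior
predictive remains available as `continuous_method = "norm"`.  Binary
fields use logistic draws.  `rubin_pool()` implements
$\bar Q,\ \bar W,\ B,\ T = \bar W + (1 + 1/M)B$ with the classical
large-sample degrees of freedom, and `pool_local_fit()` re-derives the
outcome from each completed dataset before refitting, so imputation acts
on the measurement (follow-up glucose), not directly on the outcome bit.

## The synthetic cohort generator

No cohort data ship with the package; `generate_cohort()` stands in for
the study population.  It emulates a multi-ethnic Asian health-survey
baseline: 60/20/20 Chinese/Malay/Indian mix, age 36.14 ± 10.84 y, BMI
22.80 ± 3.85 kg/m², FPG 5.35 ± 0.44 mmol/L, HDL 1.26 ± 0.31 mmol/L, SBP
114.45 ± 14.58 mmHg, 35.5% family-history prevalence, 47.8% male, and a
7.8% outcome incidence over the follow-up period.  Quantities the survey
tables do not give were fixed once at values realistic for a young Asian
cohort: waist 78 ± 9.5 cm, height 163 ± 8 cm with a ±6 cm sex shift,
triglyceride 1.35 ± 0.70 mmol/L, 2-hour glucose as FPG plus noise
(correlation ≈ 0.5), and auxiliary imputer variables (LDL, hip,
creatinine, insulin resistance) as simple correlated draws.  Correlations
default to BMI–waist 0.8, FPG–BMI 0.3, SBP–age 0.35 and 0.1 elsewhere;
Malay and Indian strata get small positive BMI/FPG mean offsets so the
non-Chinese excess risk has a covariate component as well as the race
coefficient.  All of it is configurable through `cohort_config()`.

Outcomes are Bernoulli draws from a configured logistic model (the
published ARIC coefficient vector by default) whose intercept is tuned by
root-finding so the expected incidence on the realised covariates equals
the target exactly; the tuned generating model is attached to the cohort
so experiments have ground truth.  Follow-up glucose and diagnosis flags
are drawn consistently with the outcome (15% of events are
diagnosis-only), so `define_outcome()` recovers the drawn outcome
exactly.  `generate_external_population()` shifts covariate means and the
intercept (e.g. `log(2)` doubles the odds at fixed covariates) to create
the transport mismatch the recalibration experiments need.

What the generator does *not* emulate: joint distributions beyond the
stated correlations (no skewness in lipids, no age-dependent variances),
measurement error, secular drift between baseline and follow-up, and any
true ethnic heterogeneity of *effect sizes* (the generating $\beta$ is
shared).  Passing tests therefore demonstrate that the procedures are
correct under a faithful low-risk logistic world of roughly this shape —
not that any particular published model is well calibrated for any real
population.

Continuous draws are clamped to plausible ranges (age to [18, 100],
positive lower bounds elsewhere; baseline glucose is truncated below the
diagnostic cutoffs when the generator emulates a post-exclusion cohort).
Clamping slightly biases extreme-tail moments — about +0.2 years on mean
age from the age-18 floor — which the distribution tests budget for
explicitly.

## Numerical choices

* IRLS: relative log-likelihood tolerance 1e-10, max 100 iterations.
* Root-finds (`intercept_matched` S(m), intercept tuning):
  `stats::uniroot` on a bracketing interval with tolerance 1e-10/1e-12;
  both criteria are strictly monotone so the root is unique.
* Hosmer-Lemeshow ties: stable sort on (probability, original index);
  group sizes from `floor(seq(0, n, length.out = groups + 1))` differ by
  at most one.
* Degenerate guards: ε = 1e-8 in Hosmer-Lemeshow denominators; zero-event
  strata warn and set $S(m) = 1$; `s_m = 0` is an error.
* Unit conversions: glucose 18.0182, cholesterol 38.67, triglyceride
  88.57 mg/dl per mmol/L, overridable, exactly invertible.
* All clinical thresholds are inclusive (≥), matching the diagnostic
  convention (FPG ≥ 7.0 mmol/L); the Framingham indicator cutoffs (IFG
  6.1–6.9 mmol/L, SBP ≥ 130 mmHg, triglyceride ≥ 1.7 mmol/L, HDL < 1.0 /
  < 1.3 mmol/L by sex, overweight BMI ≥ 25 with an Asian ≥ 23 option,
  obese ≥ 30) follow the conventions those definitions reference and live
  in the editable model files, since the defining sources do not pin them
  down.
* Reproducibility: every stochastic routine takes an explicit seed;
  imputation chains draw per-chain sub-seeds from the master seed.

## Problem sizes used by the test suite

The statistical guarantees are exercised at sizes chosen to make the
properties sharp while keeping the suite quick: exact-oracle equivalence
for AUC/NRI on 200 instances of n ≤ 50; DeLong variance against a
2000-replicate bootstrap at n = 200; Hosmer-Lemeshow null behaviour over
500 refitted replicates at n = 1400; the transport experiment over 200
replicates at n = 5000 (uncalibrated predictions must usually fail the
11.5 cutoff, recalibrated ones pass and match the incidence to within one
percentage point); Wald-interval coverage over 200 refits at n = 2000;
and the imputation bias check over 30 replicates at n = 2000 with M = 20
and 30% dropout.

## Known limitations

* Time-to-event structure is ignored by design: with interval-censored
  follow-up and low incidence, logistic coefficients stand in for
  proportional-hazards ones, which is the transported models' own regime;
  the package makes no attempt at baseline-survival recalibration.
* The recalibration curve and the logistic generator differ at high
  risks, so even the intercept-matched recalibration retains a small
  lack-of-fit in the upper quintile; with large samples the
  Hosmer-Lemeshow test has power against exactly this, which is why the
  transport experiment asserts a high pass rate rather than a perfect
  one.
* Complete-case local fits are consistent when dropout depends only on
  modelled covariates; the value of multiple imputation here is
  efficiency and unbiasedness under dropout driven by *any* observed
  baseline variable, not a repair of non-random missingness — MNAR
  mechanisms are out of scope and deliberately rejected by the dropout
  simulator.
* Published intercepts are unknown throughout; Table-style "uncalibrated
  published" absolute risks can only be produced for models whose
  intercept the user supplies.
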