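---
title: "Methods: constructing a Gompertz-anchored liver aging index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing a Gompertz-anchored liver aging index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lai)
```

## The problem

Biological-age clocks summarize a panel of biomarkers as an equivalent age.
First-generation clocks regress biomarkers on chronological age (CA) and so
can only ever restate it; second-generation clocks anchor the biomarker
signal to a hard outcome — mortality — so that a deviation from CA carries
risk information. `lai` implements a liver-specific second-generation clock:
13 noninvasive biomarkers (clinical, blood, and transient-elastography) are
first condensed into liver-related-event (LRE) risk scores, and those scores
are then translated into *years* through a Gompertz model of human
mortality.

## Step 1: per-category elastic-net Cox risk scores

The biomarkers are grouped into four categories — clinical (BMI, SBP, DBP),
metabolic (glucose, TC, TG, HDL-C, LDL-C), liver enzymes (ALT, AST, GGT),
and imaging (FAP, LSM). Grouping the panel keeps each sub-model small and
interpretable, and lets a category contribute even when its markers are
collinear. Within each category we maximize the penalized Cox partial
log-likelihood

$$\ell(\beta) - \lambda\left[\alpha\|\beta\|_1 +
  \tfrac{1-\alpha}{2}\|\beta\|_2^2\right]$$

on z-standardized features with LRE as the outcome. Choices that were
genuinely open, and how we fixed them:

* **Mixing parameter** `alpha = 0.5` by default: we want both shrinkage of
  collinear markers (ridge component) and the option of exact zeros (lasso
  component). Fully configurable.
* **Penalty rule**: the value maximizing mean cross-validated partial
  likelihood (`lambda.min`), not the 1-SE rule — the panels are tiny (2–5
  markers), so the extra sparsity of 1-SE buys little and costs signal.
* **Cross-validation**: 10 folds, with a seeded, event-balanced fold
  assignment (events and censored subjects are each spread evenly across
  folds) so that no fold is left without events and the selected penalty is
  reproducible under the seed.
* **Ties**: Efron's approximation wherever a partial likelihood is
  evaluated.
* **Transforms**: identity by default for all markers; a log transform can
  be declared per marker in the feature spec (it then also enforces
  positivity at cohort validation).
* **Age/sex in step 1**: the sub-models use biomarkers only. Age belongs to
  step 2's baseline; putting it into the risk scores would leak the
  timescale into the numerator of the acceleration ratio.

Each score is centered on its training mean, so all four scores have mean
zero in the training cohort. A category whose coefficients are all shrunk
to exactly zero produces a constant score; it is dropped from step 2 with a
warning rather than fitted as a degenerate covariate.

## Step 2: the Cox–Gompertz transformation to years

Adult human mortality is very nearly log-linear in age (Gompertz), so the
*age* timescale — not time-on-study — is the natural clock. Subjects enter
observation at their baseline age (left truncation) and exit at death or
censoring. For baseline stratum (sex) $s$:

$$h(u) = \exp(b_{0s} + \gamma_s u + \beta^\top x),\qquad
  H(u_0,u_1) = e^{b_{0s}+\beta^\top x}\,\frac{e^{\gamma_s u_1}-
  e^{\gamma_s u_0}}{\gamma_s}.$$

Two models are fitted independently: the *null* model (CA + sex; no
covariates) and the *full* model (CA + sex + the centered risk scores).
The null slope gives the sex-specific mortality-rate doubling time
$\mathrm{MRDT}_s = \ln 2/\gamma_s$ — the number of years it takes the
population hazard to double. The acceleration of subject $i$ is

$$\mathrm{LAA}_i = \mathrm{MRDT}_s \cdot
  \log_2\!\frac{h_\mathrm{full}(CA_i)}{h_\mathrm{null}(CA_i)},
  \qquad \mathrm{LAI}_i = CA_i + \mathrm{LAA}_i .$$

This is a dimensional statement: $\log_2$ of the hazard ratio counts
*doublings*, and MRDT is *years per doubling*, so LAA is in years. It is
exactly zero when the biomarkers say nothing beyond age, +MRDT for one
hazard doubling, −MRDT for one halving, and invariant to any common
rescaling of the two baselines.

Documented behaviors where the design was open:

* **The full model re-estimates its own slope** by default. Both hazards
  are evaluated at the subject's own CA, so a slope difference between the
  models propagates into an age-dependent LAA component. `share_gamma =
  TRUE` constrains the full model to the null slope if a pure
  score-translation is wanted.
* **Centering**: risk scores are centered on the training mean, which keeps
  the training LAA mean near zero and the LAI mean near the CA mean. This
  is the default and is what makes "LAI ≈ CA on average" hold.
* **Sex**: the 13-marker variant uses sex-stratified baselines
  $(b_{0s},\gamma_s)$ with score coefficients shared across sexes; the
  5-marker variant (`lai_feature_spec("lai5")`: ALT, AST, GGT, FAP, LSM)
  fits the entire pipeline separately per sex.
* **Quartile classes**: thresholds are the training LAA quartiles under the
  linear-interpolation quantile convention (R type 7). The convention is
  fixed and documented because class boundaries depend on it; values lying
  exactly on a threshold are *intermediate* (strict inequalities).
  Validation cohorts are always classified with the training thresholds.

### Numerics

The likelihood is maximized over $(b_0, \log\gamma, \beta)$ — the log
parametrization keeps $\gamma > 0$ — by BFGS with the analytic gradient,
initialized at $\gamma = 0.05$ with the closed-form profile $b_0$ and
$\beta = 0$, followed by Newton polishing with the observed information
until the gradient max-norm falls below $10^{-8}(1 + |\ell|)$. Failure to
reach that tolerance raises an error carrying the diagnostics; a slope
collapsing to the boundary ($\log\gamma < -13$, i.e. no aging signal) is
flagged and its MRDT reported as `NA` rather than a meaningless number.
Standard errors come from the inverse observed information (delta method
for $\gamma$). The cumulative hazard uses `expm1` and the sampling inverse
uses `log1p`, so the $\gamma \to 0$ exponential limit is exact to floating
point; fits with fewer than 10 deaths in a stratum are refused.

## The synthetic cohort generator

Real development cohorts for such an index are not redistributable, so the
generator is a first-class module that emulates the statistical structure
the method assumes, with marginals defaulted to the derivation-cohort
description (age 65.3 (9.0) years on [45, 95], 64.6% female, and the 13
biomarker means/SDs):

* ages from a truncated normal whose parent parameters are moment-matched
  so the *truncated* marginal hits the declared mean/SD (naive truncation
  of N(65.3, 9.0²) would shift the mean by ≈ +0.3 y and shrink the SD by
  ≈ 0.3 y);
* a latent liver-aging factor $A \sim N(0, \sigma_A^2)$, $\sigma_A = 1$;
* biomarkers $x_j = \mu_j + s_j(\mathrm{age} - \bar a) + \ell_j A +
  \varepsilon_j$, with the noise SD solved so the marginal SD equals the
  declared $sd_j$, and noise exchangeably correlated (ρ = 0.2) within
  category to exercise the elastic net's collinearity handling;
* death ages sampled on the age timescale from
  $h(u) = \exp(b_{0,\mathrm{sex}} + \gamma_\mathrm{sex} u +
  \theta^\top z + \kappa A)$ by the closed-form Gompertz inverse transform,
  left-truncated at entry; LRE ages analogously from a cause-specific
  hazard; administrative censoring after 10 years;
* deaths are labeled liver-related with probability 0.5 when an LRE
  preceded death and 0.02 otherwise (the data the method consumes carry
  only coded outcomes, so this link is a modeling convenience).

The free parameters with no published values — age slopes, loadings
$\ell_j$, and the per-SD log hazard ratios $\theta, \kappa$ (defaults
$\kappa = 0.3$, hepatic markers carrying most of the loading and of the
LRE hazard) — were chosen once so the synthetic index behaves at the scale
the real one is reported to have: LAA dispersion of ~2–3 years, LAI–CA
correlation ≈ 0.95, a per-SD mortality hazard ratio near 1.3, and an LRE
incidence near 5% over the horizon. Baseline mortality
($b_0$ = −10.4 female / −9.9 male, $\gamma = 0.09$, MRDT ≈ 7.7 y) gives
hazards of roughly 1%/y (women) and 1.7%/y (men) at age 65, typical of
general-population cohorts at these ages.

What the generator deliberately does **not** emulate: the right-skew of
GGT/TG/ALT (marginals are additive normals, so high-CV markers put some
mass below zero — the declared means/SDs are matched exactly instead),
regional/center structure, survey design beyond a per-subject weight
column, measurement error in elastography, and time-varying biomarkers.
Passing tests on synthetic cohorts therefore demonstrate that the
*machinery* recovers what it assumes, not that the index is valid in any
particular real population.

## Validation battery

`evaluate_lai()` reproduces the standard assessment set: Pearson r / RMSE /
MAE against CA; AUROC (Mann–Whitney with ties counted ½, DeLong
structural-component variance) of LAI vs CA for each outcome with the
paired DeLong test; Cox hazard ratios per 1 SD of LAA with Efron ties,
optional per-subject weights, and adjustment for age, sex, and any of
region/education/marital status present; and Kaplan–Meier curves with the
unadjusted two-sample log-rank test between the accelerated and
decelerated classes. AUROC uses cumulative event status over follow-up (a
single number per cohort); multiple outcomes are reported without
multiplicity correction — both choices mirror how such indexes are
conventionally reported, and are flagged here so nobody mistakes the
battery for a calibrated decision procedure.

## Simulation-study sizes

The test suite's recovery studies use cohorts of 20,000 (Gompertz slope
recovery over 20 replicates; end-to-end latent-factor recovery at
$\kappa \in \{0, 0.1, 0.3\}$ under common random numbers), 50 replicates
of n = 5,000 for hazard-ratio recovery, 200 replicates of n = 500 for null
CI coverage, and n = 50,000 for the closed-form survival check — sizes at
which the Monte-Carlo error of each check is several times smaller than
the tolerance it is asserted against.

## Known limitations

* The index is defined for ages 45–95; the reader rejects ages outside the
  declared bounds rather than extrapolating the Gompertz baseline.
* LAA inherits any misfit of the Gompertz form at the oldest ages
  (late-life deceleration is not modeled).
* The "invalid measurement" exclusion rules of real elastography devices
  are not modeled; the cohort reader enforces only schema, range, and
  event-logic checks, plus positivity for log-transformed markers.
* Survey weights enter the Cox associations only as per-subject weights;
  no design-based variance estimation is attempted.
* A category can be shrunk entirely out of the model; its score is then
  dropped from step 2 (with a warning) and contributes zero to LAA.
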