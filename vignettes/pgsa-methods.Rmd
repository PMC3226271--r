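---
title: "Placebo group simulation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placebo group simulation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsa)
```

The placebo group simulation approach (PGSA) forecasts what a trial cohort
of presymptomatic Alzheimer's (MCI) subjects would have done *without*
treatment, from the cohort's own baseline data, and compares observed
on-drug outcomes against that forecast instead of against a concurrent
placebo arm. This vignette documents the two models the package implements,
the synthetic-cohort generator that stands in for the non-redistributable
source data, the numerical and design choices that were genuinely open, and
the limits of what the package's own simulations can demonstrate.

## The endpoint model

The modified ADAS-cog total (0–85, higher = worse; the conventional subscale
plus Delayed Word Recall and Digit Cancellation) at month 24 is strongly
right-skewed in MCI, so the model regresses its square root on baseline
covariates. Candidate main effects are age, gender, years of education, the
obesity flag (BMI ≥ 30), the ApoE4 allele count, the modified Hachinski
score, and baseline FAQ, MMSE, ADAS-cog and NP-Batt. Three covariate-coding
choices deserve note:

* **ApoE4 enters as a numeric 0/1/2 count** — two alleles approximately
  double the effect of one, so a linear count is both parsimonious and
  faithful.
* **Gender reference.** Published coefficient tables rarely state the
  reference level; the package defaults to female = 1 / male = 0 and makes
  it configurable in `coding_config()`. The sign interpretation of the
  gender coefficient depends on this assumption.
* **Obesity** is the third BMI class (≥ 30 kg/m²) of the three-class split
  (<25, 25–<30, ≥30). A binary "at or above 25" variant is available via
  `coding_config(obesity_definition = "bmi2_or_3")`. For the endpoint model
  the candidate set uses the binary obesity flag; for the trajectory model
  it uses the two class dummies, mirroring how each published model is
  parameterized.

Selection is backward elimination by AIC over main effects (single-term
deletions, largest AIC drop first, ties broken by term name for
determinism), then each pairwise interaction of the surviving main effects
is tested one at a time (kept when it lowers AIC), the acceptances are
pooled, and backward AIC elimination is re-run honoring marginality. The
final model's AIC can therefore never exceed the full main-effects start.

**Virtual placebo simulation.** A virtual trial draws one parameter vector
θ from MVN(β, Σ) and applies it to *all* subjects, then adds per-subject
residual noise and back-transforms by squaring (values below 0 on the
square-root scale are floored at 0; squared values are clipped to 85). The
per-replicate (rather than per-subject) parameter draw is a deliberate
choice: it preserves the correlation of parameter uncertainty across
subjects within a virtual trial, which is what matters when the simulated
quantity is a group mean. The back-transform of an expectation is biased
low relative to the expectation of the back-transform, which is why all
power and precision arithmetic stays on the square-root scale and only
interval *endpoints* are squared.

**Power and precision.** For a randomized treatment the treatment indicator
is uncorrelated with the model covariates, so the two-sample normal
approximation applies directly: power = Φ(d/(σ√(2/n)) − z) plus the
opposite tail. The package uses two-sided α = 0.05 by default. An effect of
d = 0.16 on the square-root scale corresponds to about 1 ADAS-cog point at
a score of 10 and 2.5 points at 60 (`effect_on_original_scale()`), and with
σ = 0.669 and 286 per group gives 82% power. A 200-subject mean of 20 on
the original scale has a 95% interval of (19.2, 20.8)
(`mean_ci_original_scale()`).

## The trajectory model

The NP-Batt composite is the mean of nine subtest z-scores standardized
against cognitively normal controls (`compute_np_batt()`). Trail Making B
is a timed test where lower is better; it is sign-flipped so that a higher
composite always means better performance — an orientation the package
asserts rather than inherits, since composite definitions in the literature
leave it implicit.

The model is a linear mixed model with random intercepts and random slopes
against time, with time coded as the **visit number in units of 6 months**:
months 0, 6, 12, 18, 24, 36 are visits 0, 1, 2, 3, 4, 6, and there is no
month-30 visit, hence no visit 5. All slopes are changes per visit; a
per-year effect is twice the per-visit effect. `fit_trajectory()` can refit
on the month scale (`time_unit = "month"`), which rescales every slope term
by exactly 1/6 — a useful consistency check.

Selection starts saturated (every candidate main effect, every
candidate-by-time interaction, random intercepts and slopes). The random
structure is settled first by a likelihood-ratio test of random slopes
against intercepts only, on ML refits, using the naive χ² with 2 df. This
reference is conservative at the variance boundary; the 50:50 mixture
alternative would halve the p-value, but any dataset with real slope
heterogeneity rejects at p ≪ 0.0001 either way, so the simpler reference
was kept. Fixed effects are then eliminated backward by Wald tests —
time interactions first, then main effects, largest p first, removal at
p > 0.05 — under a strict marginality rule: a main effect (including the
time slope itself) is never removed while any retained interaction contains
it. This is why a non-significant main slope stays in a model that keeps
time interactions. Finally, pairwise interactions of the surviving main
effects are screened singly and pruned the same way. Wald p-values use the
normal reference rather than Satterthwaite degrees of freedom: the cohorts
this package targets have hundreds of subjects and over a thousand
observations, where the two are indistinguishable, and the normal reference
is deterministic and fast. Variance components are REML-estimated.

**Marginal variability.** A single observation at visit t has SD
√(σ₀² + t²σ₁² + 2tρσ₀σ₁ + σ_w²) (`marginal_sd()`), combining random
intercept (σ₀), random slope (σ₁, correlation ρ) and within-subject noise
(σ_w). With the packaged reference fit this runs from 0.311 at baseline to
0.60 at month 36. Note the direct arithmetic at t = 0 gives 0.311 even
though the source literature quotes a lower endpoint of 0.32; the package
implements the standard marginal-variance formula and documents the small
discrepancy rather than reverse-engineering an alternative.

**Power by simulation.** `simulate_power_trajectory()` generates paired
control and treated arms from the fitted model over freshly drawn synthetic
cohorts (treated slope improved by δ z-units per visit), fits a reduced
mixed model `y ~ arm * time + (time | id)` per replicate, and counts
rejections of the arm-by-time Wald test. The published workflow reused the
observed cohort's covariates as the control arm; this package must draw
covariates from the synthetic generator instead, which is the main reason
power comparisons carry a tolerance. With the packaged reference fit,
δ = 0.02 per visit (0.04 per year) and 400 subjects per arm, power is
about 0.80–0.83 at 500 simulations.

## The synthetic cohort generator

`generate_baseline()` draws from a Gaussian copula: a latent multivariate
normal vector is mapped through each covariate's marginal quantile
function. The default marginals reproduce the published baseline table of
the 397-subject ADNI MCI cohort: age N(74.2, 7.4); 36% women; education
N(15.7, 3.0); BMI N(26.1, 4.0); ApoE4 counts with probabilities
185/165/47 out of 397; MMSE N(27.0, 1.8) truncated to the 24–30 inclusion
window (the truncation shrinks the realized SD to about 1.5, a necessary
consequence of honoring both the printed moments and the eligibility
window); modified ADAS-cog N(18.6, 6.3); NP-Batt N(−1.02, 0.66); 60%
medication use. Where only a median and range are published, a shape had to
be chosen once: Hachinski is a truncated negative binomial (size 2,
mean 1.3) on 0–4 matching the median of 1, FAQ a truncated negative
binomial (size 0.8, mean 3.2) on 0–21 matching the median of 2, and the
CSF Aβ42/T-tau ratio a log-normal with median 1.564 and log-SD 0.6 matching
the printed range, generated for a random half of subjects to mirror the
lumbar-puncture subsample.

The default latent correlations couple only the cognitive measures
(ADAS-cog with NP-Batt −0.6, ADAS-cog with MMSE −0.4, FAQ with NP-Batt
−0.3); all other pairs are independent. These are assumptions — the source
cohort's covariate correlations are not published — and they are
configurable via `dependence_spec()`. Two consequences are worth knowing.
First, these correlations make the baseline ADAS-cog's variance inflation
factor about 2.2 on synthetic cohorts, higher than the "all below 1.70"
reported for the real cohort; the synthetic copula is deliberately simple,
not calibrated to replicate the real multicollinearity profile. Second, the
synthetic covariates carry slightly less outcome-relevant spread than the
real ones: the endpoint model explains about 61% of square-root-scale
variance on synthetic cohorts versus 63% reported on the source data, and
simulated month-24 ADAS-cog sample SDs land near 9.5 rather than the
published 10.5. Distribution-level comparisons against published simulated
descriptives should therefore be read as order-of-magnitude checks, not
reproductions.

Dropout (`apply_dropout()`) is missing-completely-at-random with per-visit
retention probabilities; the source cohort's actual missingness mechanism
is unknown, and no MNAR machinery is provided.

## Packaged reference artifacts

Three JSON artifacts ship with the package (`pgsa_example_fit()`): the
endpoint regression (n = 286, residual SD 0.669), the trajectory model
(375 subjects) and its CSF variant (189 subjects), each carrying the
published coefficient tables and variance components. The published tables
print standard errors but not the parameter covariance, so each artifact's
covariance matrix is the **diagonal** of squared standard errors. This is a
synthetic approximation with a real consequence: the true covariance has
large negative off-diagonals (intercept against MMSE and ADAS-cog terms,
for instance), so the diagonal version grossly overstates the
replicate-to-replicate dispersion of simulated *group means* while leaving
within-replicate dispersion essentially untouched. Analyses in this package
that depend on replicate-mean stability therefore either average
within-replicate statistics over replicates or disable the parameter draw
(`parameter_uncertainty = FALSE`); users substituting their own fitted
artifacts (where `vcov` is the genuine estimate) are unaffected.

## What the tests do and do not show

The package's tests demonstrate, on synthetic data: exact reproduction of
the closed-form quantities (analytic power, back-transformed effects,
precision arithmetic); parameter recovery of both models from data
generated under the published coefficients (5,000 subjects for the
endpoint model, 2,000 for the trajectory model, all coefficients within
3 SE); agreement of the simulators with their closed-form moments
(marginal SDs within 2% at 10,000 subjects; Monte-Carlo endpoint power
within Monte-Carlo error of the analytic formula); calibration of the
arm-by-time test under the null; and ~80% power for the 0.02-per-visit
slope effect at 400 per arm. Problem sizes were chosen so the full suite
runs in a few minutes: 500 power simulations (the published analysis used
1,000), 200 replicates for distribution bands, 10,000 subjects for moment
checks.

What passing tests do **not** show: that the published coefficient values
are recoverable from real data (no real data are bundled); that the
synthetic cohort reproduces the real covariate joint distribution (it
matches marginals plus an assumed copula, and demonstrably differs in
multicollinearity and explained variance); or that MCAR dropout reflects
real attrition. Degenerate inputs are handled explicitly: zero variance
components collapse the simulators to their deterministic means, perfectly
collinear predictors report infinite VIF with a warning, singular
random-effect fits are flagged rather than hidden, and illegal visit
numbers (including month 30) are rejected at the schema boundary.
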