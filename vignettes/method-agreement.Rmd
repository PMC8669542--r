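---
title: "Latent-variable agreement analysis for two repeated binary delirium instruments"
author: "camagree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable agreement analysis for two repeated binary delirium instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camagree)
```

## The problem

Postoperative delirium in older surgical patients is commonly ascertained
with the long-form Confusion Assessment Method (CAM) and, increasingly,
with its abbreviated screening derivative, the 3-Minute Diagnostic
Interview for CAM (3D-CAM). When two assessors administer both instruments
to the same patient at the same time, repeatedly over postoperative days,
the question is whether the instruments agree — overall and on each of the
four cardinal delirium features (acute change and fluctuating course,
inattention, disorganized thinking, altered level of consciousness).

The data are binary, repeated within patient, and crossed with a pool of
raters, so naive per-occasion agreement statistics conflate three sources
of variation: patients, raters, and the instruments themselves. `camagree`
separates them with a generalized linear mixed model and derives all
agreement summaries from that model.

## The model

For assessment $t$ of patient $i$ by rater $r$ with instrument
$m \in \{\mathrm{CAM}, \mathrm{3DCAM}\}$:

$$\mathrm{logit}\,P(y_t = 1) = \beta_0 + \beta_m \mathbf{1}[m = \mathrm{3DCAM}] + b_i + d_{im} + c_r$$

with independent random effects
$b_i \sim N(0, \sigma_p^2)$ (patient propensity),
$d_{im} \sim N(0, \sigma_d^2)$ (patient-by-method deviation, one draw per
patient per instrument, shared SD), and
$c_r \sim N(0, \sigma_r^2)$ (rater). $\beta_m$ is the method effect: a
positive value means the 3D-CAM scores positive more often than the CAM on
the same latent patient state.

Assumptions worth stating plainly: occasions within a patient are
exchangeable given $(b_i, d_{im})$ — there is no occasion-level or serial
term, which matches the way the agreement summaries are defined (one latent
value per patient per method, repetition acting only as within-patient
replication); a rater has a single effect $c_r$ regardless of which
instrument they administer (raters were cross-trained on both); and the
random effects are Gaussian on the logit scale.

### Estimation

The marginal likelihood integrates the random effects out of a Bernoulli
likelihood; there is no closed form. The fitter maximizes an approximate
marginal likelihood over $(\beta_0, \beta_m, \log\sigma)$:

* **Adaptive Gauss–Hermite quadrature** (default order 15) whenever rater
  effects are absent. The likelihood then factorizes over patients:
  patient-intercept-only models integrate one dimension per patient;
  patient + patient-by-method models integrate the correlated bivariate
  effect $a_{im} = b_i + d_{im}$ (variance $\sigma_p^2 + \sigma_d^2$,
  covariance $\sigma_p^2$) on an adaptive tensor grid centered on each
  patient's conditional mode. On five-patient fixtures this agrees with
  dense brute-force grid integration (`marginal_loglik_bruteforce`) to
  better than $10^{-3}$, typically $10^{-8}$.
* **Laplace approximation** for designs with crossed rater effects, where
  the likelihood does not factorize: a penalized Newton solve for all
  random-effect modes (sparse Cholesky) plus the Gaussian curvature
  correction. The Laplace log-likelihood carries a genuine approximation
  error on clusters with few binary observations (of order $10^{-1}$ on a
  4-patient, 6-observation-per-cluster fixture), which is why the
  brute-force oracle bound is asserted on the quadrature paths; the Laplace
  path is instead verified against an independent implementation of the
  same approximation (`lme4::glmer`), with agreement to about $10^{-4}$.
* A spec without random terms reduces to ordinary logistic regression
  fitted by the same optimizer and is checked against `stats::glm`.

Outer optimization runs Nelder–Mead, then a quasi-Newton refinement, then a
damped Newton polish on numeric gradients until the gradient infinity-norm
is below `grad_tol` (default $10^{-5}$). Variance components are optimized
as $\log\sigma$ with a floor at $\sigma = 10^{-6}$; a component ending on
the floor is reported as exactly 0 with a `boundary` flag rather than as a
convergence failure — singular fits (notably $\hat\sigma_r = 0$) are
common and legitimate in this design. There is a matching ceiling at
$\sigma = 10$: binary responses can be *quasi-separated at a random-effect
level* (every replicate within a patient, or within a patient-method cell,
concordant), in which case the marginal likelihood is monotone in that SD
and the estimate diverges along an asymptotically flat ridge. The fit then
stops at the ceiling, warns, and is flagged `boundary_upper`; downstream
summaries that only need the *share* of variance (the ICC, which tends to
1 in this regime) remain meaningful, while the component itself should be
reported as "not identified" rather than as a number. Wald covariance
comes from the numeric Hessian of the approximate log-likelihood at the
optimum, with boundary coordinates profiled out.

A note on reproducibility tolerances: relabeling patients or raters changes
summation order and therefore the floating-point path of the optimizer.
With the default tolerances the refitted optimum matches to about
$10^{-6}$ in $\beta$ and $10^{-4}$ in $\sigma^2$; exact bitwise invariance
is not attainable for an iterative fit on a likelihood this flat in
$\log\sigma$, and the tests assert invariance at those scales.

## Agreement summaries

**Latent pairs.** For each patient the fitted model yields a pair of
model-estimated continuous outcomes per instrument,
$\eta_{im} = \hat\beta_0 + \hat\beta_m + \hat b_i + \hat d_{im}$, using
empirical-Bayes posterior modes (the natural by-product of the Laplace /
adaptive-quadrature fits; posterior means are not used). Rater effects are
set to their population mean 0, so the pair describes the patient-by-method
propensity free of the particular assessor. Probabilities
$p = \mathrm{logit}^{-1}(\eta)$ and log-probabilities $\log p$ are carried
alongside.

**Bland–Altman.** One (average, difference) point per patient with the
difference oriented CAM − 3DCAM, on either the probability or the
log-probability scale. The mean difference carries a normal CI
($\bar d \pm 1.96\, s_d/\sqrt{n}$; one point per patient, so independence
is reasonable) and 95% limits of agreement $\bar d \pm 1.96\, s_d$. The
default scale policy uses the log-probability scale for the overall
outcome and for altered level of consciousness (whose probability-scale
differences are strongly skewed) and the probability scale for the other
three features; a skewness check ($|g_1| > 1$ suggests the log scale) is
advisory only — it logs a message and never switches scales on its own.

**Probability ratio.** On the log scale, $e^{\bar d}$ is the probability
of a positive CAM relative to a positive 3D-CAM, with CI $e^{\text{CI}}$.
The inverse ratio follows the reciprocal-of-rounded-values reporting
convention: a forward ratio printed as 0.36 inverts to $1/0.36 = 2.78$,
not $e^{-\bar d}$ — the two differ in the second decimal and the package
reproduces the printed convention exactly, including swapped CI endpoints.

**Cohen κ.** The latent pair is dichotomized at $p \ge 0.5$ (ties
positive; the threshold is configurable) and the resulting one-pair-per-
patient 2×2 table gives
$\kappa = (p_o - p_e)/(1 - p_e)$. The default CI is a patient-resampling
bootstrap of the latent pairs (percentile interval, $B = 2000$); a full
refit bootstrap (`refit_bootstrap`) resamples patients' assessment records
and refits the GLMM per replicate for callers who want the fit uncertainty
propagated — it is substantially more expensive. Interpretation bands
follow the over-0.75-substantial convention (0.40–0.75 moderate, below
0.40 poor), with the band table configurable; 0.75 itself falls in
"moderate" because the convention is strict ("over 0.75").

**ICC.** From a single-instrument patient + rater model,
$\mathrm{ICC} = \sigma_p^2 / (\sigma_p^2 + \sigma_r^2)$: the patient share
of latent variation, i.e. interrater reliability. The residual-inclusive
variant adds the logistic residual variance $\pi^2/3$ to the denominator;
both conventions exist in the literature, and the default excludes it
because the non-patient share is attributed to raters. The choice matters:
$(\sigma_p^2, \sigma_r^2) = (4, 1)$ gives 0.80 without and 0.48 with the
residual term, so reported ICCs must name their convention.

## The synthetic cohort generator

There is no deposited patient-level dataset, so `simulate_cohort` is a
first-class module that draws cohorts from exactly the generative model
above. `study_emulating_config()` fixes the realized structure to 299
patients, 471 concurrent assessment pairs and 16 raters for every seed by
embedding the occasion multiset (191 patients with one occasion, 68 with
two, 24 with three, 10 with four, 4 with five, 2 with six) instead of
sampling occasion counts. Its default parameters — $\beta_0 = -2$,
$\beta_m = +0.7$, $\sigma_p = 2$, $\sigma_r = 0.3$, $\sigma_d = 0.5$ —
are illustrative values chosen once to reproduce the qualitative study
regime: a positive-rate around 20% for the CAM, higher for the 3D-CAM,
per-instrument ICCs above 0.9, and an overall latent-pair κ well above the
acute-change feature κ. The per-feature intercepts and method effects
follow the direction of the published feature discordance (the CAM scores
acute change and altered level of consciousness more often; the 3D-CAM
scores inattention and disorganized thinking more often). Administration
durations are rounded log-normal draws targeting medians of 3 minutes
(3D-CAM) and 8 minutes (CAM).

What the generator deliberately does **not** emulate: fluctuating delirium
time courses (occasions are exchangeable), item-level questionnaire
responses, informative missingness or dropout, rater drift or learning,
and any dependence between features beyond the shared patient and rater
effects. Passing tests on these cohorts therefore demonstrates that the
estimation and summarization machinery is correct under the model's own
assumptions — not that the model is adequate for any particular real
cohort.

## Numerical and design choices

* Convergence: outer gradient infinity-norm below $10^{-5}$ and relative
  log-likelihood change below $10^{-8}$, maximum 500 outer evaluations;
  inner (mode-finding) Newton tolerance $10^{-10}$ with step-halving, so
  accepted penalized log-likelihood values never decrease.
* Complete separation (a constant response within an instrument arm) is
  detected up front and raised as an informative error rather than left to
  diverge.
* The brute-force oracle integrates on a trapezoidal tensor grid spanning
  ±10 prior SDs (401 nodes per dimension in 1-D, 161 in 2-D); refining the
  grid moves the result by less than $10^{-6}$. It refuses crossed rater
  designs, where the likelihood does not factorize by patient, and more
  than 5 patients.
* The Bland–Altman mean-difference CI uses the empirical SD over patients.
  When the generative method effect is exactly null and the
  patient-by-method SD is zero, every latent difference is proportional to
  $\hat\beta_m$, so for null-effect checks the Monte-Carlo SE of the mean
  difference is obtained by propagating the Wald SE of $\hat\beta_m$
  through the scale transform (delta method) instead.
* Bootstrap replicates with undefined κ (a constant margin) are redrawn,
  capped at $10B$ draws.
* Orphan occasions (one instrument missing) are reported, never silently
  dropped; a shared rater across a pair warns by default and can be
  promoted to an error.

## Problem sizes used by the tests

The test-suite simulations are sized to exercise the asymptotics the
checks rely on while staying desk-scale: parameter recovery uses 50
replicates of 300 patients × 2 occasions × 16 raters; the κ-CI coverage
check uses 50 replicates of 150 patients × 3 occasions against a
$10^6$-patient Monte-Carlo limit of the same estimator; marginal-rate
convergence uses 5 000 patients; oracle-equivalence fixtures use 3–5
patients. The full study-shaped cohort (299/471/16) is used for the
regime-level checks and the analysis scripts.

## A worked run

```{r example, eval = FALSE}
tab <- simulate_cohort(study_emulating_config(seed = 1))
summarize_cohort(tab)

icc <- instrument_reliability(tab)
icc$CAM$icc; icc$`3DCAM`$icc

agr <- feature_agreement(tab, "delirium")
agr$test         # method fixed effect, Wald CI and p-value
agr$ba           # Bland-Altman on the log-probability scale
agr$ratio        # P(CAM+) / P(3DCAM+), with the inverse convention

k <- cohen_kappa(dichotomize_pairs(agr$pairs))
k$ci <- as.numeric(kappa_ci(tab, agr$fit, B = 2000, seed = 1))
k
```

The numbered scripts under `analysis/` run the same sequence end to end
and write their tables under `results/`.

## Known limitations

* The Laplace path's approximation error is not bounded by an internal
  oracle on crossed designs; it is cross-checked against an independent
  implementation of the same approximation instead.
* Wald intervals ignore uncertainty in the variance components beyond the
  numeric-Hessian coupling, and empirical-Bayes dichotomization shrinks
  borderline patients toward the population mean — the κ estimand is the
  large-sample value of this estimator, not the κ of the true latent
  states.
* Only two instruments are supported; no MCMC or non-logit links; no
  occasion-level (disaggregated) Bland–Altman.
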