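# camagree

Method-agreement analysis for two binary delirium instruments — the
long-form Confusion Assessment Method (CAM) and the 3-Minute Diagnostic
Interview for CAM (3D-CAM) — scored concurrently and repeatedly by
multiple raters in older surgical patients.

Per-occasion agreement statistics conflate patient heterogeneity, rater
effects, and true instrument disagreement. `camagree` separates them with
a Bernoulli-logit generalized linear mixed model,

    logit P(y = 1) = β₀ + β_m·1[m = 3DCAM] + b_i + d_im + c_r,
    b_i ~ N(0, σ_p²),  d_im ~ N(0, σ_d²),  c_r ~ N(0, σ_r²),

and derives every agreement summary from the fitted model:

* **Interrater reliability** per instrument as the intraclass correlation
  ICC = σ_p² / (σ_p² + σ_r²), the patient share of latent variation
  (optionally with the logistic residual π²/3 in the denominator).
* **Method agreement** as the Wald test of the method fixed effect β_m.
* **Latent-variable Bland–Altman**: one model-estimated (CAM, 3D-CAM)
  outcome pair per patient from the empirical-Bayes modes, plotted as
  (average, difference = CAM − 3DCAM) with mean difference, its 95% CI,
  and 95% limits of agreement, on the probability or log-probability
  scale. On the log scale, exp(mean difference) is the probability of a
  positive CAM relative to a positive 3D-CAM.
* **Cohen κ** of the dichotomized latent pairs (threshold 0.5), with a
  patient-resampling bootstrap CI and the over-0.75-substantial
  interpretation bands.

Models are fitted by adaptive Gauss–Hermite quadrature (patient-level
designs; verified against a brute-force integration oracle to < 1e-3) or
the Laplace approximation (crossed rater designs; verified against
`lme4::glmer`). A synthetic cohort generator reproduces the study's
structure — 299 patients, 471 concurrent assessment pairs, 16 raters —
for testing, parameter recovery, and demonstration; there is no deposited
patient-level dataset.

## Worked example

```r
library(camagree)

tab <- simulate_cohort(study_emulating_config(seed = 1))
summarize_cohort(tab)
#> Cohort summary
#>   patients: 299  concurrent pairs: 471  raters: 16
#>   delirium positive: CAM 118  3D-CAM 160
#>   median duration (min): CAM 8  3D-CAM 3

icc <- instrument_reliability(tab)
c(icc$CAM$icc, icc$`3DCAM`$icc)
#> [1] 0.9835215 1.0000000

agr <- feature_agreement(tab, "delirium")
agr$test
#> method: 0.726 (95% CI 0.350 to 1.102), P = 0.000152
agr$ba
#> Bland-Altman (log_probability scale, CAM - 3DCAM), n = 299
#>   mean difference -0.542 (95% CI -0.561 to -0.522)
#>   95% limits of agreement -0.885 to -0.198
agr$ratio
#> P(CAM+) / P(3DCAM+): 0.58 (95% CI 0.57 to 0.59)
#>   inverse: 1.72 (95% CI 1.69 to 1.75)

k <- cohen_kappa(dichotomize_pairs(agr$pairs))
k$ci <- as.numeric(kappa_ci(tab, agr$fit, B = 2000, seed = 1))
k
#> Cohen kappa: 0.89 (substantial), 95% CI 0.82 to 0.95
#>   p_observed 0.967, p_expected 0.691, n = 299
#>   2x2: both+ 52 | CAM+ only 0 | 3DCAM+ only 10 | both- 237
```

Reading this: a positive method effect (β̂_m = 0.73) means the 3D-CAM
scores delirium-positive more often than the CAM on the same latent
patient state; the negative log-scale mean difference says the same thing
in probability terms (a positive CAM is 0.58 times as probable as a
positive 3D-CAM in this simulated regime); both instruments have high
interrater reliability (ICC ≈ 0.98 and 1.00); and the dichotomized latent
pairs agree substantially (κ = 0.89).

The numbered scripts in `analysis/` run this sequence end to end
(simulate → reliability → method agreement → κ → consolidated report) and
write their tables under `results/`. The methods vignette
(`vignettes/method-agreement.Rmd`) documents the model, the estimation
machinery, the reporting conventions, and what the synthetic cohorts do
and do not emulate.

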