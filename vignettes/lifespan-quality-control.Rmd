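---
title: "Quality control of animal lifespan data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of animal lifespan data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanqc)
```

## The problem

Control cohorts in rodent lifespan studies are strikingly inconsistent across
laboratories: published median lifespans of male C57BL/6J controls span
several hundred days, far more than the ~15% extension a "successful"
intervention typically delivers. Two distinct failure modes hide in this
spread. *Intra-study* artifacts — a cage flood, an infection, a husbandry
lapse — kill many animals on a single day and distort the survival curve from
within. *Inter-study* implausibility — a control cohort whose entire survival
pattern sits far outside the range of comparable high-quality controls —
makes any treatment comparison against it suspect. `lifespanqc` implements
one test for each failure mode, plus a harmonized "balanced meta-control"
against which new treatments can be scored.

## Data model

A cohort is a set of per-animal records `(time in days, event)` with
`event = 1` for an observed death and `0` for right censoring, together with
the *measurement grid*: the days on which cages were actually checked. Deaths
are only discovered at checks, so all recorded times live on the grid; the
generator and the file reader both enforce this. Files carry a `#key=value`
metadata header (strain, sex, source, control/treatment, …) over a CSV body
in either a per-animal (`long`) or a per-check-count (`counts`) layout; times
given in weeks or months are converted to days on read (×7, ×30.44). The
grid is always written into the header so that checks with zero deaths
survive a round trip.

## Survival estimation

The nonparametric estimates are the standard Kaplan–Meier product-limit
survival curve and the Nelson–Aalen cumulative hazard, evaluated on the full
grid with the deaths-before-censorings tie convention. Both are computed
directly from per-grid-time death/censor counts, which is what the
resampling test needs in bulk; the test suite cross-checks them against
`survival::survfit` and brute-force oracles.

Two parametric families model rodent mortality:

* **Weibull**, `S(t) = exp(-(t/λ)^ρ)` with scale `λ` (days) and unitless
  shape `ρ`; median `λ (ln 2)^{1/ρ}`. A typical male C57BL/6J control is
  near `λ ≈ 900`, `ρ ≈ 6` (median ≈ 847 d).
* **Gompertz**, hazard `h(t) = a e^{bt}` with baseline hazard `a` (1/days)
  and actuarial aging rate `b` (1/days) — the classical law of exponentially
  accelerating mortality.

Both are fitted by maximizing the right-censored log-likelihood
`Σ_deaths log h(tᵢ) + Σ_all log S(tᵢ)` over log-parameters (guaranteeing
positivity) with analytic gradients and BFGS at a relative tolerance of
1e-8; up to five deterministic jittered restarts guard against bad starting
points before a non-convergence error is raised. Starting values are cheap
and deterministic: the Weibull shape from the slope of `log(-log Ŝ)` against
`log t` over interior Kaplan–Meier points and the scale from the median
death time; the Gompertz rate from a log-hazard regression on Nelson–Aalen
increments, with `a` matched to the empirical cumulative hazard at the
median. Standard errors and the parameter covariance come from the inverse
observed information, mapped to the natural scale by the delta method — the
convention mainstream survival libraries use.

One deliberate approximation: recorded (grid-binned) times enter the
likelihood as exact event times rather than as intervals. At weekly checks
this shifts the fitted scale by roughly half a grid step (≈ 0.4% at
`λ ≈ 900`), identically for every cohort analyzed, so comparisons between
cohorts are unaffected.

## The intra-study extra-mortality test

The test statistic is the maximal downward derivative of the Kaplan–Meier
curve over grid intervals, `max_k (Ŝ(t_{k-1}) - Ŝ(t_k))/(t_k - t_{k-1})`
with `t₀ = 0, Ŝ(0) = 1`. On a uniform grid this orders cohorts exactly like
the bare maximal vertical step; the derivative form extends the statistic to
irregular check schedules. The null distribution comes from the parametric
fit itself: 1000 cohorts of the original size are drawn from the fitted
Weibull (and/or Gompertz) model, binned onto the *original* measurement grid
— a death between checks is discovered at the next check — and the statistic
recomputed for each. The p-value is the plus-one resampling form
`p = (1 + #[resampled ≥ observed])/(N + 1)`, with ties counted toward
rejection (conservative), and a model's verdict is *failed* at `p ≤ α` with
`α = 0.01` by default. By default the cohort fails overall only if it fails
under **every** tested model: a single adequately fitting model that explains
the largest drop means there is no unexplained excess; a switch flips this
to the "any model rejects" rule.

Resampled cohorts contain deaths only. Censoring influences the null only
through the parametric fit, because resampling censoring patterns would
require a censoring model the data do not identify; the function says so
when more than 10% of the input records are censored.

The plus-one construction makes the test super-uniform under exchangeability,
and fitting the null to the same data adds conservatism: simulated clean
Weibull cohorts (n = 50, weekly checks) are flagged at roughly half the
nominal 1% level, while a single-day spike reassigning 30% of deaths is
caught essentially always (the acceptance suite measures both).

## The balanced meta-control

Each accepted control cohort contributes its Weibull `(λ̂ᵢ, ρ̂ᵢ)` with
standard errors. Per parameter, the estimates are combined by
inverse-variance meta-analysis: fixed-effects weights `wᵢ = 1/SEᵢ²`, or (the
default) DerSimonian–Laird random effects, which adds the closed-form
between-study variance `τ̂² = max(0, (Q - (k-1))/(Σw - Σw²/Σw))` and weights
`wᵢ* = 1/(SEᵢ² + τ̂²)`. The combined `(λ̄, ρ̄)` define the *meta-Weibull* — a
hypothetical harmonized control — and a treated cohort is scored by the
percent change of its fitted Weibull median against the meta-Weibull median
(the nonparametric KM median is reported alongside for transparency).
Uncertainty comes from a joint bootstrap (default 2000 replicates):
resample-and-refit the treated cohort, and draw `(λ̄, ρ̄)` from Gaussians
with their combined standard errors; the 95% percentile interval of the
replicated percent changes is returned. `λ` and `ρ` are combined
independently — per-parameter intercept-only meta-regression — because each
arrives with its own standard error; a joint combination with
cross-parameter meta-covariance would need the per-study sampling
covariances to be comparable across heterogeneous studies and is left out.

## The inter-study plausibility test

High-quality control cohorts define a *reference distribution*: a 2-D
Gaussian over `(λ, ρ)` with weighted mean and covariance, each study
weighted by its inverse squared standard errors. Marginal variances use the
reliability-weight bias correction `Σw(x - x̄)²/(Σw - Σw²/Σw)`; the
cross-covariance uses pairwise weights `uᵢ = √(wᵢ^{(λ)} wᵢ^{(ρ)})` — the
geometric mean preserves the inverse-variance scale and symmetry — with the
analogous correction, centered on the reference mean vector so the matrix is
centered consistently with the mean it is used with. At least five reference
studies are required: the F reference below needs `n ≥ 3`, and fewer than
five gives a covariance too unstable to mean anything.

A new cohort's fit `θ̂ = (λ̂, ρ̂)` is tested via the squared Mahalanobis
distance `d² = (θ̂ - μ)ᵀ Σ⁻¹ (θ̂ - μ)`. Because `μ` and `Σ` are estimated
from `n` studies and the cohort is one further observation, the default uses
the one-new-observation Hotelling form `T² = d² · n/(n+1)` referred to
`T²(n-p)/(p(n-1)) ~ F(p, n-p)` with `p = 2`, which is the correct
small-sample reference at the study counts (5–20) this test will actually
see; a `χ²₂` approximation is available as an option and agrees for large
`n`. The p-value is the plausibility score: `p > α` (default 0.01) means
*plausible*, otherwise *outlier*. The Mahalanobis form makes the score
invariant under common affine rescalings — testing in weeks instead of days
changes nothing — and the score decays monotonically along any ray from the
reference mean.

Two numerical remedies keep the test defined on pathological references: a
non-positive-definite covariance (possible because the three weighted
moments are estimated with three different weight sets) gets a ridge of
`1e-6 ×` mean diagonal plus the negative-eigenvalue deficit; a reference of
numerically identical fits gets a parameter-scale ridge instead, since its
own diagonal carries no scale information. Both warn loudly.

A calibration caveat worth stating honestly: inverse-squared-SE weights are
correlated with the estimates themselves (a Weibull fit's standard errors
scale with its parameters), which shrinks the weighted covariance slightly
relative to the true dispersion of fitted parameters. In simulations at the
package's default conditions the net rejection rate of same-population
controls stays near the nominal 1% — the conservative small-`n` F reference
offsets the shrinkage — but any single small reference panel can sit
noticeably above or below it, exactly as a practitioner should expect when
conditioning on 20 studies.

## The synthetic-data generator

`generate_cohort()` emulates the study conditions every calibration result
in this package refers to: death times from Weibull (default `λ = 900` d,
`ρ = 6`, a typical male C57BL/6J control) or Gompertz; checks every
`grid_spacing` days (default 7 — weekly cage checks, with daily checks
available); optional right censoring of a chosen fraction at a uniform time
before death (a simple noninformative mechanism — real censoring, e.g.
moribund sacrifice, is usually informative); and an optional single-day
spike that *reassigns* a chosen fraction of the observed deaths to one day,
preserving cohort size, as a husbandry accident would.
`generate_population()` adds the inter-study layer: per-study `(λᵢ, ρᵢ)`
from a 2-D Gaussian (default mean `(880, 6)`, standard deviations 40 d and
0.5 — the order of heterogeneity seen across published C57BL/6J controls),
rejection-truncated to the positive quadrant (negligible at these means).

What the generator does *not* emulate bounds what green tests can claim:
no informative censoring, no cage or batch effects, no seasonal or
age-dependent check schedules, no multi-day die-offs, and real lifespan data
need not be Weibull at all. Passing calibration here shows the tests behave
correctly *when their assumptions hold*; on real data the parametric
approximation itself is part of what the extra-mortality test probes.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state. The calibration studies shipped with the package use: 2000
same-population cohorts against a 20-study reference for the plausibility
test's rejection rate; 2000 clean cohorts (n = 50, 1000 resamples each) for
the extra-mortality false-positive rate; 200 spiked cohorts for its power;
500 cohorts of n = 100 for standard-error calibration; and exhaustive
enumeration of all death/censoring patterns on up to six animals for the
product-limit oracles. `scripts/acceptance.R` re-runs the two calibration
studies end to end from a single seed.

## Known limitations

* Binned times are treated as exact in the parametric likelihoods (see
  above); at daily checks the distinction vanishes.
* The balanced meta-control harmonizes studies of one strain and sex; it
  does not model covariates (diet, temperature, vendor), which is exactly
  why implausible controls must be filtered *before* pooling.
* The extra-mortality test localizes nothing: it flags that an implausible
  drop exists, not when or why.
* The plausibility verdict inherits the quality of the reference panel;
  five studies is a floor, not a recommendation.
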