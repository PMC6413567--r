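---
title: "Methods: measurement-noise and seasonality correction of diet-adherence indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measurement-noise and seasonality correction of diet-adherence indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the choices that were genuinely open and how they were settled, and
what the shipped validation does and does not establish.

## 1. Setting

A two-arm dietary intervention trial measures a 0–160 adherence index
(the sum of sixteen continuous 0–10 component scores) twice per subject —
at recruitment (T0) and 10–14 months later (T1) — by self-completed 7-day
food records, in five countries. One week of diary is a noisy draw from a
subject's habitual diet, so the observed index is the latent adherence
plus measurement error of roughly the same magnitude as the spread between
subjects. Two artifacts follow: a spurious negative correlation between
baseline and observed change (regression to the mean), and leakage of
yearly seasonal variation into the estimated intervention effect whenever
visit pairs are not exactly a year apart.

## 2. The regression-to-the-mean null model

With true baselines standardised to $B \sim N(0,1)$, an optional
between-visit change $C \sim N(0,1)$, and measurement noise
$e_0, e_1 \sim N(0, \lambda)$ added independently at both visits
($T_0 = B + e_0$, $T_1 = B + C + e_1$), the correlation between $T_0$ and
$T_1 - T_0$ has the closed forms

$$r(\lambda) = \frac{-\lambda^2}{\sqrt{(1+\lambda^2)(1+2\lambda^2)}}
\quad\text{(with change)},\qquad
r(\lambda) = \frac{-\lambda}{\sqrt{2(1+\lambda^2)}}
\quad\text{(without)},$$

both $0$ at $\lambda = 0$ and $\to -1/\sqrt2$ as $\lambda \to \infty$.
`simulate_null()` draws the Monte-Carlo version of this curve;
`expected_correlation()` is the closed form, and the test suite requires
agreement within three Monte-Carlo standard errors at every grid point.
`invert_curve()` maps an observed correlation back to $\hat\lambda$ by
monotone (isotonic-rearranged) piecewise-linear interpolation of the mean
curve, breaking flat ties toward the smaller $\lambda$; its interquartile
range comes from inverting each per-replicate curve, which propagates the
sampling noise of a study of the configured size.

*Which variant is canonical?* The change term is part of the model's
description, so `include_change = TRUE` is the default everywhere. Both
variants are nevertheless exposed: inverting a correlation of $-0.49$
gives $\hat\lambda \approx 1.29$ with the change term and $\approx 0.96$
without, and published analyses of this design have reported intermediate
values, so fixing one variant silently would hide a real sensitivity. At
$\lambda = 0$ without the change term the difference is exactly zero and
its correlation undefined; the simulator reports 0, the noise-free limit.

## 3. The hierarchical observation model

For subject $i$ in country $c(i)$ with visit-date year fractions
$t_{0i}, t_{1i}$:

$$y_{0i} \sim N\!\big(b_i + s_{c(i)}(t_{0i}),\ \sigma_\text{meas}\big),
\qquad
y_{1i} \sim N\!\big(b_i + a_i d_i + s_{c(i)}(t_{1i}),\ \sigma_\text{meas}\big)$$

* $b_i \sim N(B_{c(i)}, \sigma_\text{between})$ — latent subject baselines
  around their country centre. The baseline layer is a **single**
  hierarchical level (independent weakly informative priors per country
  centre, no common hyper-mean): pooling baselines across countries is
  deliberately avoided because one clearly outlying country would either
  be over-shrunk or destabilise the shared level.
* $d_i \sim N(D_{c(i)}, \sigma_\text{effect})$ with
  $D_c \sim N(D, \sigma_\text{country})$ — a **two-layer** effect
  hierarchy; a Student-t option for the country level
  (`robust_effects = TRUE`, default off) is available as an
  outlier-robustness toggle.
* $a_i$ is 1 for intervention subjects and the participation drift
  fraction for controls (default 0.05: controls are assumed to experience
  about 5% of the intervention effect merely by being studied). The drift
  can alternatively be estimated under a tight truncated-normal prior
  (`estimate_drift = TRUE`).
* $s_c(t) = w^{s}_c \sin 2\pi t + w^{c}_c \cos 2\pi t$ — one yearly
  harmonic per country, **additive** on the index scale (the minimal
  reading of "seasonality modifies the average index during the year";
  shorter periods add complexity for no practical value at two visits per
  subject). Weights are pooled hierarchically around shared weights.
  Seasonality is a country-level effect: with two visits per subject an
  individual seasonal effect is not identifiable.

The Normal likelihood is justified by the index being a sum of sixteen
bounded components; observed scores are accordingly *not* clipped to
[0, 160] anywhere (clipping would bias the variance components).

**Priors** (all exposed in `model_spec()`, units = index points):
country baseline centres $N(80, 20)$; global effect $N(0, 20)$; all
standard deviations half-Normal$(0, 20)$; seasonal weights
hierarchically around shared weights with $N(0,5)$/half-Normal$(0,5)$
scales. These are weakly informative on a 0–160 scale — the prior SD of
20 points spans any plausible country mean shift or effect — and the fit
is driven by the 2,266 observations, not the priors.

**Sampling.** The model is conditionally conjugate (Normal likelihood,
Normal location priors), so it is expressed in JAGS and sampled by Gibbs
in the **centered** parametrisation. A non-centered parametrisation is the
standard remedy for divergent Hamiltonian trajectories in hierarchical
models, but under Gibbs it would *destroy* the conjugacy that makes the
sampler fast and well-mixing here, so the centered form is the right
choice for this engine. The sampler runs `n_repeats` (default 5)
independently seeded repeats of `chains` chains each; all chain seeds
derive from the single user seed, making every fit bit-reproducible.
Split-chain $\hat R$ and effective sample sizes are computed for all
population-level parameters; any $\hat R > 1.01$ flags the fit with a
warning (never silently). At the default chain lengths the weakly
identified hierarchy scales ($\sigma_\text{country}$,
$\sigma_\text{season}$) typically sit at $\hat R \approx 1.02$–$1.07$
with unchanged posterior summaries under much longer warmup; the flag is
informative, not fatal, and users wanting $\hat R < 1.01$ everywhere
should raise `draws`.

**Summaries.** Highest-density intervals are the contiguous
minimal-width interval containing the stated mass (sliding-window over
sorted draws; leftmost interval on ties). For a multimodal posterior a
single contiguous interval is a simplification — none of the monitored
parameters here is multimodal in practice, but the limitation is
inherited by anything summarised through `hdi()`. The variance ratio
$\lambda = \sigma_\text{meas}/\sigma_\text{between}$ is computed draw by
draw and summarised by median, IQR and central 95% interval. Per-repeat
posterior means are reported beside the pooled summaries; their spread
staying within the pooled 50% HDI width is the shipped stability check.

**Corrected scores.** `correct_scores()` returns posterior means (and
SDs) of $b_i$ and $b_i + a_i d_i$: seasonal terms are removed from *both*
visits, so corrected values estimate yearly-average adherence. For
controls the corrected change therefore contains the small drift term
$a_i d_i$; whether a published correction of this design includes that
term is not determinable, so the drift handling is an explicit option.
Seasonal-amplitude conventions: `amplitude`
$= \sqrt{(w^s)^2 + (w^c)^2}$ is the half-range of the oscillation
(excursion above and below the yearly average), `peak_to_trough`
$= 2 \times$ amplitude is the difference between the seasonal extremes —
both are reported because the two readings of "seasonal variation" differ
by exactly this factor of two. The peak year fraction is
$\operatorname{atan2}(w^s, w^c)/2\pi \bmod 1$, so a pure positive cosine
peaks at 0 (1 January).

## 4. The synthetic cohort generator

The generator is first-class, tested code: it draws cohorts with exactly
the generative structure of Section 3 and returns the latent truth table
alongside the records, which is what makes parameter-recovery testing
possible. Its defaults *are* the study conditions of the motivating
design, chosen once:

* **Counts** 241 (IT), 251 (UK), 235 (NL), 222 (PL), 184 (FR) — 1,133
  subjects; balanced randomisation to control/intervention within country.
* **Baselines** 80 points, with the Netherlands at 87. The direction of
  the NL deviation is a convention (the source material flags NL as the
  baseline outlier, with country differences of 6–8 points, but not the
  sign); +7 was fixed before any testing and nothing downstream depends
  on the sign.
* **Effects** 20 points in four countries, 38 in France (the effect
  outlier, "almost double").
* **Noise** $\sigma_\text{meas} = 16$ (20% of the 80-point baseline) and
  $\sigma_\text{between} = 16/1.03 \approx 15.5$, fixing the
  within/between ratio at 1.03.
* **Effect spread** $\sigma_\text{effect} = \sigma_\text{between}$ by
  default. This is the null model's own assumption — the between-visit
  variation is "distributed in the same way" as the baseline spread — and
  it is what makes the package's two routes to $\lambda$ (null-model
  inversion of the intervention-arm correlation, and the full posterior)
  agree on synthetic data; it also reflects the realistic situation that
  adherence responses range from none to roughly double the mean effect.
* **Seasonality** peak-to-trough 4 points for FR and PL, 2.5 for IT, 1
  for UK and NL; peak timing (late spring/summer for the high-seasonality
  countries) is a documented convention — only the amplitude ordering is
  meaningful.
* **Dates** T0 uniform over the year ("continuous recruitment"); T1 = T0
  plus a uniform 10–14-month gap; year fraction = (day-of-year − 1)/365.25
  on [0, 1).
* **Controls** are stable apart from the 5% participation drift; the
  optional between-visit change (`include_between_visit_change`,
  `change_sd`) exists for null-model experiments and is off by default.

What the generator does **not** emulate: individual food diaries or
component-level intake trajectories, energy-intake dynamics, dropout or
missing visits, floor/ceiling effects of the bounded index (scores are
unclipped by design), non-Normal measurement error, or subject-level
seasonal heterogeneity. Recovery tests passing on this generator show the
estimation machinery is correct *under the model's own assumptions*; they
cannot show the assumptions hold for any real cohort.

## 5. The scoring engine

`score_component()` implements the continuous scorer as piecewise-linear
interpolation between a zero-score and a full-score cutoff, clamped to
[0, 10]; "range" components (whole grains, eggs) score 10 inside their
target band with linear ramps to the outer zero-score interval. The
published guideline cut-off constants live in the guideline reference,
not here: the shipped 16-component file is explicitly illustrative and
every cutoff is configuration. Percentile caps (85th for sodium and
sweets, 100th for whole grains and low-fat meat) are computed per country
with the linear-interpolation empirical quantile (`type = 7`); at small
per-country n this choice materially affects the caps, which is why it is
documented rather than hidden. Exclusion rules are applied in a fixed
order (incomplete diary, missing supplement data, energy below 500
kcal/day, above 3500) with strict inequalities at the energy bounds
("below"/"exceeding"), and each excluded record carries its first
matching reason.

## 6. Numerical and design notes

* Curve inversion requires the observed correlation in
  $(-1/\sqrt2, 0]$; values at or below the asymptote are rejected as
  unattainable rather than extrapolated.
* `simulate_null()` with a single replicate reports the large-sample
  analytic SE $(1 - r^2)/\sqrt{n-1}$ instead of an undefined across-rep
  SD.
* `sigma_meas_fixed` pins the measurement SD (used by the degenerate
  zero-noise checks, where the likelihood must reproduce the data
  exactly). With $\sigma_\text{meas} \to 0$ the seasonal weights become
  unidentifiable — any weight vector fits perfectly with compensating
  subject baselines — which is why the zero-noise validation compares
  corrected scores to *raw minus fitted season*, not to raw alone.
* Subject-level draws are not retained in the fit object; their
  posterior means/SDs (all that the corrected scores need) are computed
  per repeat and pooled, keeping the object small at full cohort size.

## 7. Identifiability limits of the seasonal amplitude

At these variance levels a country's two seasonal weights are estimated
with roughly ±1.7-point sampling noise at ~200 subjects/country (each
subject contributes two visits at nearly the same phase, so seasonal
information is essentially between-subject). Two consequences, verified
on generated cohorts and reflected in the tests:

* The amplitude — the *norm* of the weight vector — is positive by
  construction and biased upward under uncertainty: even a cohort
  generated with zero seasonality shows posterior amplitudes around 2
  points. "No seasonality" must therefore be assessed on the signed
  weights (`amplitude_of_mean` against the weight posterior SDs), not by
  expecting the amplitude's HDI to reach zero.
* A true 4-point peak-to-trough is at the edge of detectability: its
  recovered value fluctuates by roughly ±1 point from cohort to cohort.
  The shipped recovery checks use tolerances wide enough to reflect this
  honestly.

## 8. Problem sizes used by the shipped validation

The test suite fits reduced cohorts (15–200 subjects per country, 1–5
repeats of 2 chains, 300–600 retained draws) for the property checks —
shrinkage hull, HDI calibration over 40 simulated cohorts, repeat
stability, seasonal identifiability — and one full-size cohort (1,133
subjects, 2 repeats × 2 chains × 1,000 draws) for end-to-end parameter
recovery; the acceptance script uses the same full-size configuration.
These sizes were chosen as the smallest at which each property is
informative; all are the package's own choices and are trivially
increased via `model_spec()`.

## 9. Known limitations

* Two visits per subject cannot separate subject-level response
  heterogeneity from between-visit lifestyle change; both land in
  $\sigma_\text{effect}$.
* The index is treated as continuous and unbounded; cohorts concentrated
  near 0 or 160 would violate the Normal likelihood.
* Seasonality is a single shared harmonic per country; subject-level or
  multi-harmonic seasonality is out of scope.
* The corrected scores are posterior means — appropriate as point
  estimates, but downstream analyses should propagate the attached
  posterior SDs rather than treat corrected values as exact.
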