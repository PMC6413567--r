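# dietshrink

Correcting diet-adherence indices for regression to the mean and
seasonality in multi-country intervention trials.

## The problem

Dietary intervention trials often score adherence with a summary index —
here a 0–160 index built from 16 continuous 0–10 component scores — measured
by a 7-day food record at baseline (T0) and again after roughly a year of
intervention (T1). A one-week diary is a *noisy* measurement of habitual
diet: the week observed may not represent the whole period, and the time of
year shifts what people eat. Two consequences distort naive analyses:

* **Regression to the mean.** Measurement noise enters the baseline score
  with one sign and the observed change `T1 − T0` with the other, producing
  a spurious negative correlation between baseline and change and inflating
  the apparent spread of individual responses. If the within-subject
  (measurement) SD and the between-subject SD are comparable, the effective
  variance of the data is doubled — equivalent to throwing away half the
  cohort.
* **Seasonality.** Visits cannot all be scheduled exactly one year apart,
  so a yearly oscillation in adherence leaks into the estimated
  intervention effect.

`dietshrink` implements both diagnosis and cure for a two-visit, two-arm,
multi-country design, plus a synthetic-cohort generator that exposes ground
truth so every stage can be validated by parameter recovery.

## The models

**Null model (diagnosis).** For standard-normal true baselines \(B\), a
between-visit change \(C \sim N(0,1)\) and measurement noise
\(e_0, e_1 \sim N(0, \lambda)\) added independently to both visits, the
correlation between the baseline measurement and the observed change is

    r(λ) = −λ² / √((1 + λ²)(1 + 2λ²)),

which runs from 0 (no noise) to −1/√2 ≈ −0.707 (noise-dominated). The
package simulates this curve, checks it against the closed form, and
*inverts* an observed correlation into an estimate of
λ = σ_within / σ_between with a Monte-Carlo interquartile range.

**Hierarchical model (cure).** Observed scores follow

    y_T0,i ~ N(b_i + season_c(t_0i), σ_meas)
    y_T1,i ~ N(b_i + s_i·d_i + season_c(t_1i), σ_meas)

with subject baselines `b_i ~ N(B_c, σ_between)` around country centres,
subject effects `d_i ~ N(D_c, σ_effect)` around country effects
`D_c ~ N(D, σ_country)` (a two-layer hierarchy; the baseline layer is
single-level so one outlying country cannot destabilise the rest), an
arm scale `s_i` equal to 1 for intervention subjects and a small
participation-drift fraction (default 5%) for controls, and a country-level
yearly oscillation `season_c(t) = ws_c sin 2πt + wc_c cos 2πt` pooled
hierarchically across countries. The posterior yields country baselines and
effects, the variance components and their ratio λ, per-country seasonal
amplitude and peak timing, and — the central output — **shrinkage-corrected
per-subject scores** at T0 and T1 with seasonal terms removed and extreme
noisy measurements pulled toward the country trend.

Sampling uses Gibbs (JAGS) — the model is conditionally conjugate — run as
several independently seeded repeats whose agreement is itself a reported
diagnostic, alongside split-chain R̂ and effective sample sizes.

## Worked example

```r
library(dietshrink)

cohort <- generate_cohort(cohort_config(), seed = 42)   # 1,133 subjects
tab <- regression_to_mean_table(cohort$records)
print(tab, digits = 3)
#>            arm   n mean_difference sd_difference r_diff_t0
#> 1      control 568             0.7          23.9    -0.506
#> 2 intervention 565            22.5          28.3    -0.345
```

Both arms show the clearly negative difference–baseline correlation that
signals regression to the mean. Inverting the intervention arm's
correlation through the null model:

```r
curve <- simulate_null(null_model_config(), seed = 43)
invert_curve(curve, tab$r_diff_t0[tab$arm == "intervention"])
#> Ratio estimate from observed r = -0.345: lambda = 0.849, IQR [0.799, 0.885]
```

so the within-subject noise is of the same order as the between-subject
spread. The full model recovers the generating structure (baselines 80
points, 87 for NL; effects 20 points, 38 for FR; λ = 1.03):

```r
fit <- fit_adherence(cohort$records,
                     model_spec(n_repeats = 2, draws = 1000), seed = 44)
round(coef(fit), 1)
#>    baseline effect
#> FR     82.1   30.9
#> IT     80.4   19.4
#> NL     85.6   20.9
#> PL     80.5   20.5
#> UK     80.9   20.8

variance_ratio(fit)
#> Within/between ratio: median 1.037, IQR [0.999, 1.074], 95% [0.937, 1.150]
#>   sigma_meas 16.54, sigma_between 15.98 (posterior means)

head(round(correct_scores(fit)[, -(1:3)], 1), 3)
#>   raw_t0 raw_t1 corrected_t0 corrected_t0_sd corrected_t1 corrected_t1_sd
#> 1   67.8  121.1         88.9             9.6         89.9             9.6
#> 2   90.8   82.2         84.0             9.3         85.0             9.3
#> 3   63.0   10.0         51.2             9.5         52.1             9.5
```

Subject 3's wild swing (63 → 10) is recognised as measurement noise on a
stable control and shrunk to ~51 at both visits; the posterior SD (~9.5
points) carries the honest uncertainty of a two-measurement design.
`seasonality_estimates(fit)` adds per-country oscillation amplitudes and
peak timing, and `summary(fit)` prints the full posterior table with 50%
and 95% highest-density intervals and convergence diagnostics (the fit
warns, rather than stays silent, when split-chain R̂ exceeds 1.01 — with
Gibbs sampling at these settings the weakly identified hierarchy scales
often sit a little above it).

A configurable scorer for building the 0–160 index from component intakes
(`score_component()`, `compute_index()`, `derive_caps()`,
`apply_exclusions()`) and an end-to-end driver (`run_pipeline()`) that
writes all tables as CSV/JSON with a seed-stamped run report complete the
toolkit.

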