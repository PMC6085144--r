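# painlaw

Power-law modelling of pain recovery trajectories.

`painlaw` is for biostatisticians and outcomes researchers working with
longitudinal patient-reported pain: numerical-rating-scale (NRS, 0–10)
intensities recorded at a few time marks (canonically 0, 1, 6 and 12
months). It asks and answers one modelling question — *does pain recovery
follow a time-dependent power law rather than an exponential?* — and turns
the affirmative into tools:

* **Model**: the shifted power law `F(t) = F0 · (1 + t/t0)^(−P)`, fitted by
  log–log linear regression, per record or to the cohort mean. The shift
  `t0` (default 1 month) regularizes the `t = 0` mark; the curve is
  asymptotically log–log linear with slope `−P`.
* **Chronicity**: the half-reduction ratio `M = 2^(1/P)` — elapsed time
  must grow by `M` for pain to halve. Small `P` ⇒ large `M` ⇒
  chronic-looking recovery; `P = 0.4` at one year projects ~5 more years
  to half pain, while `P = 1.7` gives `M = 1.5`.
* **Projection**: four schemes (early marks {0,6}, {0,1,6}, {0,1} with a
  fixed exponent 0.3; {0,1,6} with a per-record fitted exponent) predicting
  12-month pain, summarized by deviation distributions and tolerance-band
  accuracies (±1, ±1.5, ±2 NRS units).
* **Imputation**: a missing interior mark filled by linear vs. closed-form
  two-point power-law interpolation; the convex decay makes the linear
  chord a systematic overestimate.
* **Model comparison**: power-law vs. exponential χ² on the cohort mean
  trajectory (standard-error weights), on the NRS scale and on a geometric
  scale mapping level `N` to `2^N`.
* **Mechanism**: an ensemble of exponential decays with Gamma(a, b) rates
  aggregates to exactly `(1 + b·t)^(−a)` — a generator and closed form are
  included as mutual oracles.
* **Synthetic data**: a seeded cohort generator (and single-subject
  case-study generator) with known truth tables, so everything above is
  testable without access to any clinical registry.

## Worked example

```r
library(painlaw)

g <- generate_cohort(cohort_sim_config(seed = 1, worsener_frac = 0))
g$cohort
#> <pain_cohort> 243 records on grid {0, 1, 6, 12} months; 243 complete

compare_models(g$cohort)
#> nrs       chisq: power law 1.37, exponential 29.8 (ratio 21.7)
#> geometric chisq: power law 0.0865, exponential 10.2 (ratio 118)

cohort_deviations(g$cohort, projection_scheme("II"))
#> <deviations> scheme II at T = 12 months, n = 243
#>   mean bias 0.270, spread (SD) 1.877
#>   accuracy within +/- 1.0: 39.9%, 1.5: 58.8%, 2.0: 72.4%

ed <- exponent_distribution(g$cohort)
round(c(mean = ed$mean, sd = ed$sd), 3)
#>  mean    sd
#> 0.347 0.461
```

The χ² lines say a power law fits the simulated mean trajectory an order
of magnitude better than an exponential on both scales (the cohort *was*
generated from power laws — the comparison is a discrimination check). The
deviation summary reads: projecting each subject's 12-month pain from
their 0/1/6-month marks with the cohort exponent, 72.4% of predictions
land within ±2 NRS units; the mean bias of +0.27 says observed pain sits
slightly above the projection on average. The per-record fitted exponents
center near the generating mean of 0.3.

Single-subject case study (synthetic dose history, true exponent 1.7):

```r
cs <- generate_crps_case(true_P = 1.7, seed = 1)
case_report(dose_to_pain_proxy(cs$doses),
            strength_gap_series(cs$strength_time, cs$strength_ratio))
#> pain: P = 1.7, prefactor = 453, M = 1.5
#>   half reduction from t = 24: 36.1 months
#> strength: P = 1, prefactor = 0.9, M = 2
#>   half reduction from t = 24: 48.0 months
```

Read: the medication-dose proxy recovers `P = 1.7`, so pain halves every
time elapsed time grows by 50% — from month 24, half the current pain is
projected by month 36.

## Command line

```sh
Rscript inst/cli/painlaw.R simulate --n 243 --seed 1 --outdir out/
Rscript inst/cli/painlaw.R report-all --input out/cohort.csv --outdir out/
```

Subcommands: `simulate`, `project`, `impute`, `compare-models`,
`exponents`, `slopes`, `case`, `report-all`. Reports are JSON files that
embed the config and seed; fixed-seed reruns are byte-identical.

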