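# psychepi

Episode-based analysis of new psychiatric admissions from administrative
claims data.

## The problem

Health-insurance claims record psychiatric hospitalization as one row per
patient × hospital × ward stay. A patient transferred between psychiatric
hospitals therefore appears as two "admissions", and the sending
hospital's "discharge" is not a return to the community. Facility surveys
that count admissions per hospital inherit this distortion: admission
counts are inflated and community-discharge rates deflated relative to a
definition based on the *episode of care* — the continuous period from
admission to a psychiatric ward until discharge to the community, a
general ward, or death, concatenated across transfers.

`psychepi` is for epidemiologists and health-services researchers working
with stay-level claims extracts. It provides:

- **Episode construction** — `link_segments()` chains per-hospital stays
  into episodes (two stays chain iff the next admission is ≤ `gap_days`
  after the previous discharge); `apply_cohort_filters()` implements the
  new-admission cohort rules (prevalent patients, enrollment
  verification, same-day multi-hospital id errors) with a full exclusion
  log.
- **Competing-risks estimation** — a from-scratch Aalen-Johansen
  estimator (`aalen_johansen()`, `cif_at()`) of the cumulative incidence
  of community discharge, with general-ward transfer and death as
  competing events and dual administrative censoring (observation end and
  365 days after admission). At the *j*-th distinct event time with
  *n<sub>j</sub>* at risk and *d<sub>kj</sub>* cause-*k* events,

  S(t<sub>j</sub>) = Π<sub>i≤j</sub> (1 − Σ<sub>k</sub> d<sub>ki</sub>/n<sub>i</sub>),  CIF<sub>k</sub>(t<sub>j</sub>) = Σ<sub>i≤j</sub> S(t<sub>i−1</sub>) d<sub>ki</sub>/n<sub>i</sub>.

- **Seasonal trend** — `fit_seasonal_poisson()`, a log-linear Poisson
  model with secular trend and first harmonic for monthly admission
  counts.
- **Aggregation** — cohort descriptives, fee-category-stratified
  incidence tables, hospital-level 90-day discharge-rate rank groups
  (quintiles/tertiles), prefecture-level indicators.
- **Definitional concordance** — `single_hospital_view()` re-reads the
  same claims the way a facility survey would, and
  `indicator_correlations()` quantifies the agreement.
- **A calibrated synthetic claims generator** — `generator_config()`,
  `generate_cohort()`, `emit_claims()` simulate a national-claims-like
  extract with known latent truth: piecewise-constant cause-specific
  discharge hazards solved in closed form (`calibrate_hazards()`) so the
  true cumulative incidence hits specified targets, seasonal admission
  intensity, fragmented transfers, withheld publicly funded episodes, and
  an id-collision injector.

## Worked example

Simulate a 20,000-episode cohort under the default calibration (each fee
category's hazards solved from its published cumulative-incidence
profile), fragment it into claims, rebuild episodes, and estimate:

```r
library(psychepi)

cfg    <- generator_config(n_patients = 20000, seed = 42)
cohort <- generate_cohort(cfg)
claims <- emit_claims(cohort, cfg)       # stays + enrollment + general-ward
built  <- build_episodes(claims)         # link, filter, classify, assign outcomes

fit <- aalen_johansen(built$episodes$event_time, built$episodes$outcome)
fit
#> <cif_curve> n = 20000, 365 event times, causes: community, general_ward, death
#>   community       63.9% @90d   78.9% @180d   83.1% @270d   85.4% @360d
#>   general_ward     0.1% @90d    0.1% @180d    0.2% @270d    0.3% @360d
#>   death            0.8% @90d    1.7% @180d    2.5% @270d    3.2% @360d
```

About 64% of admissions end in community discharge within 90 days and
85% within a year; in-ward death (3.2%) and general-ward transfer (0.3%)
are the competing events. Stratified by ward fee category, high-turnover
psychiatric emergency units and slow-discharging dementia care units
bracket the range:

```r
cif_by_stratum(built$episodes, "fee_type") |>
  dplyr::filter(fee_type %in% c("pd_emergency", "pd_dementia"))
#>   fee_type         n empty cif_90 cif_180 cif_270 cif_360
#> 1 pd_dementia   1451 FALSE   36.0    52.7    61.1    66.1
#> 2 pd_emergency  2329 FALSE   79.6    92.5    95.2    96.1
```

The seasonal model recovers the July peak built into the admission
intensity:

```r
fit_seasonal_poisson(monthly_counts(built$episodes, cfg$window_start, cfg$window_end))
#> <seasonal_fit> log-linear Poisson, trend + first harmonic
#>   intercept 6.7139, trend 0.000725 per month
#>   seasonal amplitude 0.1021 (log scale), peak month 7
```

And the single-hospital (facility-survey style) definition, applied to
the very same claims, counts more admissions and a lower one-year
community-discharge proportion — the definitional distortion the episode
linkage removes:

```r
sh <- single_hospital_view(claims$stays)
#> episode admissions: 20000, single-hospital admissions: 20467
#> 1-year community discharge: episode 85.4%, single-hospital 82.9%
```

`run_pipeline(run_config("simulate", ...))` orchestrates all of the
above into a reproducible report bundle (CSV tables, exclusion log,
manifest); `inst/cli/psychepi.R` is a thin command-line wrapper.

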