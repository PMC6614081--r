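---
title: "Episode-based analysis of new psychiatric admissions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episode-based analysis of new psychiatric admissions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychepi)
```

## The problem

National health-insurance claims record psychiatric hospitalization as one
row per patient, hospital, and ward stay. When a patient is transferred
from one psychiatric hospital to another, the sending hospital books a
discharge and the receiving hospital books a new admission, so a single
continuous period of inpatient care appears as two "admissions" — and the
sending hospital's "discharge" is not a return to the community. Facility
surveys that ask each hospital about its own admissions inherit exactly
this distortion: admission counts are inflated and community-discharge
rates deflated relative to an episode-based definition.

`psychepi` implements the episode-based analysis end to end:

1. **Episode construction** — re-chain per-hospital stay rows into single
   admission episodes across inter-hospital transfers, and apply the
   cohort rules that define a *new* admission (not prevalent at the window
   start, enrollment verifiable before admission, no same-day
   multi-hospital contradictions).
2. **Competing-risks estimation** — time from admission to discharge to
   the community, with transfer to a general ward and in-ward death as
   competing events, estimated by the Aalen-Johansen estimator under dual
   administrative censoring.
3. **Seasonal trend** — a harmonic Poisson model of monthly admission
   counts.
4. **Aggregation** — cohort descriptives, fee-category-stratified
   cumulative incidence, hospital-level 90-day discharge-rate rank groups,
   and prefecture-level indicators.
5. **Definitional concordance** — the same indicators recomputed under a
   single-hospital view of the claims, and their correlation with the
   episode-based values.

Because real national claims are not publicly available, the package
ships a synthetic claims generator whose latent truth is known and
calibrated, so every pipeline stage is testable without external data.

## Episode construction

An episode runs from the date of admission to a psychiatric ward (from
home, an institution, or a general ward) to the date of discharge to the
community, a general ward, or death. Two stays of one patient are chained
into one episode iff the next admission date is at most `gap_days` after
the previous discharge date. The default `gap_days = 1` reflects how
claims encode transfers — discharge and re-admission on the same or the
next calendar day; a larger tolerance would start merging genuine
readmissions. Episode attributes with a single natural attribution (fee
category, hospital, prefecture, legal admission type) come from the
*first* segment, i.e. the admitting ward.

Cohort rules, applied in order with full accounting in the exclusion log:

* **Same-day multi-hospital** (identification-code errors): a patient with
  two stays at *different* hospitals overlapping by more than a shared
  boundary day loses all episodes. Strict overlap matters: under the
  transfer convention every legitimate transfer touches at one calendar
  day, and must not be mistaken for an id collision.
* **Prevalent at window start**: episodes admitted before the window that
  are still in the ward on the window-start date are not new admissions.
* **Out of window**: admissions outside the two-fiscal-year window.
* **Enrollment unverified**: a new admission requires evidence the patient
  was enrolled in the database at least one day before admission — an
  enrollment marker in a month strictly before the admission month, or any
  earlier claim. Because claims have monthly granularity, a marker in the
  admission month itself cannot establish "at least one day before".

Two readings of the cohort rules were genuinely open and are resolved as
follows. First, patients may contribute multiple episodes: the admission,
not the patient, is the analysis unit, so all episodes of a patient are
retained. Second, transfers separated by more than `gap_days` are not
chained; the tolerance is a configuration parameter rather than a fixed
constant.

**Outcome assignment.** Follow-up is censored at the earlier of the
observation end date (2016-09-30 by default) and `max_days = 365` days
after admission. Event time is the day difference between episode end and
admission, floored at 1 so that same-day discharges have positive
survival time. An episode whose last segment ends with destination
`other_hospital` is an unterminated transfer chain and raises an error
rather than being silently misclassified.

**Planned admissions** are defined operationally as use of
electroconvulsive therapy with a length of stay of at most 3 days;
everything else keeps the legal voluntary/involuntary flag of the first
segment. **Route** is `general_ward` iff a general-ward stay of the same
patient ends on the admission date or the day before.

## Competing-risks estimation

With \(n_j\) at risk and \(d_{kj}\) cause-\(k\) events at the \(j\)-th
distinct event time,

\[
\hat S(t_j) = \prod_{i \le j}\Bigl(1 - \sum_k \frac{d_{ki}}{n_i}\Bigr),
\qquad
\widehat{\mathrm{CIF}}_k(t_j) = \sum_{i \le j} \hat S(t_{i-1})\,\frac{d_{ki}}{n_i}.
\]

Conventions: curves are right-continuous; evaluation exactly at an event
time includes that time's events, so "within 90 days" is inclusive of day
90; at tied times events precede censorings in the risk-set accounting.
By construction the cause-specific incidences and event-free survival sum
to one at every step, which the tests assert to `1e-10`. A pointwise
delta-method variance (Marubini-Valsecchi form) is computed by default;
it agrees with independent competing-risks software to within a few
percent (the formulations differ in higher-order terms) while the point
estimates agree to machine precision.

The estimator is written from first principles rather than wrapping an
existing package, because it *is* the analytic core being exercised;
`survival::survfit` and `cmprsk::cuminc` serve as independent oracles in
the test suite only.

## The synthetic claims generator

The generator emulates the structure of a national claims extract:

* stay-level rows per patient × hospital (billing lines are not modelled;
  monthly enrollment markers carry the only monthly semantics the
  analysis needs),
* episodes fragmented at inter-hospital transfers with the
  discharge-day = admission-day contiguity convention,
* admission intensity varying by calendar month on a log-linear first
  harmonic, peaking in July,
* piecewise-constant cause-specific discharge hazards per fee category
  with change points at 90/180/270 days — reproducing the segmented
  discharge trend that certified per-diem units show around day 90,
* optional withholding of a fraction of episodes (publicly funded claims
  a claims database never sees), prevalent patients straddling the window
  start, and an id-collision injector.

Each stochastic concern (dates, event times, transfers, demographics,
withholding, ...) draws from its own named random stream derived from the
seed, so toggling one feature leaves all other draws unchanged; identical
seed and configuration give byte-identical output.

**Calibration.** Given target cumulative incidences per cause at
90/180/270/360 days, the piecewise-constant hazards that reproduce them
are available in closed form, interval by interval: event-free survival
at each horizon is one minus total cumulative incidence, the all-cause
hazard on an interval is the log-ratio of survival at its ends divided by
its width, and the cause-specific split is proportional to the
cause-specific increments. The final interval's hazard extends beyond the
last horizon. `calibrate_hazards()` implements this and
`piecewise_cif()` its exact inverse; the round trip is tested to
`1e-10`.

Default targets are the published national profiles: each fee category's
community-discharge incidence at the four horizons, with competing-event
targets obtained by scaling the pooled 360-day values (3.1% death, 0.3%
general-ward transfer) by the category's non-discharged mass — dementia
care units thus get proportionally higher in-ward mortality, and the
admission-weighted mixture reproduces the pooled values. For analyses of
the *pooled* cohort, `overall_calibrated_config()` instead applies one
overall profile (community 64.1/79.2/83.5/85.7% — the 180/270-day values
being admission-weighted category means, which reproduce the printed
endpoint values) to every category.

Planned admissions are a point mass (uniform 1-3-day stay, community
discharge) outside the hazard model; the calibration deflates its targets
by the planned share so the *cohort-level* incidences still hit the
targets exactly: \(c^{adj} = (c - p)/(1-p)\) for community,
\(c^{adj} = c/(1-p)\) for competing causes. Background
electroconvulsive-therapy flags are drawn only among episodes staying
longer than 3 days, so the planned-classification rule cannot relabel
them and configured admission-type shares are recovered exactly in
expectation.

Defaults chosen where no published value exists, fixed once and not
revisited: seasonal amplitude 0.1 on the log scale (a modest ±10% swing
consistent with a visible but not dramatic summer peak); transfer timing
uniform over the episode (the real distribution is unknown; the parameter
is exposed rather than asserted); a geometric-free single transfer per
transferred episode; one episode per patient (readmission correlation is
out of scope); hospitals assigned to prefectures by cycling; 2%
background ECT rate.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: correlated readmissions of one patient;
dependence between demographics and hazards (age, diagnosis and fee
category are drawn independently, whereas in reality dementia-unit
patients are old); the principal-diagnosis selection algorithm;
insurance-id churn and the real hashing scheme (the injector creates
clean, random collisions); billing amounts and drug claims; survey
non-response. Recovery results show the *pipeline* is correct, not that
any particular national estimate is.

## Seasonal model

Monthly counts are modelled as
\(\log \mu_m = \beta_0 + \beta_1 m + a \sin(2\pi c_m/12) + b \cos(2\pi c_m/12)\),
a log-linear Poisson regression with secular trend and first harmonic,
fitted by iteratively reweighted least squares (relative deviance change
below `1e-10`, at most 100 iterations). This is a deliberately simple,
fully specified stand-in for smoother-based trend models; no equivalence
with any particular smoother is claimed. Its peak month
(\(\arg\max_m\) of the fitted seasonal component) and amplitude
\(\sqrt{a^2+b^2}\) are closed-form, which makes peak recovery exactly
testable, including phase equivariance under circular shifts. Months are
attributed by admission date, since the quantity of interest is the
number of *new admissions*.

## Hospital- and prefecture-level tables

Hospital-level 90-day discharge rates are *crude proportions* of a
hospital's episodes discharged to the community within the horizon, not
competing-risks estimates: published hospital-level ranges include exact
0.0 and 100.0, which only crude shares produce, and competing events are
rare at 90 days. The divergence risk (crude shares treat censored and
competing episodes as non-discharges) is accepted and documented;
`hospital_rates()` exposes the horizon. Hospitals with fewer than 10
episodes in a fee category are excluded as too uncertain. Eligible
hospitals are sorted ascending by rate (ties broken by hospital id) and
split into five rank groups when at least 20 remain, three otherwise;
group sizes differ by at most one, with remainders allocated to the
lowest-ranked groups — a deterministic, order-free rule.

Prefecture-level indicators (admission counts overall, by age group, by
diagnosis; 1-year community-discharge proportion) are computed under both
definitions. In episode mode the discharge proportion is the
Aalen-Johansen incidence at 360 days; in single-hospital mode it is the
crude within-hospital share, with transferred-out patients counted as
not discharged to the community — the survey cannot follow them. By
default the single-hospital emulation runs on the same claims as the
episode analysis (no withholding, no non-response), so the measured
discrepancy isolates the *definitional* effect; the coverage gap can be
switched on separately via `public_fund_frac`.

## Numerical and degenerate-input choices

* Event times are whole days, minimum 1; the generator draws continuous
  piecewise-exponential times and takes the ceiling, so the discrete
  cumulative incidence at integer days equals the continuous closed form
  exactly.
* An all-censored sample yields a valid flat curve (all incidences zero),
  an empty sample an error.
* A stratum or prefecture with no episodes is flagged, not fatal.
* Probability vectors must sum to 1 within `1e-12`; configuration errors
  name the offending field.
* Calibration refuses targets whose total incidence reaches 100% within
  the horizon grid (hazards unidentifiable) and targets that decrease.

## Problem sizes and test design

The test suite exercises a shared 20,000-episode cohort for marginal and
round-trip checks, 50,000-episode runs for the end-to-end recovery of the
calibrated pooled targets (three Monte-Carlo standard errors at that size
is about ±0.6 percentage points at a 64% incidence), and 10,000-episode
single-stratum runs for the fee-category targets. Property checks
(probability conservation, estimator identities against the empirical
subdistribution and Kaplan-Meier, linkage round trips) run on small
randomized samples under fixed seeds. These sizes were chosen so the
whole suite completes in a few minutes while keeping recovery tolerances
meaningfully tight.

## Known limitations

* Crude hospital rates conflate censoring with non-discharge for small
  horizons near the window end.
* The single-hospital emulation models the definitional gap only; survey
  non-response and coverage differences are generator toggles, not
  defaults.
* The seasonal model has a single harmonic; multi-modal seasonality would
  be mis-summarized.
* Variance estimation is pointwise; no simultaneous bands.
* With `gap_days` large, distinct readmissions merge into one episode;
  the default of 1 day is conservative.
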