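---
title: "Methods: segmented seasonal ITS for GP care of pregnant women"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented seasonal ITS for GP care of pregnant women}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prenatalITS)
```

## The problem

During the COVID-19 pandemic, primary-care use by the general population
fluctuated with infection waves and restrictive measures. For pregnant women —
for whom the GP provides prenatal health promotion, treatment of intercurrent
problems and referrals alongside midwife-led care — foregone contacts can carry
consequences for mother and child. The question this package operationalises
is: *how did the daily GP contact rate of pregnant women change, in level and
trend, across pre-specified pandemic subphases, relative to the prepandemic
baseline?*

Because clinical EHR data cannot be redistributed, the package pairs the
analysis chain with a synthetic EHR generator whose statistical structure
matches what the analysis assumes, so every stage is testable against known
ground truth.

## Phase calendar

The pandemic is divided into six phases by national restrictive measures,
subdivided at turning points of the national infection rates into subphases
`1a…6b`; subphase `0` (all of 2019 plus 2020 ISO weeks 1–8) is the prepandemic
baseline. Spans are expressed in ISO-8601 weeks; 2020 has 53 ISO weeks, and
dates such as 2021-01-01 (ISO 2020-W53) stay with the subphase of their ISO
week. `build_phase_calendar()` maps every weekday in 2019–2021 to exactly one
subphase and errors on gaps or overlaps.

Conventions the calendar fixes:

* **Within-subphase time `t`** is the 0-based *weekday index* since the
  subphase's first weekday. Weekend days never enter the analysed series, so
  "days within the phase" is measured in trading-day time. Slopes are per
  weekday. This also makes the centered moving average exactly
  linearity-preserving (a positional window over an equally indexed series),
  which is what lets noise-free recovery be exact.
* **Seasons** are meteorological: winter Dec–Feb, spring Mar–May (the
  reference), summer Jun–Aug, autumn Sep–Nov.

## Cohort identification

Three evidence channels per contact: (1) a pregnancy/childbearing ICPC code —
the defining set ships as configurable data (chapter-W codes; W90 "normal
delivery liveborn" is hard-excluded because it is prone to false carry-over
registrations); (2) a case-insensitive Dutch regular expression over the free
text (default `zwanger|gravid[ia]|amenorroe`), where a match creates a
*candidate* that only a manual confirmation can promote — negated phrases such
as "niet zwanger" match the pattern on purpose and are resolved manually; and
(3) a manual-label table, the machine-readable stand-in for a study team's
note review (`generate_manual_labels()` derives a complete one from synthetic
truth). Evidence merges per contact: ICPC confirms outright unless manually
rejected; text confirms only with manual confirmation; otherwise the contact
is indeterminate. A woman is labelled pregnant when at least one contact
confirms.

The exclusion cascade runs in a fixed order (age 20–45 at contact first, then
sex, no confirmed pregnancy, death in period, deregistration, deregistration
reason without date, unknown birth date, registration under 90 days within the
study window, incomplete pseudonymisation; then weekend/holiday/out-of-hours
contact rules), each entity audited once at the first rule that removes it, so
the audit reproduces an inclusion flowchart and conserves counts exactly.
"Registered less than 3 months" is interpreted as fewer than 90 days of
registration overlapping the study window (configurable). The final cohort is
women with at least one included contact, which also makes the selection
idempotent. The bundled holiday list covers Dutch national holidays 2019–2021
and is replaceable.

## The rate model

With `n_d` included contacts on weekday `d` and `N_d` registered pregnant
women, the analysed series is `Y_d = 1000 · n_d / N_d`. The denominator is an
explicit input: from synthetic truth it is the generator's registered-pregnant
count; from real labels, `build_denominators()` counts women labelled pregnant
in the calendar year of `d` with active registration (`per_year`, the default,
matching per-year population framing) or women whose confirmed-contact span
covers `d` (`per_episode`).

Before fitting, a centered moving average of 15 weekdays (3 calendar weeks of
weekdays) stabilises the series; edges use a symmetrically shrunken window, so
exactly linear input is preserved. Smoothing is applied across the whole
series by default (`smooth_scope = "series"`), so segment edges borrow from
neighbouring subphases — switch to `"subphase"` to smooth within segments.

Per subphase, ordinary least squares estimates

`Y_t = b0 + b1·t + b2·S_winter + b3·S_summer + b4·S_autumn + e_t`

with spring the reference season. Since `t = 0` at the subphase start, `b0`
and its SE are the level at the start of the subphase. Season dummies that do
not vary within a subphase are dropped: seasons absent from the segment are
flagged absent, and when spring itself is absent the segment's first season
becomes the reference (its offset is absorbed into the intercept). Remaining
rank deficiencies are an error naming the collinear columns. `R²` is reported
as `NA` when the response has zero variance (the total sum of squares is 0, so
the ratio is undefined).

Baseline comparisons use the two-independent-estimates Wald form
`z = (b_P − b_0)/sqrt(SE_P² + SE_0²)` with a two-sided standard-normal P value
and a 0.05 threshold. This convention is the package's own documented choice —
the reference analysis states no formula, and its published z/P columns are
not internally consistent, so no attempt is made to reproduce them.

Residual autocorrelation is *assessed*, not corrected:
`autocorrelation_diagnostics()` returns the residual ACF for visual
inspection, and a Newey–West robust-SE option exists but is off by default,
mirroring the reference procedure.

## Code frequencies and contact mix

The 10 most registered pregnancy-relevant codes (configurable list, each code
tagged pregnancy-related or general; ties broken lexicographically) are tested
per pandemic subphase against baseline with a two-sided Fisher exact test on
contact-level presence. Because "contacts" and "registrations" denominators are
both defensible, both normalisations are emitted: presence per 1000 contacts
(`rate_*`) and registrations per 1000 contacts (`reg_rate_*`, multiplicity
counted). No multiple-testing correction is applied by default — the report
warns about interpreting many tests at α = .05 — and Benjamini–Hochberg
adjustment is available.

Contact-type shares are computed per weekday, smoothed per type with the
moving average and renormalised to sum to one, and optionally smoothed again
for display with a locally weighted linear fit: at each point the
`ceiling(span·n)` nearest neighbours are fit by weighted least squares with
tricube weights in the scaled distance. A local *linear* fit reproduces
exactly linear input for any span. Under tricube weights the span-1 fit does
**not** collapse to the global OLS line (edge points still receive unequal
weights); a `weights = "uniform"` option is provided, under which span 1 and
degree 1 reproduce the global least-squares line exactly.

Year-level descriptives (women with ≥1 included contact per year, contacts per
patient, ICPC registrations per contact, age) use sample SDs (n−1; a
single-member group reports 0 spread), age in completed years at mid-year, and
a likelihood-ratio G-test `G = 2·Σ O·ln(O/E)` against an equal-counts null
across years (the null is an assumption; the reference analysis does not state
its expected frequencies).

## The synthetic generator

`simulation_config()` fixes the emulated study conditions; the defaults are
the package's standing choices, not tuning knobs:

* women aged 20–45 throughout a 2019–2021 window; pregnancy prevalence 0.139
  with ~280-day episodes; small mutually exclusive fractions of exclusion
  traits (0.2–1.5% each);
* per-subphase intensities `intercept + slope·t + season offset` on the scale
  of the published fits (intercepts ~8–11.5 per 1000 per weekday, |slope| ≤
  0.08), seasonal offsets +0.4 winter / −0.6 summer / +0.2 autumn (chosen as a
  plausible primary-care seasonality of a few percent; no published values
  exist for this cohort);
* weekday population-level contact counts drawn as Poisson with mean
  `intensity · denominator/1000`, attributed to women whose episode covers the
  day — population-level generation is deliberate, since the analysis models
  population-level daily rates and per-patient clustering is unspecified; the
  Poisson noise choice is likewise an assumption recorded here;
* per-subphase contact-type mixes (baseline ~65% clinic / 32% telephone,
  swinging toward telephone in the first wave), ICPC code emission with
  per-subphase multipliers (e.g. gestational diabetes W84.02 elevated in later
  phases), ~1.13 registrations per contact;
* 5% of truth-pregnant contacts are detectable only through a note phrase
  (`text_signal_rate`), decoy phrases on 5% of non-pregnant notes, and an
  optional `undetected_rate` channel (default 0 so that complete manual labels
  recover truth exactly);
* no weekend or holiday contacts (the analysis excludes them regardless); a
  small out-of-hours stream and background contacts for non-cohort women give
  the exclusion cascade and the labeller something to do.

A single seed feeds fixed per-stage substreams (`seed + 10^6·stage`), so
partial reruns are reproducible. What the generator does *not* emulate:
gestational-age progression, parity, practice-level clustering, per-patient
contact correlation, true free-text variability, or infection dynamics.
Passing tests therefore demonstrate correctness of the pipeline's logic and
calibration under the stated stochastic model — not robustness to real EHR
messiness.

## Validation design

Two recovery modes ship with the package:

* **Noise-free** (`noise_free_recovery()`): fitting the exact intensity series
  recovers every generating coefficient to numerical precision when the
  smoothing window is 1. This is run with window 1 on purpose: a centered
  moving average is only exactly linearity-preserving away from season steps
  and holiday gaps, so window-15 exactness is checked separately on gap-free
  single-season series.
* **Sampled** (`recovery_study()`): 100 seeded replicates are simulated and
  refit on *raw* rates, recording whether each generating coefficient lies
  within ±2 estimated SEs. Raw rates are used because the moving average
  induces strong positive serial correlation that invalidates naive OLS SEs
  (visible in `autocorrelation_diagnostics()`); coverage is a property of the
  regression, and the default pipeline still smooths for estimation stability
  and display. The reference design (`recovery_config()`) uses three segments
  of ~110/90/60 weekdays spanning several seasons with a ~700-women
  denominator: segments of 60+ weekdays keep the ±2 SE band near its nominal
  ~95% normal coverage, whereas the full pandemic calendar contains 15–20
  weekday segments where the same band has ~93% nominal coverage (t with ~13
  df), making a 90% empirical bar a coin flip over 100 replicates regardless
  of implementation quality. Coverage on the full 13-subphase calendar is
  still computed and reported by `scripts/acceptance.R`.

A caution illustrated by the baseline segment: within a single pass through
the year, season dummies and the trend term are heavily confounded, so
seasonal coefficients carry large (honest) SEs on raw fits — and deceptively
small ones after smoothing. Interpret seasonal offsets from long segments with
care.

## Problem sizes and runtime

The shipped tests and the acceptance script use populations of 1 200–5 000
women (the published cohort screened ~79 000), 100-replicate recovery studies,
and the full 2019–2021 calendar; these sizes keep a complete run in the
low minutes on a single CPU while leaving Monte-Carlo error in coverage
estimates around ±2 percentage points.

## Known limitations

* The default pregnancy code list and text pattern are configurable stand-ins;
  they do not claim fidelity to any specific study's unpublished lists.
* The denominator definition ("registered pregnant patients") is not uniquely
  determined by the published methods; both implemented modes are
  approximations.
* Smoothing across subphase boundaries (the default) biases short-segment
  coefficients toward their neighbours; the within-subphase option trades this
  for noisier edges.
* No correction for serial correlation by default; the robust-SE option is a
  pragmatic, not exact, remedy.
* Fisher tests across many code-phase pairs inflate family-wise error unless
  the BH option is enabled.
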