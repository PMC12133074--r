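# prenatalITS

Interrupted time-series (ITS) analysis of general-practitioner (GP) health-care
use by pregnant women across the COVID-19 pandemic phases, built for routinely
registered Dutch primary-care electronic health records (EHR) coded with the
International Classification of Primary Care (ICPC).

The package is aimed at health-services researchers and epidemiologists who
want to (a) identify a pregnancy cohort in raw GP registration data, (b)
quantify how daily contact rates shifted level and trend across pre-specified
pandemic subphases, and (c) validate the whole chain on synthetic EHR data with
known ground truth, since real GP records cannot be shared.

## What it computes

**Cohort identification.** Pregnant women are identified by three methods:
pregnancy/childbearing ICPC codes (e.g. W78 "pregnancy confirmed"; W90 is never
pregnancy-defining), a case-insensitive Dutch free-text pattern over
physicians' notes (a text match is a *candidate* needing manual confirmation —
"zwangerschapstest negatief" matches the pattern but refutes pregnancy), and a
manual-label table. An audited exclusion cascade then removes women who died,
were deregistered, lack a birth date or sufficient registration time, etc., and
drops weekend, holiday, out-of-office-hours and out-of-age-range contacts.

**Segmented seasonal regression.** Weekday contact rates are normalised per
1000 registered pregnant patients, stabilised with a 3-week (15-weekday)
centered moving average, and fitted per subphase *P* with

```
Y_t(P) = b0 + b1·t + b2·S_winter + b3·S_summer + b4·S_autumn + e_t
```

where `t` counts weekdays from the subphase start (so `b0` is the level at the
start of the subphase) and spring is the reference season. Each pandemic
subphase's intercept and slope are compared with the prepandemic baseline
through Wald z-scores, `z = (b_P − b_0) / sqrt(SE_P² + SE_0²)`, with two-sided
normal P values.

**Code frequencies and contact mix.** The top-10 pregnancy-relevant ICPC codes
are ranked, each code's per-subphase contact frequency is tested against
baseline with a two-sided Fisher exact test (rates per 1000 contacts), and
contact-type shares (clinic, home visit, telephone, digital) are tracked over
time with moving-average plus locally weighted (tricube local-linear)
smoothing. Year-level descriptives use a likelihood-ratio G-test.

**Synthetic EHR generator.** `simulate_ehr()` draws a female population aged
20–45 (13.9% with a ~280-day pregnancy episode), weekday contact counts as
Poisson variates around phase-piecewise-linear intensities with seasonal
offsets, per-subphase contact-type mixes, ICPC code emission, Dutch note
phrases and decoys, and exclusion traits — together with a truth ledger for
validation.

## Worked example

```r
library(prenatalITS)

sim <- simulate_ehr(simulation_config(n_patients = 2000, seed = 42))
sel <- select_cohort(sim$patients, sim$contacts,
                     manual_labels = generate_manual_labels(sim$truth))
sel$audit
#> Exclusion audit
#>   patients: 2000 in -> 261 included
#>     - not_female                   0 removed
#>     - no_confirmed_pregnancy       1730 removed
#>     ...
#>   contacts: 11255 in -> 946 included
#>     - patient_excluded             10276 removed
#>     - outside_office_hours         33 removed

cal <- build_phase_calendar()
its <- run_its(sel$contacts, sim$truth$denominators, cal)
its$fit_table[its$fit_table$subphase %in% c("0", "1a"), ]
#>   subphase   n intercept intercept_se    slope slope_se r_squared  z_slope
#> 1        0 291      9.93        0.286 -0.00230  0.00164      0.23       NA
#> 2       1a  25     11.11        0.472 -0.12867  0.03021      0.57    -4.18
```

Reading the output: of 2000 simulated women, 261 form the analysed pregnancy
cohort with 946 eligible weekday contacts. In the baseline subphase the fitted
contact level is ~9.9 contacts per 1000 registered pregnant patients per
weekday with essentially no trend; in subphase 1a (first-wave onset) the level
starts higher but falls steeply (slope −0.13 per weekday), and the slope
differs from baseline with z = −4.18 (P < .001). On this small simulated
cohort the day-to-day noise is large relative to the generating effects, so
individual subphase estimates wander; the vignette's recovery study quantifies
this.

The published-cohort arithmetic helpers work on bundled counts:

```r
cohort_share(10985, 78941)   # 13.9 (% of screened women labelled pregnant)
```

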