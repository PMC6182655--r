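---
title: "Registry-based ascertainment and trend estimation for type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry-based ascertainment and trend estimation for type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dregistry)
library(data.table)
```

## The analysis problem

Diagnosed type 2 diabetes can be ascertained without laboratory data by
linking three national registries at the person level: pharmacy
dispensings of glucose-lowering drugs (ATC `A10`, available from 2004),
specialist-care diagnoses (ICD-10 `E10`–`E14`, linkable from 2008) and
primary-care diagnoses (ICPC-2 `T89`/`T90`, reported from 2006). The
package implements the full pipeline on such data: case ascertainment,
open-cohort person-time, and the standard trend and association
estimators. Because real registry extracts cannot be redistributed, the
package also ships a calibrated synthetic-registry generator with known
ground truth, so every stage is testable.

## Case-ascertainment algorithm

For each person, events are reduced to one record:

1. **Washout.** Any diabetes diagnosis of any type, or any `A10`
   dispensing, strictly before the study start (default 2009-01-01)
   excludes the person from the incidence analysis. Washout information is
   as deep as each source allows (drugs from 2004, primary care from 2006,
   specialist care from 2008).
2. **Onset.** The onset date is the first type-2-specific registration:
   `E11` (specialist) or `T90` (primary care). `E10`/`T89` never qualify;
   they act only as washout or possible-diabetes triggers.
3. **Qualification.** Either at least one `A10B` (non-insulin) dispensing
   within the 183-day treatment window after onset
   (`one_dx_plus_A10B`), or type 2 registrations on two or more distinct
   calendar dates pooling both diagnosis sources (`two_occasions`).
4. **Treatment class.** Pharmacological if any `A10` dispensing (insulins
   included) falls inside the treatment window; otherwise
   non-pharmacological.
5. **Incidence window.** Onsets count from the study start to
   2014-06-30, six months before the data end, so every onset has a full
   treatment-ascertainment window; the confirmatory second registration
   may occur any time up to the data end (2014-12-31).

Persons with exactly one type 2 registration and no qualifying dispensing
are `possible_unclassified`; persons with `A10` dispensings and no
diabetes diagnosis ever are `medication_without_diagnosis`. Both feed the
sensitivity summary (`unclassified_summary()`), whose yearly counts should
be stable if misclassification is not driving an incidence trend.

### Design choices on genuinely open points

* **Two occasions** means two distinct calendar dates, pooling both
  diagnosis sources; same-day duplicates collapse. The onset anchors at
  the *first* registration — the second is confirmatory — so a person's
  onset is a single date and the six-month end-of-follow-up buffer is
  meaningful.
* **Ordering.** Follow-up ends at the first diabetes evidence of any
  kind. A classification in which the first evidence is, say, a
  dispensing and the qualifying `E11` arrives later would place the case
  onset after the person has already left the cohort. The classifier
  therefore additionally requires that the first type 2 registration *is*
  the person's first diabetes evidence (same-day events allowed); persons
  failing only this ordering are `possible_unclassified`. This keeps the
  phenotype and person-time modules exactly consistent.
* **Insulin-only starters.** The one-registration rule is specifically
  `A10B`-based, yet insulin-only initiators exist. They qualify through
  the two-occasion route; once qualified, any `A10` dispensing (insulins
  included) inside the window classifies them pharmacological, and the
  initial regimen is read off the distinct substances dispensed within 30
  days of the first on-or-after-onset dispensing (all-`A10A` →
  `insulin_only`; two or more distinct substances → `multi_drug`).
* **Both occasions must be type-2-specific** (`E11`/`T90`); mixed
  `E11` + `T89` streams do not qualify.

## Cohort engine

Entry is `max(study start, 30th birthday, immigration + 365 days)`; exit
is the earliest of the day after first diabetes evidence (so the
terminating day itself contributes one day of person-time — the standard
survival convention that an event occurs at the end of its interval),
emigration, death, the 90th birthday and the period end, with ties broken
in that order. All intervals are half-open `[start, end)` in whole days.
Lexis expansion cuts each window at every 1 January and at the 50th/70th
birthdays; the attained-age band (30–49, 50–69, 70–89) is assigned by age
at segment start, which is exact because segments never cross a band
birthday. Person-years are days/365.25. Conservation is exact in days,
per person and globally, and cell assignment is verified against a
day-by-day counting oracle in the test suite.

A person who exits the cohort for another reason before their onset
(e.g. reaches 90 first) contributes person-time but no case; an onset
inside the tiled span that matched no segment would be a real
inconsistency and raises an error.

## Estimators

* `rate_with_ci()`: rate per 100,000 person-years with the log-normal
  interval `rate × exp(±1.96/√cases)`. This interval reproduces published
  registry tables to printed precision, including rows with a few dozen
  cases; an exact Poisson interval is available via `method = "exact"`.
  With zero cases the rate is 0 and the interval is absent. Its ~95%
  coverage at moderate counts is checked by simulation.
* `poisson_apc()`: Poisson log-linear model of counts on continuous time
  with a log-exposure offset; APC = `100·(exp(β) − 1)` with a Wald
  interval. Exact log-linear inputs are interpolated exactly (the model is
  saturated in that direction), which the tests exploit as a closed-form
  oracle.
* `its_fit()`: segmented variant with a slope-change term at the break
  date (September 2012 by default), monthly bins with mid-period time
  coding, Wald test on the change term. The level-change step is excluded
  by default and available as an option.
* `cox_fit()`: proportional-hazards regression via `survival::coxph`, one
  row per person on the follow-up time scale (attained age with delayed
  entry as an option — the choice is not determined by the published
  analysis), unadjusted or adjusted for sex, 10-year birth cohort,
  education and place of birth. The `missing` education level is kept as
  an explicit category but is not a contrast of interest; empty or
  degenerate levels are reported as non-estimable rather than erroring.
* `period_prevalence()`: numerator = persons whose case criteria were met
  in that year or earlier, alive/resident/aged 30–89 at some time in the
  year; denominator = all such persons. Prevalence classification runs
  without washout and without the ordering restriction.

## The synthetic registry

The generator is written so that the estimators' model families are
exactly the data-generating families, making parameter-recovery tests
well-posed.

**Latent onsets** follow a piecewise-exponential hazard on calendar time:
log-linear with slope `log(1 + APC/100)` per year (default APC −10.1 at a
marginal level of 609 per 100,000 person-years at 2009-01-01), an
optional slope change at the break date, multiplied by per-person
covariate rate ratios (female 0.66; education 2.10/1.60/1 for
low/medium/high; a birth-decade gradient from 8.73 down to 1; place-of-birth
ratios 0.76–3.08). Rate ratios are mean-centred over the realised
population so the configured baseline is the marginal rate. Onsets are
drawn by inversion of the cumulative hazard from 2004 (and a 2%
long-standing prevalent pool with onsets 1994–2004), capped at death,
emigration or the data end.

**Care and recording.** 48.1% of onsets are pharmacologically treated;
initial regimens follow the shares 82.6/4.4/0.3/0.9/11.0%
(metformin/sulfonylurea/other-oral/insulin-only/multi-drug, renormalised).
First registration occurs a mean of 30 days after onset (exponential), a
scheduled confirmatory contact follows a mean of 45 days later, and
thereafter contacts recur at 4/year — quarterly reviews being standard
care for diagnosed diabetes. The rate matters beyond realism: at
substantially lower contact rates, patients diagnosed before 2009 can
pass the short register-availability windows (specialist care opens only
in 2008) without any recorded contact, escape washout, and surface as
spurious early-study incident cases — a misclassification the washout
design cannot see. Dispensings start uniformly within 90 days of first
registration and refill every ~90 days.

**Register profiles.** Each case is assigned a register profile once —
specialist-only, primary-care-only, or both (occasions of "both" persons
go to each register independently at 0.7 per occasion). A per-occasion
independent assignment cannot produce a substantial single-register
share: with several contacts per person, almost everyone ends up in both
registers. The per-person profile decouples the overlap distribution
from the contact rate; the default profile probabilities (both = 0.80
treated / 0.50 untreated) are a frozen calibration preset under which the
one/two/three-register overlap among incident cases approximates
26/36/39%.

**Noise populations.** A constant-flow background population (0.8% over
1994–2014, onsets uniform in time) carries type-1/unspecific codes only
(`E10`/`T89`) — representing type 1 patients and coding noise — and never
qualifies as type 2; 0.2% of unaffected persons receive glucose-lowering
dispensings with no diagnosis. Both populations are calendar-stable by
construction, so the yearly sensitivity series is trend-free up to
sampling noise (the final half-year shows a boundary artefact: late
onsets that have not yet had time to qualify). An earlier design that
miscoded a fixed *fraction of cases* was discarded: it made unclassified
counts proportional to the declining incidence, which both contradicts
the stable series observed in practice and misreads what `E10`/`T89`
registrations are.

**Demography.** Birth decades 1910–1989 with shares matching a nationwide
30–89 population, equal sexes, education 23/42/31/4%, 85% native-born,
Gompertz mortality, constant emigration hazard, immigration dates for the
foreign-born with a configurable age-at-immigration range. Death and
emigration are independent of disease by default.

### What the generator does not emulate

No within-person correlation between disease and mortality or migration;
no seasonality or weekday structure in contacts; no regional or provider
effects; no age dependence of the onset hazard beyond the fixed
birth-decade ratios; no changes in coding practice over time (other than
the optional hazard slope break); at most one immigration/emigration pair
per person. Passing recovery tests therefore show the pipeline is correct
under the stated model family, not that real registries satisfy it.

## Parameter-recovery design

The end-to-end recovery experiment configures APC = −10 and switches the
covariate rate ratios off. With the strong birth-decade gradient active,
the crude year-only Poisson trend targets a *different estimand* than the
individual-level hazard slope: the risk set's covariate composition
drifts as high-risk birth cohorts age out at 90 and low-risk ones age in
at 30, so the marginal rate falls faster than any individual's hazard.
This is a property of crude rates (the published rates are likewise
neither adjusted nor standardised), not an estimator defect; an oracle
run with perfect case knowledge shows the same gap. Setting the rate
ratios to zero makes the marginal and individual trends coincide, so the
experiment isolates the trend parameter.

Problem sizes used by the tests and the acceptance script: 20 (tests) or
10 (script) replicates of n = 200,000 persons for APC recovery;
n = 100,000 for hazard-ratio recovery; n = 150,000 for the overlap,
regimen and sensitivity summaries; 1,000 replicates for interval
coverage; all event-stream patterns of up to four events for the
phenotyping oracle; 1,000 random windows for the Lexis oracle.

## Numerical conventions and degenerate inputs

Dates are whole calendar days (`data.table::IDate`); all intervals are
half-open; "6 months" is fixed at 183 days and "first month" at 30 days,
both configurable in `study_config()`. Anniversaries of 29 February fall
on 1 March off leap years. Person-years use 365.25 days throughout.
Code matching is prefix-based on the uppercase three-character stem.
Duplicate same-day registrations collapse. Empty event tables, zero-case
strata, empty covariate levels and an empty incident set all return
well-formed empty or `NA` results; genuinely contradictory inputs
(unknown person ids, wrong code family for a source, dates before source
availability, inverted date pairs, non-positive exposure) raise errors
naming the offending rows. Same seed and configuration give byte-identical
simulator output; the pipeline manifest records config hash, seed, stage
timings and output checksums.

## Known limitations

* The ascertainment algorithm is rule-based by design; no probabilistic
  phenotyping, and no validation against laboratory data is possible
  within this scope.
* Prevalence numerator/denominator use calendar-year presence, not exact
  person-time, mirroring the definition of period prevalence used with
  such registries.
* The crude APC conflates individual trend and composition drift when
  covariate effects are strong (see above); stratified or adjusted trend
  models are the remedy if that distinction matters.
* The generator's calibration targets a handful of published marginal
  quantities; it is not a population model of Norway.
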