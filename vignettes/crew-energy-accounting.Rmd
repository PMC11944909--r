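---
title: "Occupational energy-expenditure accounting for ship crews: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupational energy-expenditure accounting for ship crews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crewEE)
```

## The problem

Feeding standards for naval and border-guard personnel are normative: they
state how much energy and how many grams of protein, fat and carbohydrate a
daily ration must supply. Whether a standard is adequate — or excessive, a
known driver of overweight in closed shipboard environments — can only be
judged against what the crews actually expend. crewEE implements the
accounting needed for that audit:

1. **Activity-diary ledgers**: a crew's typical day, written as a timed
   schedule of activities with tabulated energy costs, is turned into
   per-activity and 24-h energy expenditure.
2. **Heart-rate based estimation**: where a diary is too coarse (officers on
   irregular 12-h shifts), energy expenditure is estimated from a wearable
   HR trace through an individually fitted HR–VO~2~ calibration.
3. **Severity classification**: daily, per-shift and per-minute expenditures
   are banded into the Lehmann and Christensen work-severity categories.
4. **Ration adequacy**: planned and as-served rations are audited against a
   food standard, with percent-of-energy shares from Atwater factors.
5. **Synthetic data**: a seeded generator produces subjects, schedules, HR
   traces with known ground-truth expenditure, and rations, so the whole
   pipeline is testable end to end without any external data.

## The activity-diary model

A day is an ordered set of half-open intervals $[t_i, t_{i+1})$ on the
1440-minute clock circle (intervals may wrap midnight, e.g. sleep from
22:15 to 03:15). Each activity carries a rate $r_i$ in kcal·min^-1^·kg^-1^
taken from military activity-expenditure tables, so for a subject of body
mass $m$:

$$E_i = r_i \, d_i \, m, \qquad E_{24h} = \sum_i E_i ,$$

with $d_i$ the duration in minutes and $\sum_i d_i = 1440$ enforced by
`validate_schedule()` (gaps, overlaps and total-minute deviations are
reported, not silently repaired). All arithmetic is kept at full floating
precision; rounding to one decimal is applied only when printing. This
matters: published ledger totals are only reproducible when the unrounded
row values are summed.

```{r}
sched <- ship_schedule("frigate_sea")
res <- daily_ee(sched, body_mass = attr(sched, "body_mass_kg"))
res$total_kcal
summary(res)
```

### The packaged diaries and their inconsistencies

Four published crew diaries ship as CSV fixtures (`ship_schedule()`): the
missile frigate and the training sailing ship, each at sea and in port,
together with the published per-row energy values. `reproduce_ledgers()`
re-derives every row and total and marks deviations:

* both frigate diaries reproduce row-wise to ±0.2 kcal and in total to
  under 1 kcal;
* the sailing-ship at-sea diary's *Sleep* row (237.5 kcal) contradicts its
  own printed rate (0.0166 × 300 × 79.5 ≈ 395.9 kcal); recomputation from
  rates is treated as authoritative, and the resulting total (≈4028 kcal)
  still agrees with the published ≈4032 kcal within 0.1%;
* the sailing-ship in-port diary is internally inconsistent: its rows sum
  to ≈3864 kcal while the printed total is 3380 kcal (and one rate,
  0.1199 kcal·min^-1^·kg^-1^ for a routine inspection activity, is an
  outlier against the frigate's 0.0433 for the same activity). The engine
  always reports the recomputed sum and FLAGs the mismatch — printed totals
  are never silently adopted.

```{r}
reproduce_ledgers()$totals
```

The per-row tolerance (±0.2 kcal) covers 1-decimal display rounding plus
one unit of last-digit jitter; the total tolerance (±1%) reflects that
published totals stem from per-subject measurements, not from summing the
printed column.

## Group anthropometrics

`summarize_groups()` reports per-cohort means ± SD and a grand value
defined as the **unweighted** mean of cohort means — each cohort counts
once regardless of size. This is the only convention under which a
published multi-cohort "average" column of unequal group sizes
(74/30/89/21 subjects) is reproducible from the group means alone: the
subject-weighted body-mass mean would be 82.0 kg against the published
81.5 kg. Two of the four grand means (age 29.35 y, height 178.65 cm) fall
exactly on 1-decimal rounding ties, so agreement with published values is
asserted to the printed precision (half a unit in the last digit,
tie-inclusive) rather than to a particular tie-breaking rule.

## Heart-rate based energy expenditure

During dynamic exercise, oxygen uptake rises linearly with heart rate.
`fit_calibration()` fits, per subject, the ordinary least-squares line

$$\dot{V}\mathrm{O}_2 = a + b\,\mathrm{HR}$$

over the exercise calibration points and converts predicted VO~2~ to
kcal/min with the caloric equivalent of oxygen (default 4.85 kcal/L O~2~,
the standard indirect-calorimetry value for a mixed diet; configurable).
The linear relationship fails at low heart rates, where emotional and
thermoregulatory drift dominate; the **flex-HR** convention handles this:

* with resting calibration points, the flex threshold is the midpoint
  between the highest resting HR and the lowest exercise HR, and the
  resting energy expenditure is the caloric equivalent times the mean
  resting VO~2~;
* without resting points, flex falls back to the lowest exercise HR, and
  the resting rate to the regression prediction at flex, floored at zero
  (a message notes the fallback).

`ee_from_trace()` maps each HR sample through this rule and integrates the
kcal/min series over the actual timestamps by the trapezoidal rule —
traces need not be uniformly sampled, which keeps the pipeline
device-agnostic. Negative predicted VO~2~ (possible when extrapolating a
steep line downward) is clamped to zero with a warning.
`shift_summary()` then aggregates to the standard shift-load statistics;
the per-minute rate is defined as the hourly rate divided by 60, exactly,
and the pulse minimum/mean/maximum come straight from the trace.

Published 12-h shift-load tables for the two border-guard units ship as a
fixture (`shift_loads()`). Their "measurement time" rows (15.6 h and
25.3 h, exceeding the 12-h shift) are recording-duration metadata and are
not recomputed; their per-kilogram rows are means of per-officer ratios
and are not derivable from the table's own marginal means, so only
internally consistent derivations (kcal/h → kcal/min) are checked.

## Severity classification

Two scales ship as a versioned JSON config (swappable via
`read_severity_scale()`):

| basis | bands |
|---|---|
| daily (kcal/24 h) | Light 2300–2800, Moderate 2800–3300, Moderate hard 3300–3800, Hard 3800–4300, Very hard 4300–4800, Extremely hard ≥4800 |
| 8-h shift (kcal/8 h) | Light <500, Moderate 500–1000, Moderate hard 1000–1500, Hard 1500–2000, Very hard 2000–2800, Extremely hard ≥2800 |
| per-minute (kcal/min) | Light 2.5–5.0, Moderate 5.0–7.5, Hard 7.5–10.0, Very hard 10.0–12.5, Extremely hard ≥12.5 |

Three conventions were genuinely open and are resolved as follows.
Touching bounds are read left-closed/right-open, which makes
classification deterministic and monotone (3800 kcal/day is "Hard").
The per-minute scale's thresholds are read as band *lower* bounds — the
classic reading, and the only one under which 5.61 kcal/min is "moderate"
work. Values below the lowest band (daily <2300 kcal, per-minute
<2.5 kcal/min) are labelled "Light" and flagged below-scale rather than
given an invented category. The source table prints the shift-basis
"Extremely hard" bound as ≥4800 kcal/8 h, which would leave a 2800–4800
gap after "Very hard" (2000–2800); the package reads this as a
typographical slip for ≥2800 so the scale tiles, mirroring the daily
column's structure.

```{r}
classify_daily(3874)
classify_rate_range(2.17, 5.61)
```

## Ration adequacy

`atwater_energy()` applies the general Atwater factors 4/9/4 kcal/g
(configurable); `energy_shares()` expresses each macronutrient's Atwater
energy as a percent of the Atwater total (always normalised to 100); and
`compare_to_standard()` / `compare_planned_vs_served()` report per-field
deltas, percent-of-reference and delta-as-percent-of-reference.

The audit reference is the military food standard. Its composition is not
published as a table, so the packaged default (`food_standard()`) is
**reconstructed** from the reported differences: energy 4532 kcal, protein
164.6 g, fat 145.3 g (carbohydrate is not reconstructible and stays `NA`).
This single composition simultaneously reproduces every reported
statement — frigate planned/served energy shortfalls of ≈101/≈412 kcal,
protein shortfall 15.3 g = 9.3% of supply, fat excesses of ≈56 g
(planned) and 2.1 g (served), the sailing ship's ≈22 g planned fat excess
and 22.3% served energy shortfall. A second stated energy figure of
4520 kcal exists in the source's discussion but is inconsistent with that
arithmetic and is retained only as documentation. User-supplied standards
override the fixture. Published ration energies sit ≈0.1–0.5% above their
4/9/4 reconstruction, consistent with analytically determined values;
percent-of-energy shares are always recomputed from composition, never
read off published figures.

## The synthetic-data generator

The generator emulates the study's conditions so that every stage has
inputs with known truth:

* **Subjects** (`gen_subjects()`): per-cohort normal draws at the
  published means/SDs (e.g. frigate body mass 80.4 ± 4.1 kg), truncated
  to plausible adult ranges (mass 50–130 kg, height 150–210 cm, age
  18–60 y).
* **Schedules** (`gen_schedule()`): integer-minute jitter of the template's
  internal boundaries with compensating durations, so the 1440-min total is
  preserved by construction and every output passes `validate_schedule()`.
* **HR traces** (`gen_hr_trace()`): the HR→EE model inverted — each
  activity's true energy rate is mapped to the heart rate whose calibrated
  prediction equals it, sampled every 5 s with Gaussian noise (default
  3 bpm), returning the exact ground-truth total alongside. The default
  true calibration (slope 0.012 L·min^-1^·bpm^-1^, intercept −0.6 L/min,
  4.85 kcal/L) is a representative adult exercise response, with the flex
  threshold placed below the lightest template activity so the whole day
  lies on the invertible part of the line.
* **Rations** (`gen_ration()`): normal perturbation of a target
  composition, truncated at zero.

A single master seed drives everything through *named streams*: each
generator derives its own sub-seed from the master seed plus its name (a
small polynomial hash mod 2^31^−1), so adding a generator never shifts the
draws of existing ones.

What the generator deliberately does **not** model: HR on/off kinetics,
cardiovascular drift, thermoregulatory and emotional HR elevation,
day-to-day biological variation, or device artefacts (dropouts, motion
noise). Passing round-trip tests therefore demonstrates correctness of the
estimation pipeline under the model's own assumptions — piecewise-constant
effort with white HR noise — not field accuracy on real recordings.

## Numerical choices and test design

* Trapezoidal integration over actual timestamps; at a 5-s sampling
  interval the discretisation error of a noiseless day-long round trip is
  well under 0.1%, and halving the sampling rate moves totals by <1%.
* Left-closed band boundaries; below-scale flags instead of errors.
* Full-precision accumulation everywhere; display rounding only in
  `print` methods (`round` argument, default 1 dp).
* Degenerate inputs error early with messages naming the violated
  precondition (non-positive mass, negative rates, <2 distinct calibration
  HRs, non-increasing timestamps, implausible HR, all-zero macros).
* Test problem sizes: ledger property tests run on randomly cut ≤10-entry
  full-day schedules against a per-minute brute-force oracle; calibration
  recovery uses 100 replicates of n = 30 points; round-trip tests use the
  full 1440-min template at 5-s sampling (~17k samples). The whole suite
  runs in a few seconds.

On calibration parameter recovery: at the simulated conditions
(n = 30 points, HR ~ U(90, 180), VO~2~ noise SD 0.05 L/min) OLS theory
gives SE(slope) = 0.05/(√30·sd(HR)) ≈ 3.5×10^-4^ L·min^-1^·bpm^-1^,
i.e. ≈2.9% of the true slope 0.012. Recovery of the slope to within 2%
therefore happens in only about half of replicates — a property of the
design, not of the estimator. The test suite accordingly asserts the
attainable statistical properties (unbiasedness, spread matching the
theoretical standard error, exact agreement with an independent
normal-equations solve); a stricter 2%-in-95%-of-replicates check is
retained in the acceptance suite and documents this limit by failing.

## Limitations

* The ledger model assumes tabulated per-kg rates apply uniformly to all
  crew members; inter-individual variation enters only through body mass.
* The HR method inherits the flex-HR convention's step discontinuity at
  the threshold; totals are insensitive to it unless much of the day sits
  near flex.
* The reconstructed food standard is an inference from reported
  differences, not a published composition; its carbohydrate content is
  unknown.
* Shift summaries scale the recording's mean hourly rate to the nominal
  shift length; if the recorded window is not representative of the whole
  shift, the scaled total is biased accordingly.
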