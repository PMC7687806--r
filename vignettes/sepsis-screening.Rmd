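---
title: "Screening scores from 15-minute vital-sign streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening scores from 15-minute vital-sign streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsiscreen)
```

## The problem

Surgical intermediate-care (IMCU) and intensive-care (ICU) patients are
continuously monitored, and the bedside question is whether simple screening
scores — the 1992 SIRS criteria, the three-item qSOFA score, and day-over-day
changes of the SOFA score — can flag suspected infection or predict hospital
death in this population. `sepsiscreen` implements that analysis as a
reusable pipeline over routine electronic records: 15-minute vital-sign
grids, daily laboratory values, consciousness assessments, antibiotic
administrations and outcomes. Because no such patient-level dataset is
publicly available, the package also ships a synthetic cohort generator with
a known latent ground truth, so every stage — and the pipeline end to end —
is testable.

## Cleaning the vital-sign streams

Raw monitor data contain isolated spikes and, for temperature, runs of
implausibly low readings from a dislocated probe. Cleaning proceeds per
encounter and channel:

1. **Regularization.** Samples are snapped to the 15-minute grid between
   admission and discharge; within a slot the last observation wins; empty
   slots stay missing. No interpolation is performed.
2. **Temperature artifact exclusion.** Readings at or below 31 °C are set to
   missing. The rule is inclusive (exactly 31.0 °C is excluded) and runs
   *before* smoothing, so artifact runs cannot bias the median that exists
   to suppress them.
3. **Centered rolling medians.** Window 3 (one neighbour each side) for
   heart rate, respiratory rate and systolic pressure; window 17 (eight each
   side) for temperature, long enough to bridge a typical dislocation run.
   Windows shrink at stream boundaries rather than discarding the first and
   last samples; the median of an even number of available values is the
   mean of the two middle order statistics; medians are taken over
   non-missing values only, and a window with no data yields missing. No
   absolute outlier thresholds are applied to HR/RR/SBP, because genuinely
   extreme values occur in this population.

A single-sample spike cannot survive a centered 3-point median, and an
8-sample dislocation cannot survive exclusion plus a 17-point median; both
facts are exercised in the test suite against a brute-force sorted-window
oracle and a sample-level injection log.

## Score positivity rules

All criterion flags are **missing-aware**: an unavailable input never counts
as fulfilled, so missing data can only make a determination more
conservative.

* **qSOFA** (each item one point): respiratory rate ≥ 22/min; systolic
  pressure < 100 mmHg (strict, as the reproduced analysis prints it — an
  inclusive `≤ 100` variant is a config switch); altered mentation, defined
  as GCS < 15, or RASS ≠ 0 for encounters documented only with RASS. A GCS
  of 15 cannot be "altered", so the threshold is strictly below 15.
* **SIRS (1992)**: temperature > 38 °C or < 36 °C; heart rate > 90/min;
  respiratory rate > 20/min *or* paCO₂ < 32 mmHg; leucocytes > 12 or
  < 4 × 10⁹/L. The immature-band-form criterion is omitted because only the
  routine blood count is carried. Thresholds ship as an explicit,
  overridable table (`sirs_thresholds()`).
* **Sustained positivity**: SIRS and qSOFA are rated positive only when ≥ 2
  criteria are fulfilled continuously for ≥ 30 minutes. On a 15-minute grid
  a run of k points spans (k−1)·15 minutes, so the rule requires **three
  consecutive qualifying points**; two points span only 15 minutes.
* **Laboratory look-back**: the most recent value at or before the grid time
  is used, with a validity horizon of 24 h for the (daily) leucocyte count
  and 12 h for blood-gas paCO₂; consciousness assessments persist until the
  next assessment.
* **SOFA**: six components, each 0–4, mapped from daily worst values by the
  shipped `sofa_component_table()`. Two simplifications are documented in
  that table: the respiration bands use the PaO₂/FiO₂ ratio alone (the
  ventilatory-support qualifier of the 3–4 point bands is not modelled), and
  cardiovascular support is a categorical vasopressor exposure
  (none/low/mid/high) rather than doses. A missing component scores 0 and is
  counted, never imputed. Positivity is a day-over-day **increase of ≥ 2
  points**. The first day has no previous day and is therefore not rated on
  its own by default; comparing day 1 against a baseline of 0 is available
  as an option (`sofa_delta_positive(baseline = 0)`), but the default
  follows the day-over-day rule literally — otherwise any first-day total
  of 2 or more would be positive, which contradicts the rule's own worked
  arithmetic (totals 4 → 5 must be negative).

## Suspected-infection episodes

Suspected infection is operationalized as the start of a broad-spectrum
antibiotic: carbapenems, glycopeptides, quinolones, piperacillin/sulbactam
(with piperacillin/tazobactam as the marketed class member), ceftazidime,
cefepime, linezolid, tigecycline, daptomycin, fosfomycin. Ampicillin,
cefazolin, cefuroxime, colistin, metronidazole, erythromycin,
trimethoprim/sulfamethoxazole and azithromycin are explicitly *not*
broad-spectrum here; anything off-catalog is classified `unknown` and logged,
never silently treated as broad. The catalog is an editable YAML file.

An episode is the window `[start, start + 72 h)` of the earliest qualifying
start; broad starts inside an open window are absorbed; a later start
re-triggers a new, disjoint episode; episodes truncate at discharge with a
flag. Scores are determined within each episode window; encounters without
any episode are scored over the full stay and flagged, forming the
infection-negative stratum of the evaluation.

## Evaluation

Each score yields a dichotomous encounter-level prediction, so its ROC curve
has a single interior point and

$$\mathrm{AUC} = \frac{\text{sensitivity} + \text{specificity}}{2},$$

identical to the Mann–Whitney statistic of the 0/1 predictions (a property
test checks this). Confidence intervals use the Hanley–McNeil asymptotic
standard error by default, with a stratified binomial bootstrap as the
alternative; the two agree within 0.01 on well-filled tables (checked
against a 10⁵-replicate bootstrap). Paired score comparisons use DeLong's
test for correlated AUCs, implemented from midrank placement values and
validated against an independent implementation and a sign-flip permutation
oracle. Association of score and outcome uses Pearson's chi-squared without
continuity correction when all expected cell counts are ≥ 5, otherwise
Fisher's exact test, two-sided. AUCs are graded: < 0.51 not discriminative,
[0.51, 0.70) poor, [0.70, 0.80) adequate, [0.80, 0.90) sufficient,
[0.90, 1] excellent — the half-open decimal closure of the printed bands,
so the grades partition [0, 1].

Evaluation is stratified by unit trajectory (IMCU only, ICU only, both,
plus a pooled stratum). The infection outcome is evaluated over all
encounters of a stratum; the mortality outcome is restricted by default to
encounters with suspected infection, with a switch for the all-encounter
analysis. Descriptive cohort summaries report mean ± SD when a Shapiro–Wilk
test (α = 0.05, at most 5000 sampled values) does not reject normality, and
median [IQR] (type-7 linear-interpolation quantiles) otherwise. Report
rounding is half-away-from-zero, two decimals for AUCs.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
consumes — no more.

**Latent states by quota.** Stratum membership, infection, death among the
infected, and per-score positivity intents are assigned by exact quota:
`round(p · n)` encounters per cell, sampled without replacement. Configured
conditional rates therefore hold exactly in every realization, which makes
parameter-recovery tests reflect pipeline error rather than binomial noise.
Intent probabilities have conditional semantics per score:
P(positive | infected, died) = target sensitivity and
P(positive | infected, survived) = 1 − target specificity for the mortality
outcome, and P(positive | not infected) = 1 − infection specificity.
Defaults are the published per-stratum operating points
(`default_score_targets()`); deaths occur only among infected encounters,
consistent with the IMCU arithmetic of the reproduced cohort.

**Vital signs.** Each channel is baseline + 24-h sinusoid (peak 16:00) +
AR(1) Gaussian noise at the 15-minute step: HR 78 ± 5 /min (φ = 0.8,
circadian amplitude 3), RR 16 ± 2 (0.8, 1), SBP 125 ± 6 mmHg (0.8, 4), TEMP
36.8 ± 0.15 °C (0.9, 0.3). The distributional form is an implementation
choice — the source analysis describes only the 15-minute sampling — picked
as the simplest model with realistic short-range correlation so the median
filters have work to do.

**Realizing intents.** A qSOFA-positive intent is realized as a 3-hour
window (inside the encounter's episode when infected) with a calibrated
negative systolic shift plus an altered-consciousness assessment (GCS 13 or
RASS −2); a SIRS-positive intent as an 8-hour window of calibrated fever and
tachycardia shifts — long enough to survive the 17-point temperature median;
a SOFA-positive intent as a +3 rise of non-CNS component inputs on a day
≥ 2 (the day-over-day rule cannot fire on day 1). The shift magnitudes are
not hand-tuned: `calibrate_shift()` root-finds the additive shift giving a
0.999 per-sample threshold-crossing probability at the least favourable
circadian phase, so intended windows are detected essentially surely while
baseline streams essentially never cross (the thresholds sit 3–4 SD from
baseline). Different scores deliberately use disjoint channels (qSOFA:
SBP + mentation; SIRS: temperature + heart rate) so their intents can be
controlled independently.

**Everything else.** Stay lengths are log-normal per stratum (medians 2.5,
3.5 and 5 days; σ_log = 0.7) clipped to 1–14 days — plausible right skew;
matching published stay moments is a non-goal, and the cap bounds the
simulation cost of the heavy tail. Infection onset falls uniformly in the
first 10–40 % of the stay; every infected encounter receives a
broad-spectrum start at onset (30 % a second, absorbed, start within the
window); excluded-list and off-catalog drugs appear at configurable rates.
Artifacts are injected at 0.5 spikes/channel/day and 0.2 temperature
dislocations/day (runs of ~2 h, values 24–31 °C), with a sample-level log.
Leucocytes (8 ± 1.5 × 10⁹/L, daily) and paCO₂ (40 ± 3 mmHg, 12-hourly) are
drawn in the normal range; 1 % of vitals samples are dropped as missing.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: physiological coupling between channels, drift,
therapy effects, informative missingness, sedation dynamics, and real
antibiotic prescribing behaviour. Recovery results demonstrate that the
pipeline measures what the generator encodes, not that the scores perform
identically on any real cohort.

## Numerical choices and degenerate inputs

Half-away-from-zero rounding carries a 10⁻⁸ absolute guard so that halves
represented just below their decimal value (e.g. `(0.98 + 0.65)/2`) round
up as intended. Empty criterion series, empty streams, encounters without
episodes, strata without deaths, and identical predictions in the DeLong
test (p = 1 by convention) are all defined, tested cases rather than
errors; degenerate 2×2 margins raise errors. Same-timestamp antibiotic
events are processed in lexicographic drug-name order, making episode
detection invariant to input order.

## Problem sizes used by the shipped checks

The end-to-end recovery study simulates 5000 encounters in a single stratum
at the higher (0.355) infection prevalence with 15.3 % mortality among the
infected, so the mortality operating point is estimated from roughly 270
deaths and the ±0.03 recovery band is meaningfully tighter than the
estimator's spread; at the low-prevalence stratum (0.183, 3.4 % mortality)
the same cohort size would yield ~31 deaths and the band would mostly
measure binomial noise. Property tests run 1000 random streams/series
against brute-force oracles; bootstrap and permutation oracles use 10⁵
replicates.

## Reproducing a full run

```{r, eval = FALSE}
library(sepsiscreen)
cfg <- pipeline_config(cohort_config(n_encounters = 1000, seed = 1))
res <- run_pipeline(cfg)
summary(res)
```

The same pipeline is scriptable stage by stage (`simulate`, `clean`,
`episodes`, `score`, `evaluate`, `report`) through `cli_main()` or the
`inst/scripts/sepsiscreen` Rscript, all stages exchanging the documented
CSV tables.
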