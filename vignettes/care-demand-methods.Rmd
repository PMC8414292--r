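---
title: "Measuring daily hospital care demand: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring daily hospital care demand: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecensus)
```

## The problem

Hospital care demand is not a single number. The same ward can be strained
by being full (high occupancy), by churning patients (many admissions and
discharges per day relative to the patients present), or by carrying an
unusually sick caseload. `carecensus` computes all three faces of demand
from the most widely available data there is — one row per inpatient case
with admission date, discharge date, a death flag and a case-level
severity grade — at daily resolution, per hospital, over a study year:

* **Capacity utilization (CU)**: the daily census as a percentage of that
  hospital's *highest daily census of the year*. Using the observed annual
  maximum as the denominator, rather than a licensed-bed count, makes the
  measure self-normalizing across hospitals whose administrative bed
  supply is unknown or fluid; its cost is that every hospital touches
  100% at least once by construction, so levels are only comparable
  within a hospital's own year.
* **Patient turnover**: admissions + live discharges + deaths on a day,
  as a percentage of that day's census. It captures throughput load that
  occupancy alone misses: a day can be 60% occupied yet frantic.
* **Daily mean PCCL**: the patient clinical complexity level (an ordinal
  0–4 severity grade produced per case by DRG grouping software) carried
  forward over every day of the case's stay, averaged over the patients
  present. PCCL is an *input* here; the package never re-derives it from
  diagnoses.

## Census construction

A patient occupies every calendar day from admission through discharge
**inclusive**; a same-day admission-and-discharge occupies exactly one
day. Cases admitted before the window contribute presence from the window
start (with no admission event inside the window); cases undischarged at
the window end are *censored*: they occupy the census through the last
window day, carry no discharge or death event, and — because complexity
is graded at discharge — no PCCL.

Two consequences of the inclusive convention are worth stating because
they pin down the arithmetic exactly:

* each present patient contributes at most two events to a day (its
  admission and its departure), so turnover is bounded by 200%, attained
  by a lone same-day patient;
* the census obeys the recurrence
  `census(d) = census(d-1) − departures(d-1) + admissions(d)`,
  which the test suite checks on every simulated panel, along with a
  person-day conservation identity.

The panel is built by an interval sweep (a ±1 difference array per
hospital, cumulated over days), which is linear in the number of cases.
An intentionally naive per-day membership oracle (`census_bruteforce()`)
implements the same contract quadratically; the suite requires exact
agreement on 1,000 randomized small instances.

Days with census 0 get an *absent* turnover (0/0 is undefined, and under
inclusive counting an empty day can have no events), and days with no
PCCL-bearing patient get an absent mean PCCL. Absent values are excluded
from all summaries, never zero-imputed — zero-imputation would drag down
means with information-free days.

## Summaries

Summaries pool hospital-day observations within each stratum (hospital
type; weekday name; weekday vs weekend; 7-day week index from the window
start; meteorological season). The 95% CI is the normal approximation
`mean ± 1.96·SD/√n` with the sample SD and `n` the number of hospital-day
values carrying the metric. Pooling hospital-days (rather than averaging
per-hospital means first) weights hospitals by their days present, which
is the natural unit for a panel with one observation per hospital-day;
the choice matters little for balanced panels but is stated because it is
a genuine fork.

Week indexing counts 7-day blocks from the window start rather than ISO
weeks, so week 1 is anchored to the study year's first day whatever
weekday that is; the final partial week keeps its own index. A weekly
stratum with no observations yields no summary row — this is the
mechanism by which a window starting inside a weekend can produce a
weekly dot plot with a missing weekday point in week 1.

## The synthetic population

Real national inpatient extractions are confidential, so the package
ships a generator whose defaults describe the population the analysis is
designed for, and every downstream stage is exercised against it.

* **Hospitals**: 5 university, 39 tertiary, and 58 basic hospitals
  (split 19 large / 20 medium / 19 small — the three-way split is not
  pinned down by public sources and is configurable), with target median
  daily censuses of 988 / 298 / 120 / 71 / 19 patients and a lognormal
  within-type size spread (sdlog 0.35).
* **Admissions**: per hospital and day, Poisson with intensity = type
  rate × hospital size factor × day-of-week multiplier × seasonal factor.
  The type rate comes from Little's law: target census divided by the
  expected occupied days per case (computed by quadrature from the LOS
  model, so rates stay consistent if the LOS model is reconfigured).
  Weekday multipliers peak on Monday and sag on weekends; the seasonal
  factor applies an 8% dip across weeks 20–35 and a linear ramp to a 55%
  dip over the last 14 days of each calendar year (the holiday trough).
* **Length of stay**: whole days; a 10% same-day point mass, otherwise
  `max(1, round(Lognormal(meanlog 1.17, sdlog 0.80) × m(PCCL)))` with
  multipliers m = (1.0, 1.3, 1.8, 2.6, 3.5) for PCCL 0–4. The lognormal
  shape gives the right-skew — median well below mean — characteristic
  of inpatient stays; the PCCL link encodes that sicker patients stay
  longer.
* **PCCL**: drawn per case from its hospital type's 5-category mix
  (university hospitals carry the most complex mix, medium basic the
  least).
* **Discharge timing**: each multi-day case's provisional discharge day
  is resampled among ±2 days with weights favouring Mondays and Fridays
  and penalizing weekends.
* **Warm-up and censoring**: admissions are generated from
  `max(60, P99 of modelled LOS)` days before the window start, and any
  stay overlapping the window is kept, so the window opens mid-stream
  rather than empty; cases undischarged at the window end are censored
  exactly as an extraction from routine data would deliver them.

These parameters were calibrated once, before being frozen, to land the
population in the documented bands — discharged-case LOS mean in
[5.5, 7.5] days and median in [3, 5] days, and a carried-over fraction of
1.35% ± 0.5% — and left untouched thereafter. Note the integer-day
schema makes the LOS median an integer; sub-day stay durations, which
real discharge abstracts sometimes carry, are deliberately out of scope.

Several qualitative signatures of real hospital systems *emerge* from
these ingredients rather than being drawn directly, and the acceptance
suite verifies them over 10 seeds at full scale: weekday CU exceeds
weekend CU; Monday is the weekly turnover maximum; weekend mean PCCL is
at least the weekday mean (short, light stays avoid weekends, so the
weekend residue is sicker); summer CU sits below winter CU; and per-type
mean CU is ordered university > tertiary > large > medium > small basic —
larger hospitals have relatively smaller Poisson fluctuations, so their
census sits closer to its own annual maximum.

What the generator does **not** emulate: inter-hospital transfer
networks, diagnosis codes or DRG grouping, bed-supply constraints
(admissions are never refused), outbreak dynamics, or any correlation
between severity and mortality timing. Tests passing on this population
therefore validate the *pipeline arithmetic and the stated mechanisms*,
not distributional fidelity to any particular country's data.

## Problem sizes and numerical choices

The default configuration generates roughly 0.9 million cases and a
37,230-row panel in a few seconds; the test suite runs the full-scale
population over 10 seeds and scaled-down configurations (one year, 5–6
hospitals) elsewhere. Percentages are carried at full double precision
and rounded only for presentation (the case-level PCCL table rounds to 2
decimals). LOESS smoothing of annual curves uses span 0.25 and degree 2
with a pointwise `±1.96·SE` band; on exactly linear input the smoother
reproduces the line to numerical precision, which the suite asserts.
Every figure writes a CSV sidecar of the exact numbers plotted, so
rendering is testable without image comparison.

## Known limitations

* CU is relative to the annual maximum, so absolute occupancy levels and
  cross-hospital comparisons require external bed denominators.
* PCCL availability is discharge-conditional; annual windows therefore
  show a mechanical dip in daily mean PCCL near the window end as an
  increasing share of present patients is ungraded. This mirrors the
  behaviour of real discharge-abstract data and is a feature of the
  measure, not a bug, but it means December PCCL levels are biased low.
* The 95% CIs treat hospital-days as independent observations; serial
  correlation within a hospital's year makes them anti-conservative.
  The package is descriptive and fits no inferential models.
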