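---
title: "Monitoring statistics and dietary risk assessment for pesticide residues"
author: "resmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring statistics and dietary risk assessment for pesticide residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resmon)
```

## The problem

Regulatory laboratories screen fresh produce for hundreds of pesticides and
must answer two questions: *is the food legal* (does any residue exceed its
maximum residue limit, MRL), and *is the food safe* (does the measured
contamination translate into a dietary exposure below toxicological
reference doses). `resmon` implements the standard deterministic workflow
for both questions on top of a long-format table of residue
quantifications, and ships a reconstruction of a published reference
survey — 1,146 fruit and vegetable samples of 20 commodities collected in
Incheon, Korea, in 2020 and screened for 400 pesticides — as a fully
worked, testable example.

## Data model

* **Samples** (`sample_id`, `commodity`, `group`): one row per analysed
  sample; `group` is `vegetable` or `fruit`.
* **Measurements** (`sample_id`, `pesticide`, `concentration`, `lod`,
  `loq`, all mg/kg): one row per quantified residue. Samples without any
  residue appear in the measurement file with an empty pesticide cell, so
  the denominator of every rate is recoverable from one file.
* **MRL registry** (`pesticide`, `commodity`, `mrl`): registered legal
  limits. Under the Korean positive list system (PLS), any pair *without*
  a registration is limited at a uniform default, 0.01 mg/kg
  (`pls_default_mrl`, configurable). `resolve_mrl()` makes this fallback
  total: lookup never fails, and the output records whether the limit was
  `registered` or `pls_default`.
* **Toxicological references** (`pesticide`, `adi`, `arfd`): the
  acceptable daily intake (mg/kg bw/day) and, where authorised, the acute
  reference dose (mg/kg bw). An absent ARfD is `NA` end to end — never
  zero — because "no authorised acute reference value" means the acute
  index *does not exist*, not that it is infinite or nil.
* **Consumption** (`commodity`, `daily_intake` in kg/person/day):
  user-supplied. National intake statistics are rarely reprinted in survey
  reports (the reference survey cites but does not print them), so none of
  the package's published-value checks depend on a consumption table.

## Compliance classification

`classify_residue()` applies two conventions that deserve to be explicit:

* the detection threshold is the per-pesticide LOD; a concentration below
  it is `not_detected` and is ignored by everything downstream (no LOD/2
  substitution in the compliance statistics);
* "exceeding the MRL" is a *strict* inequality; a residue exactly at the
  limit is compliant, the usual regulatory reading.

The verdict is therefore monotone in concentration
(`not_detected < below_mrl < above_mrl`), which the tests exercise as a
property. A *sample* takes its worst residue verdict
(`classify_sample()`). The reference survey happens to have exactly one
residue per contaminated sample, so the rule is invisible there; it
matters for general (multi-residue) data and the stochastic generator
produces such samples to exercise it.

## Occurrence and incidence tables

`occurrence_by_commodity()` reports, per commodity, the counts of
residue-free / compliant-residue / violating samples and their
percentages. One reporting convention is inherited from the reference
survey's published table: the percentage printed next to the below-MRL
count is the **any-residue rate**, `100*(n_below + n_above)/n_total` —
verified against its aster scaber row (19.6% = 9/46) and welsh onion row
(12.3% = 13/106). Machine output keeps this convention (`pct_with`) *and*
emits an unambiguous `pct_below`, so the ambiguity is reproduced but not
propagated.

All percentages use **round-half-up at one decimal** (configurable).
Base R's banker's rounding would print 46.85 as 46.8; survey tables in
this field round halves up, and every published percentage in the
reference tables is consistent with round-half-up with one exception: the
insecticide share of detected pesticides prints as 43.7% where
100·14/32 = 43.75 rounds to 43.8. The package keeps round-half-up and
documents the single-cell discrepancy rather than inventing a rounding
rule that fits one cell. `round_half_up()` adds a 1e-9 relative nudge
before truncation so decimal fractions that are stored just below an
exact half (an artefact of binary floating point) still round up.

`incidence_by_pesticide()` summarises per pesticide: detections and
violations as counts and rates over *all* samples, the detected
concentration range, and the range of MRLs applied across the commodities
where it was found. `function_class_breakdown()` tallies detected
pesticides by functional class (fungicide/growth regulator/herbicide/
insecticide) as percentages of distinct detected pesticides.

## Deterministic dietary risk assessment

For every pesticide x commodity pair with at least one detection:

* **ESTI** (estimated short-term intake) = highest residue x daily
  consumption / body weight;
* **aHQ** = 100 · ESTI / ARfD (%), `NA` when no ARfD is authorised;
* **EDI** (estimated daily intake) = mean residue x daily consumption /
  body weight;
* **HQ** = 100 · EDI / ADI (%);
* **cHI** = sum of HQ over all pairs (%), with the verdict
  `potential_risk` only for an index *strictly* above 100%.

Design choices, each genuinely open in the field:

* *Mean residue* is the arithmetic mean over **detected** concentrations
  only. A survey that reports detected ranges has effectively conditioned
  on detection; substituting LOD/2 for the censored majority would let
  the (huge) non-detect count dominate the mean. The substitution is
  available as `nondetect_policy = "half_lod"` for sensitivity analysis.
* *One consumption table* feeds both ESTI and EDI. Acute assessments
  sometimes use a "large portion" intake; with a single national intake
  source cited, introducing a second, invented intake would be less
  faithful than reusing the same one.
* *Body weight* is a single scalar (default 60 kg, the conventional adult
  value in Korean assessments). It is deliberately a visible
  configuration field, not a constant, because reports divide by "the
  body weight" without printing it.
* ESTI ≥ EDI whenever both use the same consumption and body weight
  (max ≥ mean); asserted as a property test.

## Analytical method validation

`lod_loq()` implements LOD = 3.3·SD, LOQ = 10·SD from replicate analyses
of a low-level spiked sample (five replicates is the customary design),
so LOQ/LOD = 10/3.3 identically. SD is the **sample** standard deviation
(n−1): with n = 5 the denominator choice changes LOD by ~12% and the
usual convention for small replicate sets is n−1. `recovery_precision()`
reports recovery = 100·mean/spike and RSD = 100·SD/mean;
`check_acceptance()` passes a pesticide when recovery lies in 70–120%
**inclusive** and RSD is **strictly** below 10% (the acceptance wording
is "less than"). `linearity()` is the R² of the OLS calibration line over
all replicate points; a constant response returns 0 (no explained
variance), and the cross-check that R² equals the squared Pearson
correlation is a test oracle, not the implementation. Whether a single
published recovery per pesticide is per-level or pooled is usually
unstated; `method_validation()` therefore reports both per-level rows and
a pooled row (mean across fortification levels).

## Synthetic campaigns

`sim_config()` / `generate_monitoring_dataset()` simulate a campaign:
every sample is independently contaminated with probability
`detection_prob`; a contaminated sample draws one residue (plus an
optional Poisson number of extras, default zero) from a uniformly chosen
pesticide; concentrations are lognormal truncated below at the
pesticide's LOD, and with conditional probability `violation_prob` the
residue is instead drawn above the commodity's MRL. Registered MRLs sit
at the 95th percentile of the concentration model. Defaults are the
reference survey's conditions: its 20 commodities with their actual
sample counts (1,146 in total), the 15 method-validated pesticides with
their reported LODs, detection probability 91/1146 ≈ 7.9%, conditional
violation probability 11/91, and a lognormal with median 0.15 mg/kg and
sdlog 1.2 — chosen once because the survey's detected ranges span roughly
two orders of magnitude (0.015–7.48 mg/kg) around a median of that order;
the concentration parameters are a model choice, not a published value.

What the generator does *not* emulate: seasonal or regional structure,
correlation between pesticides within a sample, measurement error around
the true concentration, or commodity-specific contamination rates.
Passing tests on synthetic data therefore demonstrate the *statistics*
are computed correctly under the stated sampling model, not that real
campaigns look like this.

Tests recover the generator's parameters at campaign scale (10,000
samples, detection rate within 3 standard errors; mean log-concentration
within 3·sdlog/√n in a configuration where truncation is exactly
compensated). These sizes keep the whole suite in seconds.

## Reconstructing the reference survey

`build_survey_fixture()` turns the survey's *published marginal tables*
(occurrence by commodity, incidence by pesticide, and the set of
pesticide x commodity pairs implied by its exposure table) into a full
sample-level dataset whose classification reproduces every published
count exactly. The reconstruction is a pure function of the tables — no
seed — so it is bit-identical across runs.

* **Allocation.** Violations, then below-MRL detections, are allocated to
  allowed pairs as integral transportation problems solved by max-flow
  (igraph), with a lower bound of one detection on every allowed pair.
  Max-flow solves the marginal-matching exactly and fails loudly (with
  the infeasible margin named) on inconsistent inputs, where a greedy
  fill can fail on feasible instances. On the reference tables the
  violation allocation is in fact *forced*: working through the allowed
  pairs, the 11 violations admit exactly one placement.
* **MRLs.** The published incidence table gives only the *range* of MRLs
  per pesticide. The pair holding a violation takes the low endpoint
  (violating concentrations must exceed it); a second violating pair
  takes the high endpoint; otherwise the alphabetically first compliant
  pair takes the low endpoint when feasible and the rest the high one.
  The single pair whose published MRL equals the PLS default
  (fenobucarb/aster scaber) is deliberately left out of the registered
  table so the PLS fallback path is exercised by the reconstruction
  itself. One published cell cannot be honoured: diazinon prints an MRL
  range (0.05–0.1) against a single commodity pair; the fixture uses
  0.05 and the replay test skips the MRL-range equality for diazinon
  only.
* **Concentrations.** Each pair's detections are placed geometrically
  inside their feasible interval (compliant: [range-min, min(MRL,
  range-max)]; violating: (MRL, range-max]), with designated pairs
  pinning the published range endpoints, so each pesticide's detected
  min–max reproduces the published range exactly.
* **LODs.** The validated LOD is used where it is consistent with the
  pesticide's minimum detected concentration. One published inconsistency
  forces a cap: fluopyram's validated LOD (0.022 mg/kg) exceeds its
  minimum detected concentration (0.010 mg/kg); such pesticides (and the
  17 without validation rows) get min(0.01, conc_min) so that every
  reconstructed detection is detectable.
* **Self-check.** The builder reclassifies its own output and stops
  unless every occurrence and incidence count and concentration range
  matches the spec — the reconstruction cannot silently drift.

The 91 = 91 identity between contaminated samples and detections forces
one residue per contaminated sample in the fixture; multi-residue
behaviour is covered by the stochastic generator instead.

## Replaying the published exposure table

The intake values behind the survey's exposure table (consumption, body
weight) are not published and cannot be recovered uniquely, so the
exposure table is treated as *input*: its printed ESTI/EDI cells are fed
through `acute_hq()`/`chronic_hq()` and compared with its printed
aHQ/HQ cells. The printed intakes carry two significant figures, which
bounds the achievable agreement a priori at about 5% relative (half a
unit in the second significant digit); most cells agree within 2% or
within half a unit of their printed decimals, and the handful of cells
whose printed intake provably rounds by more than 2% are held to the 5%
bound, individually enumerated in the test. Two cells are internally
inconsistent in the source beyond any rounding (myclobutanil/aster
scaber HQ prints 0.0036 where its own EDI and ADI give 0.0367;
prochloraz/banana aHQ prints 0.285 where its ESTI and ARfD give 0.260);
they are transcribed verbatim, checked for formula self-consistency, and
excluded from the numeric comparison as documented source defects.

Summing the published HQ cells gives a cumulative index of about 17.68%,
within 0.5% of the survey's pre-rounding 17.714%; recomputing every HQ
from its printed EDI/ADI and summing gives about 17.82%, within the same
print-rounding logic. Both are far below the 100% action threshold.

## Limitations

Deterministic point estimates only: no Monte-Carlo exposure percentiles,
no body-weight or intake distributions by age group, no processing
(washing/peeling) factors. The compliance statistics condition on the
reported LODs; censoring behaviour below the LOD is out of reach of this
kind of survey data by construction.
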