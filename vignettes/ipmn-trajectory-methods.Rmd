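---
title: "Methods: prediagnostic trajectory rules and the synthetic surveillance cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prediagnostic trajectory rules and the synthetic surveillance cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmntraj)
```

`ipmntraj` analyses longitudinal surveillance data of patients with
intraductal papillary mucinous neoplasms (IPMNs) who progress to pancreatic
carcinoma: rule-based classification of prediagnostic CA19-9, HbA1c and
pancreatic-enzyme series, a rules engine for the consensus-guideline
worrisome features (WF) and high-risk stigmata (HRS), cohort-level
contingency and survival statistics, and a seeded synthetic cohort
generator. This vignette documents the model choices, the tunable
parameters, the numerical conventions, and what the synthetic cohort does
and does not establish.

## Time and data model

Calendar dates are ISO-8601 in the four interchange CSVs
(`patients`, `labs`, `imaging`, `events`); internally every timestamp is
converted to days since the patient's baseline, and "years" in outputs are
days / 365.25, matching the 0.1-year resolution at which lead times are
reported. Duplicate same-day measurements of one analyte are rejected, not
averaged: all classification rules hinge on *first documentation*, so
ambiguity must surface as an error. Missing values are empty cells, never
sentinels. The record tracks one dominant lesion per patient; per-lesion
bookkeeping for multifocal IPMNs is out of scope.

Eligibility rules mirror common surveillance-study exclusions and are
checked by `validate_cohort()` as data, not errors: at least 6 months of
follow-up, no carcinoma diagnosis within 6 months of baseline, all entries
inside the follow-up interval.

## Marker rules

The cumulative average — the arithmetic mean of all values strictly before
the index measurement — is the individualised reference. The strict-prefix
convention was a genuinely open choice (a reference including the index
value is conceivable); we exclude the index measurement because a
reference that contains the new value dilutes the very doubling signal it
is meant to detect, and because "reference value" semantics imply prior
data.

For CA19-9 (`classify_ca19_9()`), with ULN 37 U/mL and the 1-year window
read as the half-open interval (dx − 365.25 d, dx]:

* **aberrant elevation**: an in-window value v > ULN that is either the
  first documentation above the ULN, or at least twice the cumulative
  average. The doubled value itself must exceed the ULN. Threshold
  conventions: the ULN comparison is strict (`> 37`), doubling is
  inclusive (`>= 2x`, configurable via `doubling_inclusive`).
* **low to low**: all prediagnostic values ≤ ULN. A transient elevation
  that normalised before the window therefore *excludes* low-to-low
  ("within normal throughout follow-up" is read literally).
* **high to high**: first value > ULN and no in-window doubling of the
  cumulative average.
* **residual / insufficient**: a first exceedance more than a year before
  diagnosis that never doubles in-window falls into an explicit residual
  class rather than being silently coerced; no in-window measurement at
  all is "insufficient data". In the motivating 100-case series the three
  named groups plus the 11 window-missing cases are exhaustive, so the
  residual class is expected to be empty on comparable data.

One caveat discovered while property-testing: "raising a single in-window
value of an aberrant case keeps it aberrant" holds whenever the trigger is
first-documentation, but can fail for doubling-triggered cases, because
raising an *earlier* value also raises the reference that a later value
must double. The monotonicity test is therefore restricted to
first-documentation cases; the behaviour is inherent to any
moving-reference rule, not an implementation artefact.

HbA1c elevation is an in-window rise of ≥ 4 mmol/mol over the cumulative
average, computed on the IFCC scale (NGSP % converted by
IFCC = 10.93 × NGSP − 23.50). Enzyme elevation requires an in-window
pancreatic amylase or lipase value above 3× its ULN *and* at least double
the cumulative average. The enzyme ULNs are not universal constants; the
defaults (pancreatic amylase 50 U/L, lipase 60 U/L) are common laboratory
limits and are exposed in `marker_rules()`. Total amylase is carried in
the data model but drives no rule, and CEA has no classification rule at
all. Patients whose every CA19-9 value sits at or below the assay
detection limit are flagged as plausible Lewis-antigen-negative
(`flag_lewis_negative()`); a sensitivity test confirms that removing them
changes no retained patient's classification.

## Morphology rules

All 12 predicates are evaluated at every imaging *and* laboratory date
with no look-ahead: imaging items use the most recent assessment at or
before the date, the CA19-9 item the most recent value, and event-based
items persist once observed. Evaluating at lab dates too is a deliberate
choice — CA19-9 can first document a worrisome feature at an interim blood
test between imaging visits — and is the reading that makes marker-borne
and imaging-borne features commensurable. The growth criterion is read
literally as "> 5 mm increase relative to some measurement within the
trailing 2 years (730.5 d)" rather than as a fitted slope: reproducible,
and free of regression choices. The jaundice stigma requires both an
obstructive-jaundice event and a pancreatic-head lesion; lesion location
is taken from the diagnosis record, a documented simplification for
patients without one. Non-enhancing nodules trigger neither nodule item,
since both printed items specify enhancement. "Thickened enhanced wall"
has no printed thickness cutoff and is modelled as a boolean radiology
call.

## Statistics

Contingency tables use Pearson's chi-square *without* continuity
correction — verified: the published 2×2 comparison of aberrant elevation
by carcinoma type (14/47 vs 25/42) gives p = 0.005 uncorrected and ≈ 0.009
corrected, so the uncorrected statistic is what the source analysis used.
"As appropriate" is resolved as: Fisher's exact test when a 2×2 table has
an expected cell below 5; larger sparse tables keep the Pearson statistic
with a `small_expected` flag (r×c exact tests are out of scope). Fisher's
two-sided p sums hypergeometric probability mass (no tail doubling).
Wilcoxon rank-sum is exact for combined n ≤ 10 without ties, otherwise the
tie-corrected normal approximation. Survival uses the Kaplan–Meier
product-limit estimator and the log-rank test via the `survival` package;
overall survival runs from carcinoma diagnosis to death of any cause, with
administrative censoring. Report percentages follow the clinical-table
convention (whole numbers at ≥ 10%, one decimal below), and medians/IQRs
use linearly interpolated quantiles rounded to one decimal.

## The synthetic cohort generator

The generator (`cohort_config()`, `generate_cohort()`) emulates the study
conditions: 100 carcinoma cases split evenly between IPMN-derived and
concomitant PDAC; 6-monthly visits (mean 182.6 d, jitter sd 15 d, labs and
imaging co-scheduled); follow-up to diagnosis log-normal with median
5.7 years truncated to 0.6–25.6; the clinical-stage distribution per type;
CA19-9 aberrant-elevation probability conditional on type and stage
stratum (23%/71% for derived stage 0–II/III–IV, 41%/100% for concomitant);
in-window CA19-9 availability of 47/50 and 42/50 per type (so ~11% of
cases are "insufficient data"); HbA1c elevation 3%, enzyme elevation
16%/20%, HRS 86%/16%, at least one WF or HRS in all derived and 49/50
concomitant cases; 8% Lewis-negative, drawn among low-to-low cases since a
Lewis-negative patient cannot show elevation. Lead times are log-normal
with parameters matched to the printed median/IQR anchors (CA19-9 0.4
[0.1–0.5] / 0.1 [0.1–0.7] years; WF/HRS 1.6 [0.7–3.7] / 0.2 [0.1–1.9]
years), truncated at the individual follow-up length.

Design choices worth recording:

* **Quota (variance-controlled) label assignment.** Intended labels are
  assigned per (type, stage-stratum) cell as floor(n·p) plus a Bernoulli
  remainder, positions randomised — not independent Bernoulli draws. The
  generator stands in for one fixed published cohort, and its purpose is
  that a default run reproduces the printed prevalences the way that
  cohort does; full binomial noise would add variance the emulated data do
  not have. Recovery tests still use binomial intervals, which are then
  conservative.
* **Calibrated onset documentation.** For an elevating case the first
  qualifying measurement is placed exactly at the drawn onset time
  (emulating a finding-prompted interim test), with prior values drawn
  from the patient's set-point; the spike is max(1.3–3 × ULN,
  2.2 × prior mean), so both rule clauses fire at the intended time and
  the classifier's lead time equals the generated one to within a day.
* **Noise levels.** Marker noise is multiplicative with log-sd 0.2 (a
  within-patient CV around 20%, an assumption exposed in the config since
  no within-patient variance is published). Set-points are truncated so
  that the rules' false-trigger rate is negligible (e.g. low-pattern
  CA19-9 set-points ≤ 20 U/mL put a 37 U/mL excursion > 3 log-sd away);
  HbA1c assay noise is 0.7 mmol/mol. A persistently elevated
  (high-to-high) series is clipped so that no value doubles its own
  running reference — a set-point that fluctuates without systematic rise.
  The configured prevalences therefore already *contain* whatever
  real-world false positives exist; the generator does not add more.
* **High-to-high observability.** An elevated-at-baseline pattern is only
  observable if baseline predates the 1-year window, so such cases get at
  least 1.2 years of follow-up.
* **Morphology realisation.** All derived cases (and concomitant cases
  that need one for the any-WF guarantee) receive a morphological WF at
  the drawn emergence time (MPD 5.5–8.5 mm, cyst 31–40 mm, or a small
  enhancing nodule, with probabilities 0.5/0.3/0.2); HRS-positive derived
  cases progress from the WF to MPD ≥ 10 mm or a ≥ 5 mm enhancing nodule
  at a later time, while concomitant HRS appears directly. HRS-negative
  cases are constructed never to cross a stigma threshold, so HRS
  prevalence is recovered essentially exactly. Acute pancreatitis occurs
  in 4%/6% of cases; obstructive jaundice events, wall thickening, abrupt
  caliber change and lymphadenopathy are not generated by default (the
  rules engine for them is exercised by hand-built fixtures in the tests).
* Postdiagnosis survival is exponential with stage-ordered medians
  (10/6/2.5/1.2/0.7 years for stages 0–IV; not published, chosen as
  clinically plausible) under uniform 1–8-year administrative censoring —
  enough structure for the log-rank comparison of aberrant vs non-aberrant
  patterns to run, with the aberrant group enriched for advanced stage.

**What passing tests do and do not show.** The generator reproduces the
marginal frequencies, lead-time anchors and co-dependencies (stage–type,
stage–elevation) that the published tables constrain, under clean
log-normal noise and perfectly regular co-scheduled visits. Real
surveillance data have irregular and informative visit timing, assay
changes over 25 years, correlated multimorbidity (diabetes affecting both
HbA1c and pancreatitis risk), and imaging variability — none of which are
modelled. Parameter recovery on synthetic cohorts validates the *pipeline
logic and its calibration*, not the clinical performance of the rules on
real patients.

## Problem sizes and determinism

All randomness flows through a single seed (`generate_cohort(cfg, seed)`);
the same seed reproduces the cohort byte for byte. The test suite runs the
recovery checks at n = 100, 200 and 1000 carcinoma cases and the
oracle-equivalence sweeps on series of length ≤ 7 over coarse value grids
(exhaustively for 4-point series); the full suite and the acceptance
script each complete in a few minutes on a single CPU. Statistical checks
across seeds compare per-patient mean log values, the independent units of
the clustered lab data.

## Known limitations

* The residual class and sub-ULN doubling interactions are specified by
  construction, not by published cases — comparable cohorts may resolve
  them differently.
* Enzyme ULNs and the CA19-9 detection limit are laboratory-specific
  parameters, not published constants.
* The per-patient dominant-lesion model cannot express multifocal disease;
  the jaundice stigma's head-lesion condition relies on the diagnosis
  location.
* Exact r×c tests are not implemented; sparse non-2×2 tables report
  Pearson statistics with a flag.
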