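---
title: "Methods: validating an STLI screening questionnaire against flexion–extension radiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating an STLI screening questionnaire against flexion–extension radiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stliscreen)
```

## Scope and model

Sub-threshold lumbar instability (STLI) is segmental lumbar motion that
exceeds asymptomatic reference ranges without reaching the radiographic
criteria for lumbar instability (LI). `stliscreen` implements the whole
chain by which a 14-item symptom questionnaire is validated as a
screening test for STLI in chronic low back pain, using
flexion–extension radiography as the reference standard:

1. **measurement** — segment kinematics from landmark geometry;
2. **classification** — per-level band thresholds plus a composite
   participant-level rule;
3. **scoring** — the 0–14 questionnaire total;
4. **validation** — per-cut-off accuracy statistics, ROC/AUC, and
   cut-off selection;
5. **reliability** — intra-rater ICC and SEM of the radiographic
   measurements;
6. **simulation** — a seeded synthetic cohort generator emulating the
   study population, so every stage is exercisable without patient data.

## Radiographic measurement

All geometry lives in the 2-D sagittal image plane, x anterior-positive,
y cranial-positive, in mm; angles are in degrees. The image-plane
orientation convention is the package's own choice — every measured
quantity is invariant to the global pose of the film, so the convention
only fixes signs.

Per film, two primitives are measured from six digitised points:

* `endplate_angle()` — the signed angle between the upper vertebra's
  endplate baseline and the lower vertebra's superior endplate baseline
  (the intervertebral angle; the baseline runs through the anterior and
  posterior endplate points). Angles are wrapped to (−180°, 180°].
* `posterior_offset()` — both posterior body corners are projected
  perpendicularly onto the lower vertebra's superior endplate line; the
  signed distance between the projections is measured along that line,
  positive when the upper corner lies anterior.

The segment excursion between films is `rotation = A − (−a)` and
`translation = B − (−b)`. The package reads these formulas as range of
motion: with `A`/`B` the flexion-film values and `a`/`b` the magnitudes
of the extension-film values on the opposite side, the excursion is
`A + a` (resp. `B + b`); equivalently, the difference of the two signed
per-film measurements, which is what `measure_segment()` computes. This
is the only reading under which the formula measures the motion between
the two films rather than their sum of postures.

Coincident landmark points raise a degenerate-geometry error rather than
silently returning zero: a zero-length baseline is a digitisation error,
not a measurement.

Each level is measured three times and the arithmetic mean is carried
forward (`measure_segment_triplicate()`). Repeat-to-repeat noise is
modelled as additive Gaussian error on the measured rotation and
translation, independent across repeats; the default noise scales in the
cohort generator (0.058° rotation, 0.025 mm translation) equal the
study's reported standard errors of measurement, which for repeated
single measures coincide with the within-subject SD.

## Band classification

`default_band_table()` holds, per level, the STLI lower bound (the upper
limit of asymptomatic motion) and the LI threshold:

| level | translation STLI low (mm) | translation LI (mm) | rotation STLI low (°) | rotation LI (°) |
|-------|--------------------------|---------------------|----------------------|-----------------|
| L1/L2 | 1.9 | 4.5 | 11.0 | 15 |
| L2/L3 | 2.4 | 4.5 | 12.6 | 15 |
| L3/L4 | 2.7 | 4.5 | 13.3 | 15 |
| L4/L5 | 2.8 | 4.5 | 14.7 | 20 |
| L5/S1 | 0.5 | 4.5 | 12.8 | 25 |

Boundary convention: the STLI band is closed at both ends ("from 1.9 to
4.5 mm"), so a value equal to the LI threshold is still STLI and LI
requires strictly exceeding it ("greater than 4.5 mm"). Measurements are
treated as absolute excursions; signs are dropped before banding, since
the excursion's sign only encodes which film came first.

The composite rule in `classify_participant()`: any single LI-band value
makes the participant LI (an exclusion criterion in the study — such
participants are flagged and excluded from the accuracy analysis, but
still labelled). Otherwise the participant is STLI when STLI-band
criteria — rotation and translation counted separately — occur in at
least two distinct segments, or when rotation *and* translation fall in
the STLI band within one segment. "Two segments" is read literally as
two distinct levels each contributing at least one criterion of either
type, so translation at one level plus rotation at another counts. The
test suite checks the implementation against an independent
clause-enumeration oracle on fuzzed inputs, and checks monotonicity:
increasing any single measurement never makes the label less severe.

## Questionnaire

`score_responses()` sums 14 binary items (1 = yes); incomplete or
non-binary response sets are rejected, never imputed, because the tool
is interviewer-administered with complete data. `screen_positive()`
applies "score ≥ cutoff"; the validated cut-off is 6/14.

## Diagnostic accuracy

For each cut-off k, participants with score ≥ k screen positive (ties
on the positive side, matching the "≥ k" row labels). Se, Sp,
LR+ = Se/(1−Sp), LR− = (1−Se)/Sp; a ratio with a zero denominator is an
explicit `NA` marker, never infinity, matching the blank cells of the
published table. Percentages render half-up to 2 decimals.

The ROC curve is built from all observed thresholds; the AUC is computed
by the trapezoidal rule *and* as the Mann–Whitney statistic (ties ½),
and the two must agree to 1e-10 — the identity is exact for
threshold-derived curves, so a disagreement indicates an implementation
fault and aborts. The AUC interval is Hanley–McNeil (a Wald interval on
the Hanley–McNeil SE, truncated to [0, 1]); the study does not name its
CI method, so agreement with the published interval end-points is
treated as a soft check only, not asserted by the tests.

**Cut-off selection.** The stated rule "the cut-off reaching maximum
sensitivity" taken literally would select ≥ 5 (Se 100%, Sp 0%), the
degenerate everyone-positive rule, whereas the study selected 6. The
implemented rule is therefore *maximum sensitivity subject to strictly
positive specificity*, ties broken toward the higher cut-off — the only
reading consistent with the selected cut-off. The run log records this
rule on every pipeline run.

**Reconstruction.** Published Se/Sp columns determine the per-group
score histograms up to rounding: positives scoring ≥ k number
`round(Se_k · n_pos)`, negatives `round((1−Sp_k) · n_neg)` (half-up),
and successive differencing recovers per-score counts, with everything
below the lowest tabulated cut-off pooled in a bottom bin. Negative
counts after differencing mean the table is internally inconsistent and
raise an error. Round-tripping the reconstructed histograms through
`accuracy_table()` reproduces every published cell to 2 decimals, and
gives AUC 0.73 at 2 decimals.

**Sample size.** `required_sample_size()` implements the Buderer-type
sensitivity-driven formula n = ⌈z²₁₋α/₂ P(1−P)/(e²·prev)⌉. At the
study's stated inputs (α = 0.01, P = 0.80, e = 0.10, prevalence 0.78) it
yields 137, not the study's 135; the study names no formula, so this is
documented as a discrepancy rather than reconciled.

## Reliability

`icc_intra_rater()` computes the two-way mixed-effects, consistency ICC
from the ANOVA mean squares of a subjects × repeats matrix. The study
does not state the ICC form; single-measures ICC(3,1) is reported by
default as the standard intra-rater choice, with the averaged-measures
ICC(3,k) exposed alongside. Confidence limits use the F distribution of
MS_subjects/MS_error. SEM = pooled SD of all observations × √(1−ICC).
The published ICC/SEM values themselves require the original ten
radiographs and are not reproduced; the tests instead verify parameter
recovery on simulated variance-components data (e.g. between-subject
SD 1.0 with repeat SD 0.045 recovers the population ICC
1/(1+0.045²) ≈ 0.998) and ≥ 90% CI coverage.

## Synthetic cohort generator

`generate_cohort()` draws, per participant: a true label
(Bernoulli at prevalence 0.837, the observed study prevalence; the
earlier conference figure 0.78 can be set via `cohort_spec()`),
demographics, five-level kinematics, triplicate measurements, and
questionnaire responses. All draws flow from one seed; identical spec +
seed gives identical cohorts.

**Kinematics are sampled constructively**, not by rejection: for a
normal participant all ten values land strictly below their STLI lower
bounds (uniform over 15–85% of the bound, away from the boundary); for
an STLI participant a trigger clause is drawn first — with equal
probability criteria in two random segments (one random measure each)
or both measures in one random segment — and the implicated values are
placed uniformly inside their STLI bands. The classifier on the
noise-free kinematics therefore reproduces the generated label with
probability 1, and LI labels are never generated (the study excluded
radiological LI). Empty STLI bands (a malformed override table) raise an
infeasible-specification error. `sample_landmarks()` forward-models film
geometry whose noise-free measurement reproduces given kinematics
exactly, splitting the excursion evenly between films and applying a
random global pose per film; the test suite verifies the round-trip to
1e-9.

**Item responses** are conditionally independent Bernoulli draws given
the group — only marginal rates are published, so no correlation
structure is identifiable. For the STLI group, items 3, 8 and 9 are
pinned to their reported rates (97.35%, 96.46%, 95.58%); the remaining
eleven probabilities, and all fourteen control probabilities, come from
`calibrate_item_probs()`, which least-squares-fits the Poisson-binomial
score pmf to the histograms reconstructed from the published table
(optimised on the logit scale from a fixed deterministic start grid, so
calibration needs no seed). The control calibration puts three items
near 1 — consistent with every study control scoring ≥ 5 — and these are
assigned to items 3, 8, 9, the dominant symptoms in both groups.

An independent-item model is underdispersed relative to the
reconstructed histograms, so the fit has a floor: achieved
total-variation distance ≈ 0.12 (STLI) and ≈ 0.29 (controls), reported
by the calibration object. In consequence the synthetic cohort's Se/Sp
profile tracks the calibrated model, not the published table cell-for-
cell (e.g. implied Se at ≥ 6 is ≈ 95% against the published 99.12%),
and small synthetic cohorts can select a neighbouring cut-off. Passing
tests therefore demonstrate that the pipeline is correct and that the
generator matches its own calibrated population — not that independent
items reproduce the real, positively correlated symptom structure.
Group-level prevalence and the pinned item rates are unaffected by this
simplification and are what the acceptance script measures.

**Demographics** are truncated Gaussians (age truncated to the 20–60
inclusion range, symptom duration to positive values), with parent
parameters moment-matched numerically so the *truncated* distribution
hits the published mean — naive use of the published mean/SD as parent
parameters would shift the age mean to ≈ 37.4 years after truncation.
A bounded support caps the attainable SD, so the SD comes as close as
feasible (age ≈ 10.9 vs published 12.02; duration ≈ 24.5 vs 27.07,
whose SD/mean ≈ 1 would need an exponential-like tail). Pain NRS is
uniform over the 4–7 inclusion range and sex/smoking are Bernoulli at
the published fractions. The published NRS mean (4.63) is below the
uniform's 5.5; matching it would require a non-uniform pmf the study
does not report, so uniform is kept as the default and can be
overridden.

## Problem sizes and numerical choices

The test suite runs the full pipeline at cohort sizes 25–135, the
calibration-closure and demographic checks at n = 1350 (binomial SE on
a proportion ≈ 1 percentage point), classifier fuzzing at 300 cases,
AUC fuzzing at 75 cases, and reliability simulations at 200–300
replicates of the study's 10 × 3 design — sizes at which every asserted
tolerance is a ≥ 4-SE bound. Angle wrap-around uses (−180°, 180°];
band boundaries are compared with plain floating-point comparisons
(band edges are exact decimals); the trapezoid/Mann–Whitney identity is
asserted to 1e-10; calibration restarts from five constant levels with
and without symmetry-breaking jitter, keeping the free items
permutation-identified only.

## Known limitations

* Item correlations within group are not modelled (not identifiable
  from marginal rates); synthetic score distributions are
  underdispersed relative to the study's.
* The published AUC CI end-points and ICC/SEM values are not
  reproduced: the former because the study's CI method is unstated, the
  latter because they require the original radiographs.
* Landmark detection from pixel data is out of scope; the package
  starts from digitised coordinates.
* The sample-size formula reproduces 137, not the study's printed 135.
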