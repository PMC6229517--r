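---
title: "Validating a blood pressure device: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a blood pressure device: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(eship2)
```

## The procedure

`eship2` implements the European Society of Hypertension International
Protocol, 2010 revision (ESH-IP2), as a grading engine for home blood
pressure monitors, together with its heart-rate extension. A validation
study enrolls 33 subjects. Each subject contributes nine consecutive
same-arm readings taken 30–60 s apart, alternating the reference (standard)
and test devices:

| slot | device | use |
|------|--------|-----|
| BPA  | reference | entry reading |
| BPB  | test      | device-detection reading |
| BP1, BP3, BP5, BP7 | reference | analysis |
| BP2, BP4, BP6      | test      | analysis |

BPA and BPB are stored with the session but excluded from the analysis,
which uses only BP1–BP7.

### Favorable-comparison pairing

Each test reading is compared first to the preceding and then to the
following reference reading, and the comparison *more favorable to the
device* — the one with the smaller absolute difference — is kept, giving 3
device-minus-reference differences per subject and 99 per study. Two
points here were genuinely open and are resolved as package defaults:

* **Per-pair, per-metric selection.** Favorability is decided
  independently for each test reading and each metric (SBP, DBP, HR).
  This is the most favorable reading of the rule and the conventional
  practice. `joint_flank_choice = TRUE` instead forces one flank shared by
  SBP and DBP (minimizing the summed absolute SBP + DBP difference), as a
  sensitivity analysis; every report echoes which mode produced it.
* **Ties break to the preceding flank.** Deterministic and time-ordered;
  with equidistant flanks the difference magnitude is unaffected, only the
  recorded reference label and the Bland–Altman pair mean.

### Banded classification and grading

Absolute differences are classified into three nested bands: ≤5/≤10/≤15
mm Hg for blood pressure and ≤3/≤5/≤8 bpm for heart rate. "Within" is
read inclusively (≤); `inclusive = FALSE` is available for sensitivity
checks. The grades are:

* **Part 1** (pooled, 99 comparisons): at least two of the three band
  counts must reach 73/87/96 *and* all three must reach 65/81/93.
* **Part 2** (per subject, 33 subjects): at least 24 subjects with ≥2 of
  their 3 differences in the narrowest band, and at most 3 subjects with
  none.
* **Part 3**: pass iff parts 1 and 2 both pass.

The requirement constants are stored as the absolute counts defined for
the canonical study size (99 comparisons, 33 subjects), not as
proportions: that is how the protocol states them. The engine warns — but
still grades — when a study has a different size. The heart-rate
extension differs from the BP grading *only* in the band thresholds; the
requirement counts are shared.

```{r}
grade_part1(c(71, 95, 98))  # passes: bands 2 and 3 meet the two-of minima
grade_part2(n_two_of_three = 27, n_zero_of_three = 0)
```

### Summary statistics and Bland–Altman analysis

`difference_summary()` reports the sample mean and SD (n − 1 denominator)
of both the signed (test − reference) and the absolute differences. Both
are reported because published validation tables often say "mean
difference" without stating sign handling; neither is privileged.

`bland_altman()` plots the signed difference against the pair mean
`(test + reference)/2` and summarizes bias and limits of agreement
`bias ± 1.96 × SD`. The 1.96 multiplier is the convention and is
configurable. The reference value entering the pair mean is the *same
favorably chosen flank* used for grading, so the figure describes exactly
the differences that were graded; the export sidecar records this.

## The synthetic-study generator

No raw readings are published for real validation studies of this kind,
so the generator is the package's test bed. Per subject and metric it
draws a latent "true" trajectory over the nine reading slots and observes
it through device-specific error:

* baseline ~ Normal(population mean, population SD), with the obese study
  population's defaults SBP 140.64 (16.38) and DBP 77.12 (8.51) mm Hg; no
  HR baseline is published for this population, so a conventional resting
  72 (8) bpm is used (documented as invented);
* a Gaussian **random walk** across slots (default step SD 2 / 1.5 / 1
  for SBP/DBP/HR) — consecutive readings minutes apart are correlated,
  and without the walk the two flanking references would be exchangeable
  and flank choice meaningless;
* reference readings = trajectory + reference noise; test readings =
  trajectory + device bias + device noise. Default noise SDs (3 / 2.5 /
  1.5 per device) are typical oscillometric repeatability figures, chosen
  once as realistic values;
* rounding to integers by default, as both devices display integers;
* resampling enforces `sbp > dbp > 0` and `hr > 0` in every slot, with a
  hard attempt limit so impossible configurations fail loudly.

Subject covariates (age, sex, weight, height, arm circumference) are
drawn from the study population's distributions with BMI resampled to
satisfy the ≥30 kg/m² inclusion criterion. An optional `sbp_strata` mode
draws entry SBP uniformly within user-given ranges, for recruitment-range
stratification; the quotas themselves are protocol-specific and must be
supplied by the user.

What the generator does **not** emulate: cuff–arm interaction artifacts
(conical arms in obese subjects), proportional (pressure-dependent) device
bias, arrhythmia-induced outliers, observer effects. Passing tests on
synthetic data therefore show the *grading machinery* is correct under a
plausible error model, not that any real device passes.

### Selection effects, and how the generator is tested

Because pairing keeps the min-|difference| flank, the selected differences
are not the raw error model: their mean is pulled toward zero relative to
the configured bias and their SD is smaller than the composite
`sqrt(device² + reference² + drift²)`. Parameter-recovery tests therefore
compare `difference_summary()` output against an independent Monte-Carlo
oracle that simulates the selection rule directly from the error-model
parameters, at 30,000 draws, rather than against the naive closed form.
For the unbiased default model the selected mean is symmetric about zero
and is checked against a `4·SD/√n` sampling bound.

`pass_probability()` estimates the part-3 pass rate of an error model by
replicate simulation, with per-replicate seeds derived deterministically
from the configured seed, and attaches a binomial standard error.

## Numerical and interface choices

* All readings are treated as supplied (integers stay integers); pairing
  introduces no rounding.
* Degenerate inputs: fewer than 2 comparisons has no defined SD and
  errors; an empty study pairs to an empty record set; a single session
  grades (with a size warning) but cannot meet the count-based minima.
* Exit statuses of the CLI layer: 0 pass, 3 protocol fail, 2 input error
  — protocol failure is a result, not a program error, so scripts can
  branch on it.
* Report JSON serializes the grades, counts, requirement sets, summary
  statistics and engine options (flank mode, tie-break, inclusivity), and
  round-trips losslessly; per-comparison data are exported separately as
  CSV.

## Problem sizes used in the test suite

The suite grades the published worked examples exactly; runs 1000
randomized small studies (2–8 subjects) against brute-force loop oracles
for pairing and grading; and uses 300–400-subject studies (900–1200
comparisons) for parameter recovery against the 30,000-draw selection
oracle. These sizes give sampling bounds a few times tighter than the
effects being checked while keeping the default test run to a couple of
minutes on one CPU.

## Known limitations

* The engine validates the analysis stage only; recruitment-range quotas
  and observer-agreement machinery of the full protocol are out of scope.
* Requirement constants are meaningful for the canonical 33-subject
  design; other sizes grade against the same absolute counts, which is
  rarely what one wants (hence the warning).
* The generator's additive, homoscedastic error model is a deliberate
  simplification; real oscillometric error grows with pressure and with
  arm circumference.
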