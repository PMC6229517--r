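# eship2

Pass/fail validation of automated blood pressure monitors under the
**European Society of Hypertension International Protocol, 2010 revision
(ESH-IP2)**, with the heart-rate extension (3/5/8 bpm bands).

Validation studies of home blood pressure monitors — including
app-connected cuffs used for self-measurement, and studies in specific
populations such as obese adults — grade a test device against a
reference device on 33 subjects, nine alternating same-arm readings each
(BPA, BPB, then BP1–BP7; only BP1–BP7 are analyzed). `eship2` implements
the complete analysis stage of that protocol for analysts who have the
readings and need the verdict:

* **Pairing.** Each test reading (BP2, BP4, BP6) is compared to both
  flanking reference readings and the comparison more favorable to the
  device (smaller |test − reference|) is kept: 3 differences per subject,
  99 per study.
* **Part 1** (pooled): the counts of differences within ≤5/≤10/≤15 mm Hg
  (≤3/≤5/≤8 bpm for HR) must meet at least two of the minima
  {73, 87, 96} and all of the minima {65, 81, 93}.
* **Part 2** (per subject): ≥24 of 33 subjects with ≥2 of 3 differences
  in the narrowest band, and ≤3 subjects with none.
* **Part 3**: pass iff parts 1 and 2 both pass.
* **Statistics.** Mean (SD) of signed and absolute differences, and
  Bland–Altman analysis (bias, limits of agreement bias ± 1.96 SD) on the
  same favorably chosen pairs.
* **Simulation.** A seeded generator of realistic synthetic studies
  (population baselines, within-subject random-walk drift, configurable
  device bias/noise, integer rounding) plus a Monte-Carlo
  `pass_probability()` for a given device error model.

Everything takes and returns tidy tables, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(eship2)

study  <- generate_study(generator_config(seed = 42))  # 33 synthetic subjects
report <- validate_study(study)                        # sbp + dbp + hr
report
```

```
ESH-IP2 validation report  (33 subjects; favorable-flank pairing)
-----------------------------------------------------------------
SBP  (bands <=5 / <=10 / <=15 mm Hg; n = 99 comparisons)
  Part 1                           <=5   <=10   <=15  Grade 1  Mean (SD)
    Pass requirements  Two of     73     87     96
                       All of     65     81     93
    Achieved                       89     99     99  Pass    -0.19 (3.15)
  Part 2                       2/3 <=5   0/3 <=5   Grade 2
    Pass requirements        >=24       <=3
    Achieved                   33         0   Pass
  Part 3                                                  Pass
...
```

Reading the SBP block: 89 of the 99 favorable-comparison differences were
within 5 mm Hg, 99 within 10 and 15 mm Hg. Two of the three counts exceed
{73, 87, 96} and all exceed {65, 81, 93}, so part 1 passes; all 33
subjects had ≥2 of 3 differences within 5 mm Hg and none had zero, so
part 2 passes; part 3 follows. The mean (SD) signed difference was −0.19
(3.15) mm Hg — this study was simulated with an unbiased test device.

The same pieces are available individually:

```r
cmp <- pair_study(study, "sbp")      # 99 comparison records
difference_summary(cmp)              # mean/SD of signed + absolute diffs
glance(bland_altman(cmp))
#> # A tibble: 1 × 7
#>   metric     n   bias sd_difference loa_low loa_high loa_multiplier
#>   <chr>  <int>  <dbl>         <dbl>   <dbl>    <dbl>          <dbl>
#> 1 sbp       99 -0.192          3.15   -6.37     5.99           1.96
autoplot(bland_altman(cmp))          # Bland-Altman plot
```

Real data enter as a long CSV, one row per reading
(`subject_id,label,sbp,dbp,hr[,age,sex,weight,height,arm_circumference]`),
via `read_sessions()`. Shell wrappers live in `inst/cli/`:

```sh
Rscript inst/cli/simulate.R --out study.csv --seed 7
Rscript inst/cli/validate.R --input study.csv --out results/
# exit status: 0 pass, 3 protocol fail, 2 input error
```

## Scope

The package implements the analysis stage of the protocol: grading,
statistics, reporting and simulation. Recruitment logistics, the
recruitment BP-range quotas, and device hardware concerns (cuff fit on
conical arms, Bluetooth pairing) are out of scope. See the methods
vignette (`vignettes/device-validation.Rmd`) for the model, design
decisions and limitations.
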