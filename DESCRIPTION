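Package: eship2
Title: Blood Pressure Device Validation with the ESH International Protocol (2010 Revision)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating automated blood pressure monitors against a
    reference device under the European Society of Hypertension International
    Protocol, 2010 revision (ESH-IP2), including a heart-rate extension with
    3/5/8 bpm difference bands. Implements the nine-reading session model,
    favorable-comparison pairing of test and reference readings, banded
    difference classification, part 1/2/3 pass-fail grading for systolic and
    diastolic blood pressure and heart rate, difference summary statistics and
    Bland-Altman limits of agreement, plus a seeded generator of synthetic
    33-subject validation studies with configurable device bias, noise and
    within-subject drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
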