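# ESH-IP2 grading engine.
#
# Part 1 grades the 99 pooled device-reference differences against banded
# minima; part 2 grades per-subject performance in the narrowest band;
# part 3 is the conjunction. The requirement constants are absolute counts
# printed for the canonical study size (33 subjects, 99 comparisons) and are
# stored as such, not as proportions.

#' Difference band schemes
#'
#' ESH-IP2 classifies absolute device-reference differences into three
#' nested bands: 5/10/15 mm Hg for blood pressure, and — in the heart-rate
#' extension — 3/5/8 bpm. "Within" is inclusive (<=) by default.
#'
#' @param band1,band2,band3 Strictly increasing positive thresholds.
#' @return A named numeric vector `c(band1=, band2=, band3=)`.
#' @examples
#' bp_bands() # 5 10 15 mm Hg
#' hr_bands() # 3  5  8 bpm
#' @export
band_scheme <- function(band1, band2, band3) {
  if (!(band1 > 0 && band1 < band2 && band2 < band3)) {
    abort("Band thresholds must satisfy 0 < band1 < band2 < band3")
  }
  c(band1 = band1, band2 = band2, band3 = band3)
}

#' @rdname band_scheme
#' @export
bp_bands <- function() band_scheme(5, 10, 15)

#' @rdname band_scheme
#' @export
hr_bands <- function() band_scheme(3, 5, 8)

#' @rdname band_scheme
#' @param metric Metric name; BP metrics get the mm Hg scheme, `"hr"` the
#'   bpm scheme.
#' @export
default_bands <- function(metric) {
  switch(metric, sbp = bp_bands(), dbp = bp_bands(), hr = hr_bands(),
         abort(paste0("No default band scheme for metric '", metric, "'")))
}

#' Protocol pass requirements
#'
#' Part 1: of the three band counts (out of 99 comparisons), at least two
#' must reach 73/87/96 and all three must reach 65/81/93. Part 2: at least
#' 24 of 33 subjects must have >= 2 of their 3 comparisons within the
#' narrowest band, and at most 3 subjects may have none.
#'
#' @return `part1_requirements()`: list with numeric triples `two_of` and
#'   `all_of`. `part2_requirements()`: list with
#'   `min_subjects_two_of_three` and `max_subjects_zero_of_three`.
#' @export
part1_requirements <- function() {
  list(two_of = c(73, 87, 96), all_of = c(65, 81, 93))
}

#' @rdname part1_requirements
#' @export
part2_requirements <- function() {
  list(min_subjects_two_of_three = 24, max_subjects_zero_of_three = 3)
}

#' Count comparisons within each difference band
#'
#' @param comparisons Comparison tibble from [pair_study()], single metric.
#' @param scheme Band scheme from [band_scheme()]; defaults to the metric's
#'   protocol scheme.
#' @param inclusive Logical; count differences equal to a threshold as
#'   within the band (the protocol reading, default `TRUE`).
#' @return One-row tibble: `metric`, `n_total`, `n_within1`, `n_within2`,
#'   `n_within3`.
#' @examples
#' study <- generate_study(generator_config(seed = 7))
#' classify_bands(pair_study(study, "sbp"))
#' @export
classify_bands <- function(comparisons, scheme = NULL, inclusive = TRUE) {
  if (nrow(comparisons) == 0) abort("No comparison records to classify")
  metric <- unique(comparisons$metric)
  if (length(metric) != 1) {
    abort("classify_bands() requires records of a single metric")
  }
  scheme <- scheme %||% default_bands(metric)
  cmp <- if (inclusive) `<=` else `<`
  d <- comparisons$absolute_difference
  tibble::tibble(
    metric = metric,
    n_total = length(d),
    n_within1 = sum(cmp(d, scheme[["band1"]])),
    n_within2 = sum(cmp(d, scheme[["band2"]])),
    n_within3 = sum(cmp(d, scheme[["band3"]]))
  )
}

#' Grade part 1 (pooled measurement criterion)
#'
#' Pass requires at least two of the three band counts to meet the "two of"
#' minima (73/87/96) and all three to meet the "all of" minima (65/81/93).
#'
#' @param counts Either the tibble returned by [classify_bands()] or a
#'   numeric triple of achieved counts (within band 1, 2, 3).
#' @param requirements Requirement list from [part1_requirements()].
#' @return Logical: does the device pass part 1?
#' @examples
#' grade_part1(c(71, 95, 98)) # TRUE (two-of met by bands 2 and 3)
#' grade_part1(c(64, 99, 99)) # FALSE (64 < 65 breaks the all-of minimum)
#' @export
grade_part1 <- function(counts, requirements = part1_requirements()) {
  achieved <- achieved_triple(counts)
  sum(achieved >= requirements$two_of) >= 2 &&
    all(achieved >= requirements$all_of)
}

achieved_triple <- function(counts) {
  if (is.data.frame(counts)) {
    if (nrow(counts) != 1) abort("Expected a single row of band counts")
    achieved <- c(counts$n_within1, counts$n_within2, counts$n_within3)
    if (counts$n_total != 99) {
      warn(paste0(
        "Part-1 requirement constants are printed for 99 comparisons; ",
        "got n_total = ", counts$n_total
      ))
    }
  } else {
    achieved <- as.numeric(counts)
  }
  if (length(achieved) != 3 || any(diff(achieved) < 0)) {
    abort("Band counts must be a nondecreasing triple")
  }
  achieved
}

#' Per-subject narrow-band profiles
#'
#' Counts, for each subject, how many of their 3 comparisons have an
#' absolute difference within the narrowest band.
#'
#' @inheritParams classify_bands
#' @return Tibble with `subject_id` and `n_within_band1` (0-3).
#' @export
profile_subjects <- function(comparisons, scheme = NULL, inclusive = TRUE) {
  metric <- unique(comparisons$metric)
  if (length(metric) != 1) {
    abort("profile_subjects() requires records of a single metric")
  }
  scheme <- scheme %||% default_bands(metric)
  cmp <- if (inclusive) `<=` else `<`
  bad <- names(which(table(comparisons$subject_id) != 3L))
  if (length(bad) > 0) {
    abort(paste0(
      "Each subject must have exactly 3 comparisons; violated for: ",
      paste(bad, collapse = ", ")
    ))
  }
  comparisons |>
    dplyr::summarise(
      n_within_band1 = sum(cmp(.data$absolute_difference, scheme[["band1"]])),
      .by = "subject_id"
    )
}

#' Grade part 2 (per-subject criterion)
#'
#' Pass requires at least `min_subjects_two_of_three` (24) subjects with
#' >= 2 of 3 comparisons within the narrowest band and at most
#' `max_subjects_zero_of_three` (3) subjects with none. Either supply
#' subject profiles, or the two achieved subject counts directly.
#'
#' @param profiles Tibble from [profile_subjects()], or `NULL` when the
#'   counts are given directly.
#' @param requirements Requirement list from [part2_requirements()].
#' @param n_two_of_three,n_zero_of_three Achieved subject counts, used when
#'   `profiles` is `NULL`.
#' @return One-row tibble: `n_two_of_three`, `n_zero_of_three`, `pass`.
#' @examples
#' grade_part2(n_two_of_three = 27, n_zero_of_three = 0)
#' @export
grade_part2 <- function(profiles = NULL, requirements = part2_requirements(),
                        n_two_of_three = NULL, n_zero_of_three = NULL) {
  if (!is.null(profiles)) {
    if (nrow(profiles) != 33) {
      warn(paste0(
        "Part-2 requirement constants are printed for 33 subjects; got ",
        nrow(profiles)
      ))
    }
    n_two_of_three <- sum(profiles$n_within_band1 >= 2)
    n_zero_of_three <- sum(profiles$n_within_band1 == 0)
  }
  tibble::tibble(
    n_two_of_three = n_two_of_three,
    n_zero_of_three = n_zero_of_three,
    pass = n_two_of_three >= requirements$min_subjects_two_of_three &&
      n_zero_of_three <= requirements$max_subjects_zero_of_three
  )
}

#' Grade part 3 (overall verdict)
#'
#' The device passes overall if and only if parts 1 and 2 both pass.
#'
#' @param part1_pass,part2_pass Logicals.
#' @return Logical.
#' @export
grade_part3 <- function(part1_pass, part2_pass) {
  isTRUE(part1_pass) && isTRUE(part2_pass)
}

#' Run the full validation for one metric
#'
#' Composes pairing, band classification, part 1/2/3 grading, difference
#' summary statistics and Bland-Altman analysis into a single report. BP
#' metrics use the 5/10/15 mm Hg scheme; HR uses 3/5/8 bpm.
#'
#' @inheritParams pair_study
#' @inheritParams classify_bands
#' @param scheme Band scheme; defaults to the metric's protocol scheme.
#' @return An object of class `esh_validation` with the band counts, grades,
#'   subject profiles, summary statistics and Bland-Altman result. Has
#'   [tidy()], [glance()], [autoplot()] and `print()` methods.
#' @examples
#' study <- generate_study(generator_config(seed = 11))
#' v <- validate_device(study, "sbp")
#' glance(v)
#' @export
validate_device <- function(sessions, metric = c("sbp", "dbp", "hr"),
                            scheme = NULL, joint_flank_choice = FALSE,
                            inclusive = TRUE) {
  metric <- match.arg(metric)
  scheme <- scheme %||% default_bands(metric)
  sessions <- validate_sessions(sessions)
  n_subjects <- length(unique(sessions$subject_id))
  if (n_subjects != 33) {
    warn(paste0(
      "The protocol's requirement constants are defined for 33 subjects; ",
      "got ", n_subjects
    ))
  }
  comparisons <- pair_study(sessions, metric,
                            joint_flank_choice = joint_flank_choice)
  counts <- classify_bands(comparisons, scheme, inclusive = inclusive)
  part1 <- suppressWarnings(grade_part1(counts))
  profiles <- profile_subjects(comparisons, scheme, inclusive = inclusive)
  part2 <- suppressWarnings(grade_part2(profiles))
  structure(
    list(
      metric = metric,
      n_subjects = n_subjects,
      scheme = scheme,
      part1_requirements = part1_requirements(),
      part2_requirements = part2_requirements(),
      band_counts = counts,
      part1_pass = part1,
      subject_profiles = profiles,
      n_two_of_three = part2$n_two_of_three,
      n_zero_of_three = part2$n_zero_of_three,
      part2_pass = part2$pass,
      part3_pass = grade_part3(part1, part2$pass),
      summary = difference_summary(comparisons),
      bland_altman = bland_altman(comparisons),
      comparisons = comparisons,
      options = list(
        joint_flank_choice = joint_flank_choice,
        inclusive = inclusive,
        tie_break = "preceding"
      )
    ),
    class = "esh_validation"
  )
}

#' Run the full validation for several metrics
#'
#' @inheritParams validate_device
#' @param metrics Metrics to validate (default all three).
#' @return An object of class `esh_study_report`: a per-metric list of
#'   [validate_device()] results plus study metadata.
#' @export
validate_study <- function(sessions, metrics = c("sbp", "dbp", "hr"),
                           joint_flank_choice = FALSE, inclusive = TRUE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  sessions <- validate_sessions(sessions)
  validations <- purrr::map(
    setNames(metrics, metrics),
    ~ validate_device(sessions, .x, joint_flank_choice = joint_flank_choice,
                      inclusive = inclusive)
  )
  structure(
    list(
      validations = validations,
      n_subjects = length(unique(sessions$subject_id)),
      metrics = metrics,
      options = list(
        joint_flank_choice = joint_flank_choice,
        inclusive = inclusive,
        tie_break = "preceding"
      )
    ),
    class = "esh_study_report"
  )
}

#' @export
print.esh_validation <- function(x, ...) {
  cat(render_validation_block(x), sep = "\n")
  invisible(x)
}

#' @export
print.esh_study_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}

#' @rdname validate_device
#' @param x An `esh_validation` object.
#' @param ... Unused.
#' @method tidy esh_validation
#' @export
tidy.esh_validation <- function(x, ...) {
  req <- x$part1_requirements
  achieved <- c(x$band_counts$n_within1, x$band_counts$n_within2,
                x$band_counts$n_within3)
  tibble::tibble(
    metric = x$metric,
    band = paste0("<=", x$scheme),
    threshold = unname(x$scheme),
    achieved = achieved,
    required_two_of = req$two_of,
    required_all_of = req$all_of,
    meets_two_of = achieved >= req$two_of,
    meets_all_of = achieved >= req$all_of
  )
}

#' @rdname validate_device
#' @method glance esh_validation
#' @export
glance.esh_validation <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    n_subjects = x$n_subjects,
    n_comparisons = x$band_counts$n_total,
    n_within1 = x$band_counts$n_within1,
    n_within2 = x$band_counts$n_within2,
    n_within3 = x$band_counts$n_within3,
    n_two_of_three = x$n_two_of_three,
    n_zero_of_three = x$n_zero_of_three,
    part1_pass = x$part1_pass,
    part2_pass = x$part2_pass,
    part3_pass = x$part3_pass,
    mean_signed = x$summary$mean_signed,
    sd_signed = x$summary$sd_signed,
    mean_absolute = x$summary$mean_absolute,
    sd_absolute = x$summary$sd_absolute
  )
}

#' @rdname validate_device
#' @method glance esh_study_report
#' @export
glance.esh_study_report <- function(x, ...) {
  purrr::map(x$validations, glance) |> purrr::list_rbind()
}

#' @rdname validate_device
#' @param object An `esh_validation` object (for `autoplot`).
#' @method autoplot esh_validation
#' @export
autoplot.esh_validation <- function(object, ...) {
  d <- tidy(object)
  d$band <- factor(d$band, levels = d$band)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$achieved)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$required_two_of,
                                     shape = "two-of minimum"), size = 3) +
    ggplot2::geom_point(ggplot2::aes(y = .data$required_all_of,
                                     shape = "all-of minimum"), size = 3) +
    ggplot2::labs(
      title = paste0(toupper(object$metric), " part 1: achieved band counts"),
      x = "absolute difference band", y = "comparisons within band",
      shape = NULL
    ) +
    ggplot2::theme_minimal()
}
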