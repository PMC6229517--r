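# Human-readable report rendering, JSON serialization, and the CLI surface.
#
# Exit statuses (stable contract for shell scripting):
#   0 - all requested metrics pass part 3
#   2 - input or configuration error
#   3 - the device fails the protocol (a result, not a program error)

EXIT_OK <- 0L
EXIT_INPUT_ERROR <- 2L
EXIT_PROTOCOL_FAIL <- 3L

pass_label <- function(x) if (isTRUE(x)) "Pass" else "Fail"

render_validation_block <- function(v) {
  unit <- if (v$metric == "hr") "bpm" else "mm Hg"
  bands <- sprintf("<=%g", v$scheme)
  req1 <- v$part1_requirements
  req2 <- v$part2_requirements
  bc <- v$band_counts
  s <- v$summary
  c(
    sprintf("%s  (bands %s %s; n = %d comparisons)",
            toupper(v$metric), paste(bands, collapse = " / "), unit,
            bc$n_total),
    sprintf("  Part 1 %22s %6s %6s %6s  %-6s  %s",
            "", bands[1], bands[2], bands[3], "Grade 1", "Mean (SD)"),
    sprintf("    Pass requirements  Two of %6d %6d %6d",
            req1$two_of[1], req1$two_of[2], req1$two_of[3]),
    sprintf("                       All of %6d %6d %6d",
            req1$all_of[1], req1$all_of[2], req1$all_of[3]),
    sprintf("    Achieved %17s %6d %6d %6d  %-6s  %.2f (%.2f)",
            "", bc$n_within1, bc$n_within2, bc$n_within3,
            pass_label(v$part1_pass), s$mean_signed, s$sd_signed),
    sprintf("  Part 2 %21s 2/3 %s   0/3 %s   Grade 2", "",
            bands[1], bands[1]),
    sprintf("    Pass requirements %11s %9s", sprintf(">=%d", req2$min_subjects_two_of_three),
            sprintf("<=%d", req2$max_subjects_zero_of_three)),
    sprintf("    Achieved %20d %9d   %s",
            v$n_two_of_three, v$n_zero_of_three, pass_label(v$part2_pass)),
    sprintf("  Part 3 %48s %s", "", pass_label(v$part3_pass))
  )
}

#' Render a study report as fixed-width text tables
#'
#' One block per metric mirroring the protocol's result-table layout: the
#' "Two of" / "All of" part-1 pass requirements against the achieved band
#' counts, the part-2 subject counts, and the part-3 verdict.
#'
#' @param report An `esh_study_report` from [validate_study()] or
#'   [read_report_json()].
#' @return A character vector of text lines.
#' @export
render_tables <- function(report) {
  header <- sprintf(
    "ESH-IP2 validation report  (%d subjects; favorable-flank pairing%s)",
    report$n_subjects,
    if (isTRUE(report$options$joint_flank_choice)) ", joint SBP/DBP flank" else ""
  )
  blocks <- purrr::map(report$validations, render_validation_block)
  c(header, strrep("-", nchar(header)),
    unlist(purrr::imap(blocks, ~ c(.x, ""))))
}

validation_to_list <- function(v) {
  list(
    metric = v$metric,
    n_subjects = v$n_subjects,
    scheme = as.list(v$scheme),
    part1_requirements = v$part1_requirements,
    part2_requirements = v$part2_requirements,
    band_counts = as.list(v$band_counts),
    part1_pass = v$part1_pass,
    n_two_of_three = v$n_two_of_three,
    n_zero_of_three = v$n_zero_of_three,
    part2_pass = v$part2_pass,
    part3_pass = v$part3_pass,
    summary = as.list(v$summary),
    bland_altman = as.list(glance(v$bland_altman)),
    options = v$options
  )
}

#' Write and read a study report as JSON
#'
#' Serializes the grading outcome (schemes, requirements, achieved counts,
#' grades, summary statistics, Bland-Altman summary, engine options) so
#' that the text tables can be regenerated losslessly. Per-comparison data
#' are not part of the report JSON; export those with
#' [write_comparisons()] or [export_bland_altman()].
#'
#' @param report An `esh_study_report`.
#' @param path JSON file path.
#' @return `write_report_json()`: the path, invisibly.
#'   `read_report_json()`: an `esh_study_report` (without the per-subject
#'   and per-comparison tables).
#' @export
write_report_json <- function(report, path) {
  out <- list(
    n_subjects = report$n_subjects,
    metrics = report$metrics,
    options = report$options,
    validations = purrr::map(report$validations, validation_to_list)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  validations <- purrr::map(x$validations, function(v) {
    ba <- v$bland_altman
    structure(
      list(
        metric = v$metric,
        n_subjects = v$n_subjects,
        scheme = unlist(v$scheme),
        part1_requirements = v$part1_requirements,
        part2_requirements = v$part2_requirements,
        band_counts = tibble::as_tibble(v$band_counts),
        part1_pass = v$part1_pass,
        n_two_of_three = v$n_two_of_three,
        n_zero_of_three = v$n_zero_of_three,
        part2_pass = v$part2_pass,
        part3_pass = v$part3_pass,
        summary = tibble::as_tibble(v$summary),
        bland_altman = structure(
          list(pairs = NULL, bias = ba$bias, sd_difference = ba$sd_difference,
               loa_low = ba$loa_low, loa_high = ba$loa_high,
               loa_multiplier = ba$loa_multiplier, metric = ba$metric,
               n = ba$n),
          class = "bland_altman"
        ),
        options = v$options
      ),
      class = "esh_validation"
    )
  })
  names(validations) <- x$metrics
  structure(
    list(
      validations = validations,
      n_subjects = x$n_subjects,
      metrics = x$metrics,
      options = x$options
    ),
    class = "esh_study_report"
  )
}

#' Command-line validation entry point
#'
#' Reads a session CSV, runs the full validation and writes `report.json`
#' and `report.txt` into `out_dir`. Intended to back a thin Rscript wrapper
#' (see `inst/cli/validate.R`); returns the exit status rather than calling
#' `quit()` so it is testable in-process.
#'
#' @param input Path to a session CSV.
#' @param out_dir Output directory (created if needed).
#' @param metrics Metrics to validate.
#' @param joint_flank_choice,inclusive Engine options, echoed into the
#'   report.
#' @param height_unit Passed to [read_sessions()].
#' @param quiet Suppress the rendered tables on stdout.
#' @return Invisibly, the exit status: 0 if every requested metric passes
#'   part 3, 3 on protocol failure, 2 on input error.
#' @export
cli_validate <- function(input, out_dir = ".",
                         metrics = c("sbp", "dbp", "hr"),
                         joint_flank_choice = FALSE, inclusive = TRUE,
                         height_unit = "m", quiet = FALSE) {
  report <- tryCatch(
    {
      sessions <- read_sessions(input, height_unit = height_unit)
      suppressWarnings(validate_study(
        sessions, metrics,
        joint_flank_choice = joint_flank_choice, inclusive = inclusive
      ))
    },
    error = function(e) {
      message("Input error: ", conditionMessage(e))
      NULL
    }
  )
  if (is.null(report)) return(invisible(EXIT_INPUT_ERROR))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_json(report, file.path(out_dir, "report.json"))
  writeLines(render_tables(report), file.path(out_dir, "report.txt"))
  if (!quiet) cat(render_tables(report), sep = "\n")
  all_pass <- all(vapply(report$validations, `[[`, logical(1), "part3_pass"))
  invisible(if (all_pass) EXIT_OK else EXIT_PROTOCOL_FAIL)
}

#' Command-line simulation entry point
#'
#' Generates a synthetic study and writes it as a session CSV, recording
#' the seed in a `#` comment line that [read_sessions()] skips. Generator
#' parameters come from a YAML config file and/or direct overrides.
#'
#' @param out Output CSV path.
#' @param config_path Optional YAML file whose keys are
#'   [generator_config()] arguments.
#' @param ... Direct [generator_config()] overrides (take precedence over
#'   the YAML file).
#' @return Invisibly, the exit status: 0 on success, 2 on invalid
#'   configuration.
#' @export
cli_simulate <- function(out, config_path = NULL, ...) {
  status <- tryCatch(
    {
      args <- if (!is.null(config_path)) yaml::read_yaml(config_path) else list()
      args <- modifyList(args, list(...))
      config <- do.call(generator_config, args)
      study <- generate_study(config)
      write_sessions(study, out,
                     comment = paste0("seed: ", config$seed %||% "none"))
      EXIT_OK
    },
    error = function(e) {
      message("Input error: ", conditionMessage(e))
      EXIT_INPUT_ERROR
    }
  )
  invisible(status)
}
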