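# Session model: one subject's ordered nine-reading protocol visit.
#
# Reading slots, in protocol order. BPA (entry, reference device) and BPB
# (device-detection, test device) are recorded but excluded from the
# validation analysis, which uses only BP1-BP7.

PROTOCOL_LABELS <- c("BPA", "BPB", "BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7")
REFERENCE_LABELS <- c("BPA", "BP1", "BP3", "BP5", "BP7")
TEST_LABELS <- c("BPB", "BP2", "BP4", "BP6")
ANALYSIS_TEST_LABELS <- c("BP2", "BP4", "BP6")
METRICS <- c("sbp", "dbp", "hr")
COVARIATE_COLS <- c("age", "sex", "weight", "height", "arm_circumference")
SESSION_COLS <- c("subject_id", "label", "role", "sbp", "dbp", "hr")

#' Protocol reading labels and device roles
#'
#' The nine-reading session alternates the reference (standard) and test
#' devices: BPA (entry reading, reference), BPB (device-detection reading,
#' test), then BP1/BP3/BP5/BP7 with the reference device interleaved with
#' BP2/BP4/BP6 with the test device. Only BP1-BP7 enter the validation
#' analysis.
#'
#' @return `protocol_labels()` returns the nine labels in protocol order;
#'   `label_role()` returns `"reference"` or `"test"` for each label.
#' @param label Character vector of reading labels.
#' @examples
#' protocol_labels()
#' label_role(c("BP1", "BP2"))
#' @export
protocol_labels <- function() PROTOCOL_LABELS

#' @rdname protocol_labels
#' @export
label_role <- function(label) {
  bad <- setdiff(unique(label), PROTOCOL_LABELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown reading label(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(label %in% REFERENCE_LABELS, "reference", "test")
}

#' Validate a session table
#'
#' Checks the structural invariants of a long-format session table: known
#' labels, no duplicate (subject, label) pairs, physiologic ordering
#' `sbp > dbp > 0` and `hr > 0`, and (in strict mode) session completeness —
#' exactly one reading per protocol slot for every subject.
#'
#' @param data A data frame with columns `subject_id`, `label`, `sbp`, `dbp`,
#'   `hr` and optionally `age`, `sex`, `weight`, `height`, `arm_circumference`.
#' @param strictness `"strict"` (default) errors on incomplete sessions;
#'   `"permissive"` flags them in a logical `session_complete` column instead.
#' @return A tibble ordered by subject and protocol slot, with a derived
#'   `role` column and, in permissive mode, a `session_complete` column.
#' @export
validate_sessions <- function(data, strictness = c("strict", "permissive")) {
  strictness <- match.arg(strictness)
  data <- tibble::as_tibble(data)

  required <- c("subject_id", "label", "sbp", "dbp", "hr")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }

  data$subject_id <- as.character(data$subject_id)
  data$label <- as.character(data$label)
  for (m in METRICS) data[[m]] <- as.numeric(data[[m]])

  bad_label <- which(!data$label %in% PROTOCOL_LABELS)
  if (length(bad_label) > 0) {
    abort(paste0(
      "Unknown reading label '", data$label[bad_label[1]],
      "' at row ", bad_label[1]
    ))
  }

  dup <- duplicated(data[, c("subject_id", "label")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0(
      "Duplicate reading for subject '", data$subject_id[i],
      "', label ", data$label[i], " at row ", i
    ))
  }

  bad_val <- which(!(data$sbp > data$dbp & data$dbp > 0 & data$hr > 0))
  if (length(bad_val) > 0) {
    i <- bad_val[1]
    abort(paste0(
      "Implausible reading at row ", i, " (subject '", data$subject_id[i],
      "'): requires sbp > dbp > 0 and hr > 0"
    ))
  }

  data$role <- label_role(data$label)

  counts <- table(data$subject_id)
  complete_ids <- names(counts)[counts == 9L]
  incomplete <- setdiff(unique(data$subject_id), complete_ids)
  if (strictness == "strict" && length(incomplete) > 0) {
    abort(paste0(
      "Incomplete session(s) for subject(s): ",
      paste(incomplete, collapse = ", "),
      " (a complete session has exactly 9 readings, one per label)"
    ))
  }

  data <- dplyr::arrange(
    data,
    .data$subject_id,
    match(.data$label, PROTOCOL_LABELS)
  )
  if (strictness == "permissive") {
    data$session_complete <- !data$subject_id %in% incomplete
  }

  keep <- c(SESSION_COLS, intersect(COVARIATE_COLS, names(data)),
            if (strictness == "permissive") "session_complete")
  data[, keep]
}

#' Read measurement sessions from CSV
#'
#' Reads long-format session data — one row per reading with columns
#' `subject_id,label,sbp,dbp,hr` and optional subject covariates — and
#' validates the protocol structure. Lines starting with `#` are treated as
#' comments (the simulator records its seed this way).
#'
#' @inheritParams validate_sessions
#' @param path Path to a UTF-8 CSV file.
#' @param height_unit Unit of the optional `height` column: `"m"` (default)
#'   or `"cm"`, converted to meters on ingest.
#' @return A validated session tibble (see [validate_sessions()]).
#' @examples
#' study <- generate_study(generator_config(n_subjects = 2, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_sessions(study, f)
#' read_sessions(f)
#' @export
read_sessions <- function(path, strictness = c("strict", "permissive"),
                          height_unit = c("m", "cm")) {
  strictness <- match.arg(strictness)
  height_unit <- match.arg(height_unit)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (height_unit == "cm" && "height" %in% names(data)) {
    data$height <- data$height / 100
  }
  validate_sessions(data, strictness = strictness)
}

#' Write measurement sessions to CSV
#'
#' Writes a session table in the same long CSV layout accepted by
#' [read_sessions()], so that a write/read round trip is the identity.
#'
#' @param sessions A validated session tibble.
#' @param path Output file path.
#' @param comment Optional character vector of comment lines written (each
#'   prefixed with `# `) before the header, e.g. the generator seed.
#' @return The input, invisibly.
#' @export
write_sessions <- function(sessions, path, comment = NULL) {
  sessions <- validate_sessions(sessions)
  out <- sessions[, c(setdiff(SESSION_COLS, "role"),
                      intersect(COVARIATE_COLS, names(sessions)))]
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(sessions)
}

#' Body mass index (Quetelet's equation)
#'
#' BMI = weight (kg) / height (m) squared. The study population is obese
#' adults, defined by the inclusion criterion BMI >= 30 kg/m^2.
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in meters (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' body_mass_index(90, 1.5) # 40, well above the obesity threshold
#' body_mass_index(30, 1.0) # exactly at the BMI >= 30 inclusion boundary
#' @export
body_mass_index <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    abort("body_mass_index() requires weight > 0 kg and height > 0 m")
  }
  weight / height^2
}
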