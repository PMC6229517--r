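# Favorable-comparison pairing.
#
# Each test reading (BP2, BP4, BP6) is flanked by two reference readings
# (BP1/BP3, BP3/BP5, BP5/BP7). The protocol first compares the test reading
# to the preceding reference and then to the following one, and keeps the
# comparison more favorable to the device, i.e. the flank with the smaller
# absolute difference. Ties break to the preceding (earlier) flank.

FLANKS <- list(
  BP2 = c("BP1", "BP3"),
  BP4 = c("BP3", "BP5"),
  BP6 = c("BP5", "BP7")
)

#' Pair test readings with their favorable reference readings
#'
#' For every test reading in every complete session, computes the signed
#' (test minus reference) and absolute differences against both flanking
#' reference readings and keeps the flank with the smaller absolute
#' difference. Ties break to the preceding flank. Selection is per test
#' reading and per metric; `joint_flank_choice = TRUE` instead forces one
#' flank shared by SBP and DBP (chosen to minimize the summed absolute
#' SBP + DBP difference), a sensitivity-analysis mode.
#'
#' @param sessions A validated session tibble (see [validate_sessions()]);
#'   all sessions must be complete.
#' @param metric One of `"sbp"`, `"dbp"`, `"hr"`.
#' @param joint_flank_choice Logical; share the flank choice between SBP and
#'   DBP rather than minimizing each metric separately. Ignored for HR.
#' @return A tibble with 3 rows per subject: `subject_id`, `test_label`,
#'   `chosen_reference_label`, `metric`, `test_value`, `reference_value`,
#'   `signed_difference`, `absolute_difference`.
#' @examples
#' study <- generate_study(generator_config(n_subjects = 3, seed = 42))
#' pair_study(study, "sbp")
#' @export
pair_study <- function(sessions, metric = c("sbp", "dbp", "hr"),
                       joint_flank_choice = FALSE) {
  metric <- match.arg(metric)
  sessions <- validate_sessions(sessions, strictness = "permissive")
  if (!all(sessions$session_complete)) {
    bad <- unique(sessions$subject_id[!sessions$session_complete])
    abort(paste0(
      "Pairing requires complete sessions; incomplete for subject(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  if (nrow(sessions) == 0) {
    return(tibble::tibble(
      subject_id = character(), test_label = character(),
      chosen_reference_label = character(), metric = character(),
      test_value = numeric(), reference_value = numeric(),
      signed_difference = numeric(), absolute_difference = numeric()
    ))
  }

  # wide layout: one row per subject, one column per label, per metric
  wide <- function(m) {
    sessions |>
      dplyr::select("subject_id", "label", dplyr::all_of(m)) |>
      tidyr::pivot_wider(names_from = "label", values_from = dplyr::all_of(m))
  }
  w <- wide(metric)
  use_joint <- isTRUE(joint_flank_choice) && metric %in% c("sbp", "dbp")
  if (use_joint) {
    w_sbp <- wide("sbp")
    w_dbp <- wide("dbp")
  }

  purrr::map(ANALYSIS_TEST_LABELS, function(tl) {
    fl <- FLANKS[[tl]]
    d_prev <- w[[tl]] - w[[fl[1]]]
    d_next <- w[[tl]] - w[[fl[2]]]
    if (use_joint) {
      score_prev <- abs(w_sbp[[tl]] - w_sbp[[fl[1]]]) +
        abs(w_dbp[[tl]] - w_dbp[[fl[1]]])
      score_next <- abs(w_sbp[[tl]] - w_sbp[[fl[2]]]) +
        abs(w_dbp[[tl]] - w_dbp[[fl[2]]])
    } else {
      score_prev <- abs(d_prev)
      score_next <- abs(d_next)
    }
    take_prev <- score_prev <= score_next
    tibble::tibble(
      subject_id = w$subject_id,
      test_label = tl,
      chosen_reference_label = ifelse(take_prev, fl[1], fl[2]),
      metric = metric,
      test_value = w[[tl]],
      reference_value = ifelse(take_prev, w[[fl[1]]], w[[fl[2]]]),
      signed_difference = ifelse(take_prev, d_prev, d_next),
      absolute_difference = abs(ifelse(take_prev, d_prev, d_next))
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$subject_id, match(.data$test_label, ANALYSIS_TEST_LABELS))
}

#' @rdname pair_study
#' @param session A single complete session (nine readings of one subject).
#' @export
pair_session <- function(session, metric = c("sbp", "dbp", "hr"),
                         joint_flank_choice = FALSE) {
  metric <- match.arg(metric)
  if (length(unique(session$subject_id)) > 1) {
    abort("pair_session() expects readings of a single subject")
  }
  pair_study(session, metric, joint_flank_choice = joint_flank_choice)
}

#' Export comparison records to CSV
#'
#' @param comparisons A comparison tibble from [pair_study()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_comparisons <- function(comparisons, path) {
  readr::write_csv(comparisons, path, progress = FALSE)
  invisible(comparisons)
}
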