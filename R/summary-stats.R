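# Difference summaries and Bland-Altman method-comparison analysis.

#' Summary statistics of paired differences
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' signed (test minus reference) and of the absolute differences.
#'
#' @param comparisons Comparison tibble from [pair_study()], single metric,
#'   at least 2 records.
#' @return One-row tibble: `metric`, `n`, `mean_signed`, `sd_signed`,
#'   `mean_absolute`, `sd_absolute`.
#' @export
difference_summary <- function(comparisons) {
  metric <- unique(comparisons$metric)
  if (length(metric) != 1) {
    abort("difference_summary() requires records of a single metric")
  }
  if (nrow(comparisons) < 2) {
    abort("At least 2 comparison records are needed for a standard deviation")
  }
  tibble::tibble(
    metric = metric,
    n = nrow(comparisons),
    mean_signed = mean(comparisons$signed_difference),
    sd_signed = sd(comparisons$signed_difference),
    mean_absolute = mean(comparisons$absolute_difference),
    sd_absolute = sd(comparisons$absolute_difference)
  )
}

#' Bland-Altman analysis of device-reference agreement
#'
#' For each comparison, the pair mean `(test + reference) / 2` is plotted
#' against the signed difference. The reference value is the favorably
#' chosen flank, the same one used for grading, so the figure and the
#' pass-fail analysis describe the same differences. Bias is the mean
#' signed difference; the limits of agreement are `bias +/- k * SD` with
#' `k = 1.96` by convention.
#'
#' @inheritParams difference_summary
#' @param loa_multiplier Half-width of the limits of agreement in SD units
#'   (default 1.96).
#' @return An object of class `bland_altman`: list with `pairs` (tibble of
#'   `pair_mean`, `signed_difference`), `bias`, `sd_difference`, `loa_low`,
#'   `loa_high`, `loa_multiplier`, `metric`, `n`.
#' @examples
#' study <- generate_study(generator_config(seed = 5))
#' ba <- bland_altman(pair_study(study, "sbp"))
#' glance(ba)
#' @export
bland_altman <- function(comparisons, loa_multiplier = 1.96) {
  metric <- unique(comparisons$metric)
  if (length(metric) != 1) {
    abort("bland_altman() requires records of a single metric")
  }
  required <- c("test_value", "reference_value", "signed_difference")
  if (!all(required %in% names(comparisons))) {
    abort("Comparison records must carry test_value and reference_value")
  }
  d <- comparisons$signed_difference
  if (any(abs(comparisons$test_value - comparisons$reference_value - d) >
            sqrt(.Machine$double.eps))) {
    abort("signed_difference does not match test_value - reference_value")
  }
  bias <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  structure(
    list(
      pairs = tibble::tibble(
        pair_mean = (comparisons$test_value + comparisons$reference_value) / 2,
        signed_difference = d
      ),
      bias = bias,
      sd_difference = s,
      loa_low = bias - loa_multiplier * s,
      loa_high = bias + loa_multiplier * s,
      loa_multiplier = loa_multiplier,
      metric = metric,
      n = length(d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (%s, n = %d): bias %.2f, SD %.2f, LoA [%.2f, %.2f]\n",
    x$metric, x$n, x$bias, x$sd_difference, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, n = x$n, bias = x$bias,
    sd_difference = x$sd_difference,
    loa_low = x$loa_low, loa_high = x$loa_high,
    loa_multiplier = x$loa_multiplier
  )
}

#' @rdname bland_altman
#' @param object A `bland_altman` object (for `autoplot`).
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  unit <- if (object$metric == "hr") "bpm" else "mm Hg"
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pair_mean,
                               y = .data$signed_difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      title = paste0(toupper(object$metric), ": Bland-Altman"),
      x = paste0("pair mean (", unit, ")"),
      y = paste0("test - reference (", unit, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Export Bland-Altman plot data
#'
#' Writes the per-pair plot data as CSV and the bias/SD/limits as a JSON
#' sidecar, enough to regenerate a Bland-Altman figure elsewhere.
#'
#' @param result A `bland_altman` object.
#' @param path CSV output path.
#' @param sidecar JSON sidecar path; defaults to `path` with a
#'   `_summary.json` suffix.
#' @return Invisibly, the sidecar path.
#' @export
export_bland_altman <- function(result, path, sidecar = NULL) {
  if (result$n == 0) abort("Refusing to export an empty Bland-Altman result")
  sidecar <- sidecar %||%
    paste0(sub("\\.csv$", "", path), "_summary.json")
  readr::write_csv(result$pairs, path, progress = FALSE)
  jsonlite::write_json(
    list(
      metric = result$metric, n = result$n, bias = result$bias,
      sd_difference = result$sd_difference, loa_low = result$loa_low,
      loa_high = result$loa_high, loa_multiplier = result$loa_multiplier
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
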