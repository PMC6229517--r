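# Seeded generator of synthetic validation studies.
#
# Error model per subject and metric: a latent true trajectory over the nine
# reading slots (baseline draw from the population distribution plus a
# Gaussian random walk, since consecutive readings 30-60 s apart are
# correlated), observed through device-specific additive bias and noise.
# Reference readings observe the trajectory with reference noise; test
# readings add the configured device bias and device noise. Values are
# rounded to integers by default, as oscillometric displays are.

metric_vec <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- setNames(rep(as.numeric(x), 3), METRICS)
  }
  if (!all(METRICS %in% names(x))) {
    abort(paste0(what, " must be a single number or named for sbp, dbp, hr"))
  }
  as.numeric(x[METRICS]) |> setNames(METRICS)
}

#' Configuration for the synthetic study generator
#'
#' Population baselines default to the study population of obese adults:
#' SBP 140.64 (SD 16.38) and DBP 77.12 (SD 8.51) mm Hg. No HR baseline is
#' reported for this population, so a conventional resting default of
#' 72 (SD 8) bpm is used. Per-metric error parameters may be given as a
#' single number (recycled) or a vector named `sbp`, `dbp`, `hr`.
#'
#' @param n_subjects Number of subjects (protocol canonical: 33).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,hr_mean,hr_sd Population baseline
#'   distributions (mm Hg / bpm).
#' @param drift_sd Within-subject random-walk SD per reading step.
#' @param device_bias Additive test-device bias.
#' @param device_noise_sd,reference_noise_sd Per-reading measurement noise SD
#'   of the test and reference devices.
#' @param rounding `"integer"` (default, as devices display) or `"none"`.
#' @param covariates Logical; also draw age, sex, weight, height and arm
#'   circumference from the study population's distributions (BMI resampled
#'   to satisfy the >= 30 kg/m^2 inclusion criterion).
#' @param sbp_strata Optional stratified-draw mode: a data frame with
#'   columns `min`, `max`, `n` giving SBP baseline ranges and subject counts
#'   per recruitment stratum (uniform draws within range). `NULL` (default)
#'   draws all baselines from the normal population model.
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- generator_config(seed = 1, device_bias = c(sbp = 3, dbp = 2, hr = 1))
#' @export
generator_config <- function(n_subjects = 33,
                             seed = NULL,
                             sbp_mean = 140.64, sbp_sd = 16.38,
                             dbp_mean = 77.12, dbp_sd = 8.51,
                             hr_mean = 72, hr_sd = 8,
                             drift_sd = c(sbp = 2, dbp = 1.5, hr = 1),
                             device_bias = 0,
                             device_noise_sd = c(sbp = 3, dbp = 2.5, hr = 1.5),
                             reference_noise_sd = c(sbp = 3, dbp = 2.5, hr = 1.5),
                             rounding = c("integer", "none"),
                             covariates = TRUE,
                             sbp_strata = NULL) {
  rounding <- match.arg(rounding)
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    seed = if (!is.null(seed)) as.integer(seed),
    sbp_mean = sbp_mean, sbp_sd = sbp_sd,
    dbp_mean = dbp_mean, dbp_sd = dbp_sd,
    hr_mean = hr_mean, hr_sd = hr_sd,
    drift_sd = metric_vec(drift_sd, "drift_sd"),
    device_bias = metric_vec(device_bias, "device_bias"),
    device_noise_sd = metric_vec(device_noise_sd, "device_noise_sd"),
    reference_noise_sd = metric_vec(reference_noise_sd, "reference_noise_sd"),
    rounding = rounding,
    covariates = covariates,
    sbp_strata = sbp_strata
  )
  sds <- c(cfg$sbp_sd, cfg$dbp_sd, cfg$hr_sd, cfg$drift_sd,
           cfg$device_noise_sd, cfg$reference_noise_sd)
  if (any(sds < 0)) abort("All standard deviations must be >= 0")
  structure(cfg, class = "generator_config")
}

round_if <- function(x, rounding) {
  if (rounding == "integer") round(x) else x
}

# one subject's 9 readings across the three metrics; resamples until the
# physiologic invariants (sbp > dbp > 0, hr > 0) hold in every slot
simulate_subject <- function(cfg, subject_id, max_attempts = 1000L) {
  roles <- label_role(PROTOCOL_LABELS)
  for (attempt in seq_len(max_attempts)) {
    vals <- purrr::map(setNames(METRICS, METRICS), function(m) {
      baseline <- switch(m,
        sbp = rnorm(1, cfg$sbp_mean, cfg$sbp_sd),
        dbp = rnorm(1, cfg$dbp_mean, cfg$dbp_sd),
        hr = rnorm(1, cfg$hr_mean, cfg$hr_sd)
      )
      traj <- baseline + cumsum(c(0, rnorm(8, 0, cfg$drift_sd[[m]])))
      noise <- ifelse(
        roles == "test",
        cfg$device_bias[[m]] + rnorm(9, 0, cfg$device_noise_sd[[m]]),
        rnorm(9, 0, cfg$reference_noise_sd[[m]])
      )
      round_if(traj + noise, cfg$rounding)
    })
    ok <- all(vals$sbp > vals$dbp) && all(vals$dbp > 0) && all(vals$hr > 0)
    if (ok) {
      return(tibble::tibble(
        subject_id = subject_id,
        label = PROTOCOL_LABELS,
        sbp = vals$sbp, dbp = vals$dbp, hr = vals$hr
      ))
    }
  }
  abort(paste0(
    "Could not generate physiologically consistent readings for subject '",
    subject_id, "' within ", max_attempts,
    " attempts; check that dbp_mean is well below sbp_mean relative to the SDs"
  ))
}

simulate_covariates <- function(n) {
  # study population: obese adults; resample weight/height until BMI >= 30
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(14, 19) / 33)
  age <- pmin(pmax(round(rnorm(n, 59.88, 14.97)), 25), 95)
  weight <- numeric(n)
  height <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      w <- rnorm(1, 91.06, 11.74)
      h <- rnorm(1, 167.52, 7.06) / 100
      if (w > 0 && h > 0 && body_mass_index(w, h) >= 30) break
    }
    weight[i] <- round(w, 1)
    height[i] <- round(h, 2)
  }
  tibble::tibble(
    age = age, sex = sex, weight = weight, height = height,
    arm_circumference = round(rnorm(n, 320.70, 35.35))
  )
}

#' Generate a synthetic validation study
#'
#' Draws `n_subjects` complete nine-reading sessions under the configured
#' error model. Reproducible: the same config (including seed) yields an
#' identical study.
#'
#' @param config A [generator_config()].
#' @return A validated session tibble, ready for [validate_study()] or
#'   [write_sessions()].
#' @examples
#' study <- generate_study(generator_config(n_subjects = 5, seed = 3))
#' nrow(study) # 45 readings
#' @export
generate_study <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    abort("config must be created with generator_config()")
  }
  run <- function() {
    strata_baselines <- NULL
    if (!is.null(config$sbp_strata)) {
      s <- config$sbp_strata
      if (sum(s$n) != config$n_subjects) {
        abort("sbp_strata counts must sum to n_subjects")
      }
      strata_baselines <- unlist(purrr::pmap(
        s, function(min, max, n) runif(n, min, max)
      ))
    }
    ids <- sprintf("S%02d", seq_len(config$n_subjects))
    sessions <- purrr::map(seq_along(ids), function(i) {
      cfg_i <- config
      if (!is.null(strata_baselines)) {
        # stratified entry SBP: fixed baseline, drift/noise still apply
        cfg_i$sbp_strata <- NULL
        cfg_i$sbp_mean <- strata_baselines[i]
        cfg_i$sbp_sd <- 0
      }
      simulate_subject(cfg_i, ids[i])
    }) |> purrr::list_rbind()
    if (config$covariates) {
      cov <- simulate_covariates(config$n_subjects)
      cov$subject_id <- ids
      sessions <- dplyr::left_join(sessions, cov, by = "subject_id")
    }
    sessions
  }
  out <- if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
  validate_sessions(out)
}

#' Monte-Carlo pass probability of a device error model
#'
#' Repeatedly generates studies under `config` (with per-replicate seeds
#' derived from `config$seed`) and estimates the probability that the
#' device passes part 3 for the given metric, with a binomial standard
#' error.
#'
#' @param config A [generator_config()].
#' @param n_replicates Number of simulated studies (>= 1).
#' @param metric Metric to validate.
#' @return One-row tibble: `metric`, `n_replicates`, `pass_probability`,
#'   `se`.
#' @export
pass_probability <- function(config, n_replicates = 50,
                             metric = c("sbp", "dbp", "hr")) {
  metric <- match.arg(metric)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  base_seed <- config$seed %||% 0L
  passes <- vapply(seq_len(n_replicates), function(r) {
    cfg_r <- config
    cfg_r$seed <- (base_seed + 104729L * r) %% .Machine$integer.max
    study <- generate_study(cfg_r)
    suppressWarnings(validate_device(study, metric))$part3_pass
  }, logical(1))
  p <- mean(passes)
  tibble::tibble(
    metric = metric,
    n_replicates = as.integer(n_replicates),
    pass_probability = p,
    se = sqrt(p * (1 - p) / n_replicates)
  )
}
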