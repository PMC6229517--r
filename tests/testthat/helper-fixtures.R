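# Fixture builders and independent oracles.
#
# The oracles re-evaluate the protocol rules with plain loops and explicit
# conditionals, deliberately avoiding the package's vectorized code paths.

LABELS9 <- c("BPA", "BPB", "BP1", "BP2", "BP3", "BP4", "BP5", "BP6", "BP7")

# one complete session from per-label values (defaults keep sbp > dbp > 0)
make_session <- function(subject_id = "S01", sbp = rep(120, 9),
                         dbp = sbp - 50, hr = rep(70, 9)) {
  tibble::tibble(
    subject_id = subject_id, label = LABELS9,
    sbp = sbp, dbp = dbp, hr = hr
  )
}

# random integer-valued complete sessions, physiologically plausible
random_sessions <- function(n_subjects) {
  purrr::map(seq_len(n_subjects), function(i) {
    make_session(
      subject_id = sprintf("R%02d", i),
      sbp = round(rnorm(9, 140, 12)),
      dbp = round(rnorm(9, 75, 7)),
      hr = round(rnorm(9, 72, 6))
    )
  }) |> purrr::list_rbind()
}

# ---- brute-force pairing: loop over subjects, test slots and both flanks
oracle_pair <- function(sessions, metric) {
  flanks <- list(BP2 = c("BP1", "BP3"), BP4 = c("BP3", "BP5"),
                 BP6 = c("BP5", "BP7"))
  out <- list()
  for (id in sort(unique(sessions$subject_id))) {
    s <- sessions[sessions$subject_id == id, ]
    val <- function(lbl) s[[metric]][s$label == lbl]
    for (tl in names(flanks)) {
      fp <- flanks[[tl]][1]
      fn <- flanks[[tl]][2]
      dp <- val(tl) - val(fp)
      dn <- val(tl) - val(fn)
      if (abs(dp) <= abs(dn)) {
        chosen <- fp; d <- dp
      } else {
        chosen <- fn; d <- dn
      }
      out[[length(out) + 1]] <- data.frame(
        subject_id = id, test_label = tl, chosen_reference_label = chosen,
        metric = metric, signed_difference = d, absolute_difference = abs(d)
      )
    }
  }
  do.call(rbind, out)
}

# ---- brute-force grading straight from the printed rules
oracle_grades <- function(sessions, metric) {
  prs <- oracle_pair(sessions, metric)
  b <- if (metric == "hr") c(3, 5, 8) else c(5, 10, 15)
  within1 <- 0; within2 <- 0; within3 <- 0
  for (d in prs$absolute_difference) {
    if (d <= b[1]) within1 <- within1 + 1
    if (d <= b[2]) within2 <- within2 + 1
    if (d <= b[3]) within3 <- within3 + 1
  }
  achieved <- c(within1, within2, within3)
  two_of_met <- sum(achieved >= c(73, 87, 96)) >= 2
  all_of_met <- achieved[1] >= 65 && achieved[2] >= 81 && achieved[3] >= 93
  part1 <- two_of_met && all_of_met
  n2 <- 0; n0 <- 0
  for (id in unique(prs$subject_id)) {
    k <- sum(prs$absolute_difference[prs$subject_id == id] <= b[1])
    if (k >= 2) n2 <- n2 + 1
    if (k == 0) n0 <- n0 + 1
  }
  part2 <- n2 >= 24 && n0 <= 3
  list(
    achieved = achieved, part1 = part1,
    n_two_of_three = n2, n_zero_of_three = n0, part2 = part2,
    part3 = part1 && part2
  )
}

# ---- Monte-Carlo oracle for the favorable-selection error model:
# simulates the distribution of the chosen (min-|.|, tie to preceding)
# signed difference directly from the generator's parameters, without the
# session machinery; returns its mean and SD
oracle_selected_moments <- function(bias, device_sd, reference_sd, drift_sd,
                                    rounding = TRUE, n_sim = 30000) {
  base <- runif(n_sim, 100, 200) # arbitrary offsets so rounding is generic
  t_prev <- base
  t_test <- t_prev + rnorm(n_sim, 0, drift_sd)
  t_next <- t_test + rnorm(n_sim, 0, drift_sd)
  r <- function(x) if (rounding) round(x) else x
  test <- r(t_test + bias + rnorm(n_sim, 0, device_sd))
  ref_prev <- r(t_prev + rnorm(n_sim, 0, reference_sd))
  ref_next <- r(t_next + rnorm(n_sim, 0, reference_sd))
  dp <- test - ref_prev
  dn <- test - ref_next
  d <- ifelse(abs(dp) <= abs(dn), dp, dn)
  list(mean = mean(d), sd = sd(d))
}

# comparison records built directly from absolute differences (3 per subject)
make_comparisons <- function(abs_diffs, metric = "sbp", signs = 1) {
  n <- length(abs_diffs)
  stopifnot(n %% 3 == 0)
  tibble::tibble(
    subject_id = rep(sprintf("C%02d", seq_len(n / 3)), each = 3),
    test_label = rep(c("BP2", "BP4", "BP6"), n / 3),
    chosen_reference_label = rep(c("BP1", "BP3", "BP5"), n / 3),
    metric = metric,
    signed_difference = abs_diffs * signs,
    absolute_difference = abs_diffs
  )
}
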