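test_that("the generator is reproducible and structurally valid", {
  cfg <- generator_config(n_subjects = 10, seed = 55)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)

  expect_equal(nrow(a), 90)
  expect_true(all(a$sbp > a$dbp))
  expect_true(all(a$dbp > 0 & a$hr > 0))
  expect_true(all(a$role == label_role(a$label)))
  expect_true(all(table(a$subject_id) == 9))
  # integer displays by default
  expect_true(all(a$sbp == round(a$sbp)))

  cont <- generate_study(generator_config(n_subjects = 2, seed = 55,
                                          rounding = "none"))
  expect_false(all(cont$sbp == round(cont$sbp)))
})

test_that("generated covariates respect the obesity inclusion criterion", {
  study <- generate_study(generator_config(n_subjects = 20, seed = 8))
  subj <- dplyr::distinct(study, subject_id, weight, height, sex, age)
  expect_equal(nrow(subj), 20)
  expect_true(all(body_mass_index(subj$weight, subj$height) >= 30))
  expect_true(all(subj$sex %in% c("male", "female")))

  bare <- generate_study(generator_config(n_subjects = 3, seed = 8,
                                          covariates = FALSE))
  expect_false("weight" %in% names(bare))
})

test_that("degenerate error models produce the exact expected differences", {
  perfect <- generate_study(generator_config(
    seed = 6, device_noise_sd = 0, reference_noise_sd = 0, drift_sd = 0
  ))
  for (m in c("sbp", "dbp", "hr")) {
    expect_true(all(pair_study(perfect, m)$absolute_difference == 0))
  }

  biased <- generate_study(generator_config(
    seed = 6, device_bias = c(sbp = 20, dbp = 0, hr = 0),
    device_noise_sd = 0, reference_noise_sd = 0, drift_sd = 0
  ))
  expect_true(all(pair_study(biased, "sbp")$signed_difference == 20))
  expect_true(all(pair_study(biased, "dbp")$signed_difference == 0))
})

test_that("an unbiased device shows no systematic difference", {
  study <- generate_study(generator_config(n_subjects = 33, seed = 77))
  s <- difference_summary(pair_study(study, "sbp"))
  # total per-comparison error SD: sqrt(3^2 + 3^2 + 2^2) ~ 4.69 mm Hg
  expect_lt(abs(s$mean_signed), 4 * sqrt(22) / sqrt(99))
})

test_that("difference summaries recover the selection-model moments", {
  # the favorable (min-|difference|) selection shifts the mean below the
  # configured bias and shrinks the SD; the expected moments come from an
  # independent Monte-Carlo oracle of the error model
  cfg <- generator_config(
    n_subjects = 400, seed = 303,
    device_bias = c(sbp = 4, dbp = 0, hr = 0)
  )
  s <- difference_summary(pair_study(generate_study(cfg), "sbp"))

  withr::local_seed(404)
  want <- oracle_selected_moments(
    bias = 4, device_sd = 3, reference_sd = 3, drift_sd = 2
  )
  expect_lt(abs(s$mean_signed - want$mean), 5 * want$sd / sqrt(s$n))
  expect_lt(abs(s$sd_signed - want$sd) / want$sd, 0.05)
  # selection makes the observed spread narrower than the raw error model
  expect_lt(s$sd_signed, sqrt(3^2 + 3^2 + 2^2))
})

test_that("impossible physiologic constraints hit the resampling limit", {
  bad <- generator_config(
    n_subjects = 1, seed = 1,
    sbp_mean = 100, sbp_sd = 0.1, dbp_mean = 150, dbp_sd = 0.1
  )
  expect_error(generate_study(bad), "attempts")
})

test_that("stratified entry-pressure draws keep sessions well-formed", {
  cfg <- generator_config(
    n_subjects = 6, seed = 10,
    sbp_strata = data.frame(min = c(110, 140, 170), max = c(130, 160, 190),
                            n = c(2, 2, 2))
  )
  study <- generate_study(cfg)
  expect_equal(length(unique(study$subject_id)), 6)
  expect_true(all(table(study$subject_id) == 9))

  off <- generator_config(n_subjects = 5, seed = 10,
                          sbp_strata = data.frame(min = 110, max = 130, n = 3))
  expect_error(generate_study(off), "sum to n_subjects")
})

test_that("pass probability is exact for degenerate devices and stable", {
  perfect <- generator_config(seed = 1, device_noise_sd = 0,
                              reference_noise_sd = 0, drift_sd = 0)
  expect_equal(pass_probability(perfect, 10, "sbp")$pass_probability, 1)

  hopeless <- generator_config(seed = 1, device_bias = c(sbp = 20, dbp = 0, hr = 0),
                               device_noise_sd = 0, reference_noise_sd = 0,
                               drift_sd = 0)
  expect_equal(pass_probability(hopeless, 10, "sbp")$pass_probability, 0)

  # an intermediate device: two independent estimates agree within 3 SEs
  mid <- generator_config(seed = 11, device_bias = c(sbp = 5, dbp = 0, hr = 0))
  p1 <- pass_probability(mid, 20, "sbp")
  mid$seed <- 2222L
  p2 <- pass_probability(mid, 20, "sbp")
  se <- sqrt(p1$se^2 + p2$se^2 + 1e-12)
  expect_lt(abs(p1$pass_probability - p2$pass_probability), max(3 * se, 0.3))
})
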