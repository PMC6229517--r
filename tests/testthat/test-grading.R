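test_that("band classification counts inclusively against the thresholds", {
  cmp <- tibble::tibble(
    subject_id = "X", metric = "sbp",
    signed_difference = c(0, 5, 7, 12, 16),
    absolute_difference = c(0, 5, 7, 12, 16)
  )
  counts <- classify_bands(cmp)
  expect_equal(counts$n_total, 5)
  expect_equal(c(counts$n_within1, counts$n_within2, counts$n_within3),
               c(2, 3, 4))

  zeros <- classify_bands(make_comparisons(rep(0, 6)))
  expect_equal(zeros$n_within1, 6)
  expect_equal(zeros$n_within3, 6)

  # strict mode drops boundary differences: of {5,10,15,4,9,14} only
  # {4} < 5, {4,5,9} < 10 and {4,5,9,10,14} < 15
  strict <- classify_bands(make_comparisons(c(5, 10, 15, 4, 9, 14)),
                           inclusive = FALSE)
  expect_equal(c(strict$n_within1, strict$n_within2, strict$n_within3),
               c(1, 3, 5))
})

test_that("band counts are monotone and widen with the thresholds", {
  withr::local_seed(99)
  for (i in 1:20) {
    cmp <- make_comparisons(abs(rnorm(30, 0, 8)))
    c1 <- classify_bands(cmp)
    expect_true(c1$n_within1 <= c1$n_within2)
    expect_true(c1$n_within2 <= c1$n_within3)
    expect_true(c1$n_within3 <= c1$n_total)
    wider <- classify_bands(cmp, scheme = band_scheme(6, 11, 16))
    expect_true(wider$n_within1 >= c1$n_within1)
    expect_true(wider$n_within2 >= c1$n_within2)
    expect_true(wider$n_within3 >= c1$n_within3)
  }
})

test_that("part 1 applies the two-of and all-of minima as printed", {
  expect_true(grade_part1(c(71, 95, 98)))  # SBP: two-of met by bands 2 and 3
  expect_true(grade_part1(c(84, 91, 98)))  # DBP
  expect_true(grade_part1(c(90, 94, 98)))  # HR against the shared triples
  expect_false(grade_part1(c(64, 99, 99))) # 64 < 65 breaks the all-of floor
  expect_false(grade_part1(c(72, 86, 97))) # only one two-of minimum met
  expect_error(grade_part1(c(90, 80, 99)), "nondecreasing")
})

test_that("subject profiles count narrow-band comparisons per subject", {
  cmp <- make_comparisons(c(2, 5, 9, 0, 0, 0, 6, 7, 8))
  prof <- suppressWarnings(profile_subjects(cmp))
  expect_equal(prof$n_within_band1, c(2, 3, 0))
  bad <- cmp[-1, ]
  expect_error(profile_subjects(bad), "exactly 3")
})

test_that("part 2 applies the subject-count thresholds as printed", {
  expect_true(grade_part2(n_two_of_three = 27, n_zero_of_three = 0)$pass)
  expect_true(grade_part2(n_two_of_three = 30, n_zero_of_three = 0)$pass)
  expect_true(grade_part2(n_two_of_three = 31, n_zero_of_three = 1)$pass)
  expect_false(grade_part2(n_two_of_three = 23, n_zero_of_three = 0)$pass)
  expect_false(grade_part2(n_two_of_three = 30, n_zero_of_three = 4)$pass)

  prof <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:33),
    n_within_band1 = c(rep(3, 20), rep(2, 7), rep(1, 5), 0)
  )
  g <- grade_part2(prof)
  expect_equal(g$n_two_of_three, 27)
  expect_equal(g$n_zero_of_three, 1)
  expect_true(g$pass)
})

test_that("part 3 is the conjunction of parts 1 and 2", {
  for (p1 in c(TRUE, FALSE)) {
    for (p2 in c(TRUE, FALSE)) {
      expect_equal(grade_part3(p1, p2), p1 && p2)
    }
  }
})

test_that("improving any band count never flips a grade from pass to fail", {
  withr::local_seed(5)
  for (i in 1:200) {
    a <- sort(sample(0:99, 3))
    b <- pmin(a + sample(0:5, 3, replace = TRUE), 99) |> sort()
    if (grade_part1(a)) expect_true(grade_part1(pmax(a, b)))
  }
  for (i in 1:100) {
    n2 <- sample(0:33, 1)
    n0 <- sample(0:(33 - n2), 1)
    if (grade_part2(n_two_of_three = n2, n_zero_of_three = n0)$pass) {
      expect_true(grade_part2(n_two_of_three = min(n2 + 1, 33),
                              n_zero_of_three = max(n0 - 1, 0))$pass)
    }
  }
})

test_that("a perfect device passes and a grossly biased one fails", {
  perfect <- generate_study(generator_config(
    seed = 1, device_noise_sd = 0, reference_noise_sd = 0, drift_sd = 0
  ))
  for (m in c("sbp", "dbp", "hr")) {
    v <- validate_device(perfect, m)
    expect_true(v$part1_pass)
    expect_true(v$part2_pass)
    expect_true(v$part3_pass)
    expect_equal(v$band_counts$n_within1, 99)
  }

  biased <- generate_study(generator_config(
    seed = 2, device_bias = c(sbp = 20, dbp = 0, hr = 0),
    device_noise_sd = 0, reference_noise_sd = 0, drift_sd = 0
  ))
  v <- validate_device(biased, "sbp")
  expect_equal(v$band_counts$n_within3, 0) # every difference is 20 mm Hg
  expect_false(v$part1_pass)
  expect_false(v$part3_pass)
})

test_that("the report object is internally consistent and tidies cleanly", {
  study <- generate_study(generator_config(seed = 31))
  v <- validate_device(study, "dbp")
  expect_equal(v$part3_pass, v$part1_pass && v$part2_pass)
  expect_equal(v$n_two_of_three, sum(v$subject_profiles$n_within_band1 >= 2))
  expect_equal(v$summary$mean_signed, v$bland_altman$bias)

  td <- tidy(v)
  expect_equal(nrow(td), 3)
  expect_equal(td$achieved, c(v$band_counts$n_within1, v$band_counts$n_within2,
                              v$band_counts$n_within3))
  gl <- glance(v)
  expect_equal(gl$part3_pass, v$part3_pass)

  report <- validate_study(study)
  expect_equal(nrow(glance(report)), 3)
  expect_s3_class(autoplot(v), "ggplot")
})
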