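test_that("the exam schedule matches the policy arithmetic", {
  s <- build_schedule(screening_policy(interval = 1 / 3, duration = 6))
  expect_length(s, floor(6 / (1 / 3)) + 1)  # 19 exams
  expect_equal(s[1], 0)
  expect_equal(s[length(s)], 6)
  expect_true(all(diff(s) > 0))

  expect_identical(build_schedule(screening_policy(duration = 0)), 0)
  expect_length(build_schedule(screening_policy(interval = 1, duration = 6)), 7)
})

test_that("a perfect test detects at the first exam in the detectable window", {
  test <- test_characteristics()  # sens 1, syserr 0
  # stage II window [49, 53.5), surfacing at 54; exams at trial times 0..6,
  # entry age 48: first exam inside the window is trial time 1 (age 49)
  path <- make_path(t_II = 49, t_III = 53.5, dx_age = 54)
  out <- apply_screening(path, death_age = 100, trial_entry_age = 48,
                         schedule = 0:6, test = test, attendance_prob = 1)
  expect_identical(out$mode, "screen_detected")
  expect_equal(out$dx_time, 1)
  expect_identical(out$dx_stage_group, "II_minus")
  # lead time is positive: detection precedes the clinical surfacing time
  expect_lt(out$dx_time, path$clinical_dx_age - 48)

  # a tumor already in stage III at an exam is detected in group III+
  out3 <- apply_screening(make_path(t_II = 40, t_III = 47, dx_age = 60),
                          100, 48, 0:6, test, 1)
  expect_identical(out3$dx_stage_group, "III_plus")
  expect_equal(out3$dx_time, 0)
})

test_that("a useless or unattended test never screen-detects", {
  path <- make_path(t_II = 49, t_III = 53.5, dx_age = 54)
  zero <- test_characteristics(sens_II = 0, sens_III = 0)
  set.seed(61)
  modes <- replicate(50, apply_screening(path, 100, 48, 0:6, zero, 1)$mode)
  expect_true(all(modes == "clinically_diagnosed"))

  perfect <- test_characteristics()
  out <- apply_screening(path, 100, 48, 0:6, perfect, attendance_prob = 0)
  expect_identical(out$mode, "clinically_diagnosed")
  expect_equal(out$dx_time, 54 - 48)
  expect_identical(out$dx_stage_group, "III_plus")

  # diagnosis censored by death: surfacing after death is never diagnosed
  out2 <- apply_screening(path, death_age = 50, trial_entry_age = 48,
                          schedule = numeric(0), test = perfect,
                          attendance_prob = 1)
  expect_identical(out2$mode, "never_diagnosed")
})

test_that("detection frequency matches hit/miss enumeration at spot settings", {
  # s = 0.5, no systematic error, 3 exams in window: 1 - 0.5^3
  expect_equal(enum_detect_prob(rep("II", 3), 0.5, 0.5), 0.875)
  # s = 0.5, syserr 0.2, 2 exams: 0.5 + 0.5 * (1 - min(1, 0.5 + 0.2))
  expect_equal(enum_detect_prob(rep("II", 2), 0.5, 0.5, 0.2, 0.2), 0.65)

  path <- make_path(t_II = 49, t_III = 53.5, dx_age = 54)
  test <- test_characteristics(sens_II = 0.5, sens_III = 0.5,
                               syserr_II = 0.2, syserr_III = 0.2)
  n <- 2e4
  set.seed(62)
  hits <- sum(replicate(n, apply_screening(path, 100, 48,
                                           schedule = c(1, 2),
                                           test, 1)$mode) == "screen_detected")
  p <- 0.65
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("saturating systematic error clips the repeat-miss probability", {
  # miss' = min(1, (1 - 0.5) + 0.9) = 1: only the first exam can detect
  expect_equal(enum_detect_prob(rep("II", 4), 0.5, 0.5, 0.9, 0.9), 0.5)
  path <- make_path(t_II = 49, t_III = 53.5, dx_age = 54)
  test <- test_characteristics(sens_II = 0.5, sens_III = 0.5,
                               syserr_II = 0.9, syserr_III = 0.9)
  set.seed(63)
  n <- 2e4
  hits <- sum(replicate(n, apply_screening(path, 100, 48, c(1, 1.5, 2, 2.5),
                                           test, 1)$mode) == "screen_detected")
  expect_lt(abs(hits / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("raising stage II sensitivity never loses stage II detections (CRN)", {
  cfg <- small_config()
  lo <- simulate_trial(cfg, test = test_characteristics(sens_II = 0.6, sens_III = 0.8),
                       oversample = 3, seed = 64)
  hi <- simulate_trial(cfg, test = test_characteristics(sens_II = 0.9, sens_III = 0.8),
                       oversample = 3, seed = 64)
  expect_gte(cell_count(hi, "intervention", "screen_detected", "II_minus"),
             cell_count(lo, "intervention", "screen_detected", "II_minus"))
})

test_that("indolent paths stay screen-detectable for life but never surface", {
  test <- test_characteristics()
  path <- make_path(t_II = 49, indolent = TRUE)
  # detectable years after stage II entry, long after any finite stage III
  out <- apply_screening(path, 100, 48, schedule = c(20, 21), test = test,
                         attendance_prob = 1)
  expect_identical(out$mode, "screen_detected")
  expect_identical(out$dx_stage_group, "II_minus")
  out2 <- apply_screening(path, 100, 48, numeric(0), test, 1)
  expect_identical(out2$mode, "never_diagnosed")
})
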