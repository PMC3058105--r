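test_that("onset sampling respects the lifetime probability and the Weibull law", {
  nh <- default_natural_history()
  nh$onset$lifetime_onset_prob <- c(0, 0, 0)
  set.seed(11)
  expect_true(all(is.na(sample_onset(nh, "squamous", risk_factor = 2, n = 500))))

  nh2 <- default_natural_history()
  nh2$onset$weibull_shape[1] <- 2
  nh2$onset$weibull_mean[1] <- 70
  nh2$onset$lifetime_onset_prob[1] <- 1
  set.seed(12)
  x <- sample_onset(nh2, "squamous", n = 1e5)
  expect_true(all(!is.na(x)))
  # closed-form Weibull: mean 70, sd = scale * sqrt(gamma(2) - gamma(1.5)^2)
  scale <- 70 / gamma(1.5)
  sdx <- scale * sqrt(gamma(2) - gamma(1.5)^2)
  expect_lt(abs(mean(x) - 70), 3 * sdx / sqrt(1e5))
  gof <- suppressWarnings(ks.test(x, pweibull, shape = 2, scale = scale))
  expect_gt(gof$p.value, 1e-3)

  expect_error(sample_onset(nh2, "squamous", risk_factor = 1.5),
               "invalid probability")
  expect_error(sample_onset(nh2, "squamous", risk_factor = -1), "positive")
})

test_that("disease paths honor stage ordering and degenerate parameter values", {
  nh <- default_natural_history()
  nh$progression$indolent_fraction <- rep(1, 3)
  set.seed(21)
  for (i in 1:50) {
    p <- sample_disease_path(50, sample(cell_types(), 1), nh)
    expect_true(p$indolent)
    expect_true(is.na(p$clinical_dx_age))
    expect_true(is.na(p$stage_entry_ages[["CLIN_III"]]))
  }

  nh2 <- default_natural_history()
  nh2$progression$p_clinical_dx_at_III <- rep(1, 3)
  set.seed(22)
  for (i in 1:50) {
    p <- sample_disease_path(50, "adeno_large", nh2)
    expect_identical(p$clinical_dx_stage, "CLIN_III")
    expect_true(is.na(p$stage_entry_ages[["CLIN_IV"]]))
  }

  # invariants over a mixed sweep: entry ages strictly increase along the
  # visited stages, surfacing only in stage III or IV
  nh3 <- default_natural_history()
  nh3$progression$indolent_fraction <- rep(0.3, 3)
  set.seed(23)
  for (i in 1:300) {
    p <- sample_disease_path(runif(1, 40, 70), sample(cell_types(), 1), nh3)
    ages <- p$stage_entry_ages[!is.na(p$stage_entry_ages)]
    expect_true(all(diff(ages) > 0))
    if (p$indolent) {
      expect_true(is.na(p$clinical_dx_age))
    } else {
      expect_true(p$clinical_dx_stage %in% c("CLIN_III", "CLIN_IV"))
      expect_gt(p$clinical_dx_age, p$stage_entry_ages[["CLIN_III"]])
    }
  }
})

test_that("simulated preclinical dwell time matches the exponential mean", {
  nh <- default_natural_history()
  nh$progression$mean_dwell_II <- rep(2, 3)
  nh$progression$indolent_fraction <- rep(0, 3)
  set.seed(31)
  dwell <- replicate(1e5, {
    p <- sample_disease_path(50, "squamous", nh)
    p$stage_entry_ages[["CLIN_III"]] - p$stage_entry_ages[["PRE_II"]]
  })
  expect_lt(abs(mean(dwell) - 2), 3 * 2 / sqrt(1e5))
  expect_lt(abs(sd(dwell) - 2), 4 * 2 / sqrt(1e5))
})

test_that("other-cause death follows the life table", {
  lt1 <- life_table(40:99, rep(1, 60))
  set.seed(41)
  d <- replicate(20, sample_other_cause_death(lt1, 50))
  expect_true(all(d >= 50 & d < 51))

  lt0 <- life_table(40:99, rep(0, 60))
  expect_identical(sample_other_cause_death(lt0, 57.5), 100)
  expect_error(sample_other_cause_death(lt0, 20), "range")

  # constant hazard: years survived is geometric (failures before death)
  # plus the uniform within-year placement
  q <- 0.1
  ltq <- life_table(0:299, rep(q, 300))
  set.seed(42)
  y <- replicate(1e5, sample_other_cause_death(ltq, 0))
  target <- (1 - q) / q + 0.5
  sd_y <- sqrt((1 - q) / q^2)
  expect_lt(abs(mean(y) - target), 3 * sd_y / sqrt(1e5))
})

test_that("equal risk factors make the two arms exchangeable", {
  nh <- default_natural_history()
  rejections <- 0L
  set.seed(51)
  for (r in 1:20) {
    a <- sum(!is.na(sample_onset(nh, "squamous", risk_factor = 1, n = 3000)))
    b <- sum(!is.na(sample_onset(nh, "squamous", risk_factor = 1, n = 3000)))
    p <- prop.test(c(a, b), c(3000, 3000))$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("parameter containers reject invalid values", {
  nh <- default_natural_history()
  bad <- nh$onset
  bad$weibull_shape[2] <- -1
  expect_error(natural_history_params(bad, nh$progression, nh$mix), "positive")
  bad2 <- nh$progression
  bad2$indolent_fraction[1] <- 1.2
  expect_error(natural_history_params(nh$onset, bad2, nh$mix), "indolent_fraction")
  expect_error(natural_history_params(nh$onset, nh$progression,
                                      c(squamous = 0.5, adeno_large = 0.4,
                                        small = 0.2)), "sum to 1")
  expect_error(life_table(c(40, 42), c(0.1, 0.1)), "contiguous")
  expect_error(life_table(40:41, c(0.1, 1.4)), "\\[0, 1\\]")
})
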