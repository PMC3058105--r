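rand_tables <- function(seed, ncells = 4) {
  set.seed(seed)
  O <- count_table(data.frame(arm = rep(c("intervention", "control"), 2),
                              mode = rep(c("screen_detected",
                                           "clinically_diagnosed"), each = 2),
                              count = rpois(4, 20)))
  E <- O
  E$count <- O$count * exp(rnorm(4, 0, 0.2)) + 0.5
  list(O = O, E = E)
}

test_that("the Poisson log-likelihood matches its closed form", {
  # single informative cell: O = 0, E = 2 gives loglik -2
  O <- count_table(data.frame(arm = "intervention", mode = "screen_detected",
                              count = 0))
  E <- O
  E$count[1] <- 2
  expect_equal(poisson_loglik(O, E), -2)

  # saturated maximality and the deviance/log-likelihood identity
  for (s in 1:20) {
    t <- rand_tables(s)
    ll <- poisson_loglik(t$O, t$E)
    ll_sat <- poisson_loglik(t$O, t$O)
    expect_lte(ll, ll_sat)
    expect_equal(count_deviance(t$O, t$E), 2 * (ll_sat - ll), tolerance = 1e-12)
  }

  # zero expected with positive observed: -Inf with a warning, not an error
  Z <- count_table(data.frame(arm = "intervention", mode = "screen_detected",
                              count = 3))
  EZ <- Z
  EZ$count[1] <- 0
  expect_warning(llz <- poisson_loglik(Z, EZ), "-Inf")
  expect_identical(llz, -Inf)
  expect_warning(dz <- count_deviance(Z, EZ), "Inf")
  expect_identical(dz, Inf)
})

test_that("the deviance agrees with the direct formula and is zero when saturated", {
  O <- count_table(data.frame(arm = c("intervention", "intervention"),
                              mode = c("screen_detected", "clinically_diagnosed"),
                              count = c(10, 20)))
  E <- O
  E$count[E$count == 10] <- 12
  E$count[E$count == 20] <- 18
  # frozen from the direct formula 2*(10*log(10/12) + 20*log(20/18))
  expect_equal(count_deviance(O, E), 0.5679895, tolerance = 1e-6)

  for (s in 21:40) {
    t <- rand_tables(s)
    expect_identical(count_deviance(t$O, t$O), 0)
    expect_gte(count_deviance(t$O, t$E), 0)
  }

  mism <- aggregate_counts(rand_tables(1)$O, "marginal")
  expect_error(count_deviance(rand_tables(1)$O$count, mism), "count_table")
})

test_that("the multinomial family scores allocation only", {
  t <- rand_tables(5)
  # scaling every expected cell by a constant changes the Poisson deviance
  # but not the per-arm multinomial one
  E2 <- t$E
  E2$count <- E2$count * 3
  expect_equal(count_deviance(t$O, E2, family = "multinomial"),
               count_deviance(t$O, t$E, family = "multinomial"))
  expect_false(isTRUE(all.equal(count_deviance(t$O, E2), count_deviance(t$O, t$E))))
  expect_identical(count_deviance(t$O, t$O, family = "multinomial"), 0)
  expect_gte(count_deviance(t$O, t$E, family = "multinomial"), 0)
})

test_that("chi-squared tail probabilities are exact and monotone", {
  expect_equal(chi2_pvalue(0, 3), 1)
  expect_error(chi2_pvalue(-1, 1), "nonnegative")
  expect_error(chi2_pvalue(2, 0.5), "positive integer")
  # numerical-integration oracle of the chi-squared density
  for (df in c(1, 2, 4)) for (d in c(0.07, 1.27, 2.14, 5.04)) {
    ref <- integrate(dchisq, lower = d, upper = Inf, df = df,
                     rel.tol = 1e-10)$value
    expect_equal(chi2_pvalue(d, df), ref, tolerance = 1e-6)
  }
  x <- seq(0, 10, by = 0.25)
  expect_true(all(diff(chi2_pvalue(x, 1)) < 0))
})

test_that("the binomial excess test has its exact-tail behavior", {
  # central case: observed equals the expectation, upper tail near one half
  expect_lt(abs(binomial_excess_test(200, 200, 10000) - 0.5), 0.05)
  # extreme case: all persons diagnosed has closed-form tail (E/n)^n
  expect_equal(binomial_excess_test(5, 2.5, 5), 0.5^5)
  expect_error(binomial_excess_test(10, 20, 15), "below n_at_risk")
  expect_error(binomial_excess_test(-1, 2, 10), "integer")
  # an excess of the fixture's size over its expectation is improbable
  p <- binomial_excess_test(206, 170, 4618)
  expect_lt(p, 0.05)
})

test_that("the Simple model is a single objective evaluation", {
  obs <- generate_trial_counts(truth_spec(config = small_config()), seed = 91)
  fit <- fit_model(model_spec("Simple"), obs, small_config(),
                   oversample = 2, seed = 92)
  expect_identical(fit$n_evals, 1L)
  expect_length(fit$fitted_values, 0)
  expect_equal(fit$deviance, count_deviance(obs, fit$expected))
  expect_gte(fit$deviance, 0)
})

test_that("model specifications free exactly the hypothesis parameters", {
  expect_length(model_spec("Simple")$free, 0)
  expect_setequal(model_spec("Sensitivity")$free, c("sens_II", "sens_III"))
  expect_setequal(model_spec("SystematicError")$free, c("syserr_II", "syserr_III"))
  expect_setequal(model_spec("SensitivityError")$free,
                  c("sens_II", "sens_III", "syserr_II", "syserr_III"))
  expect_identical(model_spec("Overdiagnosis")$free, "indolent_fraction")
  expect_identical(model_spec("riskdiff")$name, "RiskDifference")
  expect_error(model_spec("nonsense"))
})

test_that("nested fits cannot do worse than the models they extend", {
  obs <- generate_trial_counts(truth_spec(config = small_config()), seed = 93)
  cfg <- small_config()
  f_simple <- fit_model(model_spec("Simple"), obs, cfg, oversample = 3, seed = 94)
  f_sys <- fit_model(model_spec("SystematicError"), obs, cfg, oversample = 3, seed = 94)
  f_both <- fit_model(model_spec("SensitivityError"), obs, cfg, oversample = 3, seed = 94)
  expect_lte(f_sys$deviance, f_simple$deviance + 1e-9)
  expect_lte(f_both$deviance, f_sys$deviance + 0.5)
})

test_that("a single-replicate risk-difference fit lands near the truth", {
  truth <- truth_spec(config = trial_config(n_intervention = 3000, n_control = 3000,
                                            risk_factor_intervention = 1.4))
  obs <- generate_trial_counts(truth, seed = 95)
  fit <- fit_model(model_spec("RiskDifference"), obs,
                   trial_config(n_intervention = 3000, n_control = 3000),
                   oversample = 4, seed = 96)
  expect_lt(abs(fit$fitted_values[["risk_factor"]] - 1.4), 0.35)
})
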