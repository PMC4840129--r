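test_that("response probabilities carry Wald standard errors", {
  est <- estimate_response_probability(22, 45)
  expect_equal(est$mean, 22 / 45)
  expect_equal(est$se, sqrt((22 / 45) * (23 / 45) / 45))
  expect_equal(est$family, "beta")
  # published values (truncated at the third decimal)
  expect_lt(abs(est$mean - 0.489), 1e-3)
  expect_lt(abs(est$se - 0.074), 1e-3)

  est2 <- estimate_response_probability(4, 48)
  expect_lt(abs(est2$mean - 0.083), 1e-3)
  expect_lt(abs(est2$se - 0.039), 1e-3)

  est3 <- estimate_response_probability(0, 10)
  expect_equal(est3$mean, 0)
  expect_equal(est3$se, 0)
  expect_equal(est3$family, "fixed")

  expect_error(estimate_response_probability(3, 0), "integer >= 1")
  expect_error(estimate_response_probability(5, 4), "exceed n")
})

test_that("resource-use standard errors follow sd / sqrt(n)", {
  # the six arm-level medication summaries
  cases <- list(
    list(mean = 1.6, sd = 5.5, n = 45, se2 = 0.82),
    list(mean = 2.8, sd = 4.0, n = 45, se2 = 0.60),
    list(mean = 6.5, sd = 11.1, n = 45, se2 = 1.65),
    list(mean = 1.3, sd = 3.6, n = 48, se2 = 0.52),
    list(mean = 7.5, sd = 9.6, n = 48, se2 = 1.39),
    list(mean = 10.8, sd = 15.3, n = 48, se2 = 2.21)
  )
  for (cs in cases) {
    est <- estimate_resource_use(cs$mean, cs$sd, cs$n)
    expect_equal(est$mean, cs$mean)
    expect_equal(est$se, cs$sd / sqrt(cs$n))
    expect_equal(round(est$se, 2), cs$se2)
    expect_equal(est$family, "gamma")
  }
  expect_equal(estimate_resource_use(3, 0, 48)$se, 0)
  expect_equal(estimate_resource_use(3, 0, 48)$family, "fixed")
})

test_that("state utilities are linear combinations of the coefficients", {
  u <- utilities_from_regression(c(0.523, 0.2366, 0.01246))
  expect_equal(unname(u), c(0.523, 0.7596, 0.53546, 0.77206), tolerance = 1e-12)
  expect_equal(names(u), c("soc_nonresponder", "soc_responder",
                           "nvns_nonresponder", "nvns_responder"))
  expect_equal(unname(utilities_from_regression(c(0.5, 0, 0))), rep(0.5, 4))
  expect_equal(unname(utilities_from_regression(c(0.6, 0.2, 0.1))),
               c(0.6, 0.8, 0.7, 0.9))
  # out-of-range predictions are clamped to the tariff range
  expect_equal(unname(utilities_from_regression(c(0.9, 0.3, 0))),
               c(0.9, 1, 0.9, 1))
})

test_that("exponential loss is the inverse of exponential decay", {
  expect_equal(fit_exponential_loss(0.69, 1), 0.31)
  expect_equal(fit_exponential_loss(1, 1), 0)
  expect_equal(fit_exponential_loss(0.25, 2), 0.5)
  expect_error(fit_exponential_loss(0, 1), "infinite hazard")
  expect_error(fit_exponential_loss(0.5, 0), "positive")
  for (r in c(0.9, 0.5, 0.1)) {
    for (dt in c(0.5, 1, 3)) {
      loss <- fit_exponential_loss(r, dt)
      expect_equal((1 - loss)^dt, r, tolerance = 1e-12)
    }
  }
})

test_that("noise-free data recovers the regression coefficients exactly", {
  trial <- generate_trial(synth_config(eq5d_noise_sd = 0, seed = 4))
  reg <- fit_utility_regression(trial)
  expect_equal(reg$intercept, 0.523, tolerance = 1e-10)
  expect_equal(reg$coef_response, 0.2366, tolerance = 1e-10)
  expect_equal(reg$coef_device, 0.01246, tolerance = 1e-10)
  expect_true(isSymmetric(reg$coefficient_covariance, tol = 1e-12))
  expect_true(all(eigen(reg$coefficient_covariance)$values > -1e-12))
})

test_that("regression errors name the missing design cell", {
  trial <- generate_trial(synth_config(seed = 4))
  no_resp <- trial
  no_resp$responder_week4 <- FALSE
  no_resp$late_responder <- FALSE
  expect_error(fit_utility_regression(no_resp), "no responders")
  expect_error(fit_utility_regression(trial[1:5, ]), "at least 10")
})

test_that("coefficients are recovered from noisy data", {
  # low noise: no mass at the index bounds, so OLS is unbiased
  cfg <- synth_config(n_active = 10000L, n_control = 10000L,
                      eq5d_noise_sd = 0.05, seed = 21)
  reg <- fit_utility_regression(generate_trial(cfg))
  se <- sqrt(diag(reg$coefficient_covariance))
  expect_lt(abs(reg$intercept - 0.523), 3 * se[1])
  expect_lt(abs(reg$coef_response - 0.2366), 3 * se[2])
  expect_lt(abs(reg$coef_device - 0.01246), 3 * se[3])

  # default noise: clamping at 1 censors part of the responder distribution;
  # compare against the closed-form censored-normal projection instead
  cfg <- synth_config(n_active = 10000L, n_control = 10000L,
                      eq5d_noise_sd = 0.2, seed = 22)
  trial <- generate_trial(cfg)
  reg <- fit_utility_regression(trial)
  responder <- trial$responder_week4 | trial$late_responder
  device <- trial$arm == "active"
  counts <- as.numeric(table(factor(paste0(responder, device),
                                    levels = c("FALSEFALSE", "TRUEFALSE",
                                               "FALSETRUE", "TRUETRUE"))))
  expected <- expected_clamped_coefs(c(0.523, 0.2366, 0.01246), 0.2, counts)
  se <- sqrt(diag(reg$coefficient_covariance))
  fitted <- c(reg$intercept, reg$coef_response, reg$coef_device)
  expect_true(all(abs(fitted - expected) < 3 * se))
})

test_that("the full parameter table is recovered from large trials", {
  cfg <- synth_config(n_active = 20000L, n_control = 20000L, seed = 31)
  trial <- generate_trial(cfg)
  params <- estimate_parameters(trial)
  expect_setequal(
    params$name,
    c("p_response_nvns", "p_response_soc", "p_discontinue",
      "zolmitriptan_nvns", "zolmitriptan_soc", "sumatriptan_nvns",
      "sumatriptan_soc", "oxygen_nvns", "oxygen_soc",
      "utility_intercept", "utility_response", "utility_device"))
  g <- function(n) params$mean[params$name == n]
  expect_lt(abs(g("p_response_nvns") - 22 / 45), 0.01)
  expect_lt(abs(g("p_response_soc") - 4 / 48), 0.01)
  expect_lt(abs(g("p_discontinue") - 0.31), 0.02)
  expect_equal(params$se[params$name == "p_discontinue"], 0.378)
  expect_lt(abs(g("oxygen_soc") - 10.8), 0.3)
  expect_equal(params$family[params$name == "sumatriptan_nvns"], "gamma")
  expect_s3_class(attr(params, "regression"), "utility_regression")
})

test_that("parameter tables round-trip through CSV", {
  trial <- generate_trial(synth_config(seed = 6))
  params <- estimate_parameters(trial)
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_table(params, path)
  back <- read_parameter_table(path)
  expect_equal(back$name, params$name)
  expect_equal(back$mean, params$mean, tolerance = 1e-12)
  expect_equal(back$family, params$family)
})
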