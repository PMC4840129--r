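test_that("per-dose costs reproduce the tariff arithmetic", {
  expect_equal(per_dose_cost(86.22, 6), 14.07)
  expect_equal(per_dose_cost(64.40, 2), 31.31)
  expect_equal(per_dose_cost(10.00, 1, 0), 10.00)
  expect_error(per_dose_cost(86.22, 0), "integer >= 1")
  expect_error(per_dose_cost(1.00, 2, 1.77), "exceed the discount")
  uc <- unit_costs()
  expect_equal(uc$zolmitriptan, 14.07)
  expect_equal(uc$sumatriptan, 31.31)
  expect_equal(uc$oxygen, 2.87)
  expect_equal(uc$nvns_stimulation, 0.87)
})

test_that("trajectories conserve occupancy and decline after the late step", {
  params <- default_parameters()
  for (kind in c("maintained", "constant_loss", "diminishing_loss",
                 "no_soc_response")) {
    for (arm in c("active", "control")) {
      traj <- build_trajectory(params, scenario_spec(kind), arm)
      expect_equal(nrow(traj), 13L)
      expect_equal(traj$responder + traj$non_responder, rep(1, 13),
                   tolerance = 1e-12)
      expect_true(all(traj$responder >= 0 & traj$responder <= 1))
      # responder fraction never increases once late responders have joined
      expect_true(all(diff(traj$responder[-1]) <= 1e-12))
    }
  }
})

test_that("arm- and scenario-specific trajectory rules hold", {
  params <- default_parameters()
  ctl <- build_trajectory(params, scenario_spec("maintained"), "control")
  expect_equal(ctl$responder, c(0.083, rep(0, 12)))
  expect_equal(ctl$on_device, rep(0, 13))
  ctl0 <- build_trajectory(params, scenario_spec("no_soc_response"), "control")
  expect_equal(ctl0$responder, rep(0, 13))

  act <- build_trajectory(params, scenario_spec("maintained"), "active")
  expect_equal(act$responder[1], 18 / 45)
  expect_equal(act$responder[2:13], rep(0.489 * (1 - 0.31), 12))
  expect_equal(act$on_device, c(1, act$responder[2:13]))

  cl <- build_trajectory(params, scenario_spec("constant_loss"), "active")
  expect_equal(cl$responder[2:13], 0.489 * (1 - 0.31)^(1:12))

  # a loss scenario with zero loss is the maintained base case
  p0 <- default_parameters(p_discontinue = 0)
  expect_equal(build_trajectory(p0, scenario_spec("constant_loss"), "active"),
               build_trajectory(p0, scenario_spec("maintained"), "active"))
  # zero hazard reduction collapses diminishing to constant loss
  pr0 <- default_parameters(diminishing_reduction = 0)
  expect_equal(
    build_trajectory(pr0, scenario_spec("diminishing_loss"), "active"),
    build_trajectory(pr0, scenario_spec("constant_loss"), "active"))

  # excluding late responders removes the cycle-2 step up
  s <- scenario_spec("maintained", include_late_responders = FALSE)
  act_sens <- build_trajectory(params, s, "active")
  expect_equal(act_sens$responder[2], (18 / 45) * (1 - 0.31))

  expect_error(build_trajectory(params, scenario_spec("maintained"), "placebo"),
               "unknown arm")
  expect_error(scenario_spec("linear_loss"))
})

test_that("QALY accumulation matches closed-form values", {
  params <- default_parameters()
  traj <- build_trajectory(params, scenario_spec("maintained"), "control")
  ones <- c(soc_nonresponder = 1, soc_responder = 1,
            nvns_nonresponder = 1, nvns_responder = 1)
  expect_equal(accumulate_qalys(traj, ones, 28, "control"), 364 / 365.25)

  u <- state_utilities(params)
  q_ctl <- accumulate_qalys(traj, u, 28, "control")
  hand <- ((0.083 * 0.7596 + 0.917 * 0.523) + 12 * 0.523) * 28 / 365.25
  expect_equal(q_ctl, hand, tolerance = 1e-12)
  expect_equal(round(q_ctl, 3), 0.523)

  traj0 <- build_trajectory(default_parameters(p_response_control = 0),
                            scenario_spec("maintained"), "control")
  expect_equal(accumulate_qalys(traj0, u, 28, "control"),
               0.523 * 364 / 365.25)
})

test_that("cost accumulation matches hand-computed components", {
  # a single 28-day cycle in the pure non-responder state
  params <- default_parameters(n_cycles = 1L, p_response_control = 0)
  traj <- build_trajectory(params, scenario_spec("maintained"), "control")
  comp <- accumulate_costs(traj, params, "control")
  expect_equal(comp[["sumatriptan"]], 7.5 * 2 * 31.31)
  expect_equal(comp[["zolmitriptan"]], 1.3 * 2 * 14.07)
  expect_equal(comp[["oxygen"]], 10.8 * 2 * 2.87)
  expect_equal(comp[["device"]], 0)

  # all resource means and stimulation use zero
  ru <- default_parameters()$resource_use
  ru$nvns_mean <- ru$soc_mean <- 0
  pz <- default_parameters(resource_use = ru, stimulations_per_day = 0)
  tz <- build_trajectory(pz, scenario_spec("maintained"), "active")
  expect_equal(unname(accumulate_costs(tz, pz, "active")), rep(0, 4))

  # 1-year control-arm total
  params <- default_parameters()
  traj <- build_trajectory(params, scenario_spec("maintained"), "control")
  total <- sum(accumulate_costs(traj, params, "control"))
  expect_lt(abs(total / 7511.35 - 1), 0.03)
})

test_that("total cost equals the sum of its components to the cent", {
  params <- default_parameters()
  for (kind in c("maintained", "constant_loss")) {
    res <- run_deterministic(params, scenario_spec(kind))
    for (arm in c("active", "control")) {
      expect_equal(res[[arm]]$cost_total, sum(res[[arm]]$cost_components),
                   tolerance = 0.01)
    }
  }
})

test_that("device usage calibration solves the linear cost equation", {
  params <- default_parameters()
  p0 <- params
  p0$stimulations_per_day <- 0
  abortive <- sum(accumulate_costs(
    build_trajectory(p0, scenario_spec("maintained"), "active"), p0, "active"))
  expect_equal(calibrate_device_usage(params, abortive), 0)
  expect_error(calibrate_device_usage(params, abortive - 1), "infeasible")

  s1 <- calibrate_device_usage(params, 7096.69)
  expect_equal(s1, 10.3888, tolerance = 1e-4)
  # the shipped default is this calibrated value
  expect_equal(params$stimulations_per_day, s1, tolerance = 1e-3)
  # doubling the per-stimulation price halves the calibrated usage
  p2 <- default_parameters(costs = unit_costs(nvns_stimulation = 2 * 0.87))
  expect_equal(calibrate_device_usage(p2, 7096.69), s1 / 2, tolerance = 1e-10)
})

test_that("the deterministic base case reproduces the headline results", {
  res <- run_deterministic(default_parameters(), scenario_spec("maintained"))
  expect_lt(abs(res$active$cost_total - 7096.69), 1)
  expect_lt(abs(res$active$qaly - 0.607), 0.02)
  expect_lt(abs(res$control$qaly - 0.522), 0.02)
  expect_equal(res$icer$label, "dominant")
  # response loss strictly reduces active-arm QALYs
  res_cl <- run_deterministic(default_parameters(), scenario_spec("constant_loss"))
  expect_lt(res_cl$active$qaly, res$active$qaly)
})

test_that("identical arms yield zero increments and an equivalent label", {
  ru <- default_parameters()$resource_use
  ru$nvns_mean <- ru$soc_mean
  params <- default_parameters(
    resource_use = ru, stimulations_per_day = 0,
    utility_coefficients = c(intercept = 0.6, response = 0, device = 0))
  res <- run_deterministic(params, scenario_spec("maintained"))
  expect_equal(res$incremental$cost, 0)
  expect_equal(res$incremental$qaly, 0)
  expect_equal(res$icer$label, "equivalent")
})

test_that("scenario ordering holds for QALYs and device cost", {
  params <- default_parameters()
  kinds <- c("maintained", "diminishing_loss", "constant_loss")
  runs <- lapply(kinds, function(k) run_deterministic(params, scenario_spec(k)))
  qalys <- vapply(runs, function(r) r$active$qaly, numeric(1))
  dev <- vapply(runs, function(r) r$active$cost_components[["device"]], numeric(1))
  expect_true(all(diff(qalys) <= 1e-12))
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("ICER classification covers all quadrants", {
  expect_equal(icer(7096.69, 0.607, 7511.35, 0.522)$label, "dominant")
  expect_equal(icer(1000, 1, 0, 0), list(label = "icer", value = 1000))
  expect_equal(icer(0, 0, 0, 0)$label, "equivalent")
  expect_equal(icer(10, -0.1, 0, 0)$label, "dominated")
})

test_that("QALYs stay within the horizon bound for unit-interval utilities", {
  params <- default_parameters()
  u <- state_utilities(params)
  for (kind in c("maintained", "constant_loss", "diminishing_loss")) {
    for (arm in c("active", "control")) {
      traj <- build_trajectory(params, scenario_spec(kind), arm)
      q <- accumulate_qalys(traj, u, params$cycle_days, arm)
      expect_gte(q, 0)
      expect_lte(q, 364 / 365.25)
    }
  }
})

test_that("the cohort engine agrees with a patient-level microsimulation", {
  params <- default_parameters()
  for (kind in c("maintained", "constant_loss")) {
    for (arm in c("active", "control")) {
      res <- run_deterministic(params, scenario_spec(kind))
      mic <- oracle_microsim(params, kind, arm, n_patients = 100000,
                             seed = 101)
      coh <- res[[if (arm == "active") "active" else "control"]]
      expect_lt(abs(mic$qaly / coh$qaly - 1), 0.005)
      expect_lt(abs(mic$cost / coh$cost_total - 1), 0.005)
    }
  }
})
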