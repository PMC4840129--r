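# Deterministic cohort engine: a 1-year responder-state model run in 13
# cycles of 28 days. Each arm is tracked as occupancy fractions over two
# states (responder / non-responder); QALYs and itemised abortive-medication
# and device costs are accumulated per cycle.

DAYS_PER_YEAR <- 365.25
MEDICATIONS <- c("zolmitriptan", "sumatriptan", "oxygen")

#' Per-dose cost from pack price, pack size and mandatory discount
#'
#' German pharmacy prices: `(pack_price - discount) / doses_per_pack`,
#' rounded to cents with exact half-cents rounded down, as in the published
#' tariff arithmetic (86.22 over 6 doses gives 14.075 -> 14.07). The
#' statutory pharmacy discount is EUR 1.77 per pack.
#'
#' @param pack_price Pack price in euros.
#' @param doses_per_pack Doses per pack (>= 1).
#' @param discount Mandatory per-pack discount in euros (default 1.77).
#' @return Cost per dose in euros, rounded to cents.
#' @examples
#' per_dose_cost(86.22, 6)   # 14.07, intranasal zolmitriptan
#' per_dose_cost(64.40, 2)   # 31.31, subcutaneous sumatriptan
#' @export
per_dose_cost <- function(pack_price, doses_per_pack, discount = 1.77) {
  doses_per_pack <- assert_count(doses_per_pack, "doses_per_pack", min = 1L)
  assert_positive(discount, "discount", strict = FALSE)
  if (pack_price <= discount) {
    stop("pack_price must exceed the discount", call. = FALSE)
  }
  x <- (pack_price - discount) / doses_per_pack
  # round half down at the cent: 14.075 -> 14.07 (matches the listed prices)
  floor(x * 100 + 0.5 - 1e-9) / 100
}

#' Unit costs of abortive treatments and the nVNS device
#'
#' Defaults are the German per-dose prices: intranasal zolmitriptan
#' EUR 14.07 per dose (EUR 86.22 per 6-dose pack less the EUR 1.77
#' discount), subcutaneous sumatriptan EUR 31.31 per dose (EUR 64.40 per
#' 2-dose pack less the discount), inhaled oxygen EUR 2.87 per attack, and
#' EUR 0.87 per device stimulation.
#'
#' @param zolmitriptan,sumatriptan,oxygen,nvns_stimulation Per-dose /
#'   per-attack / per-stimulation costs in euros.
#' @return An object of class `unit_costs`.
#' @export
unit_costs <- function(zolmitriptan = per_dose_cost(86.22, 6),
                       sumatriptan = per_dose_cost(64.40, 2),
                       oxygen = 2.87,
                       nvns_stimulation = 0.87) {
  vals <- c(zolmitriptan = zolmitriptan, sumatriptan = sumatriptan,
            oxygen = oxygen, nvns_stimulation = nvns_stimulation)
  if (any(vals < 0)) stop("unit costs must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "unit_costs")
}

#' Deterministic model parameter set
#'
#' All inputs of the cohort model. Defaults reproduce the German analysis:
#' week-4 response 18/45 in the active arm, overall (including the 4 late
#' responders) 0.489, control response 0.083, monthly response-discontinuation
#' probability 0.310 (from the exponential fit to month-2 retention), a 10 %
#' monthly reduction of the loss rate in the diminishing-loss scenario,
#' EQ-5D utility coefficients (0.523, 0.2366, 0.01246), arm-level 14-day
#' medication use, German unit costs, and a device usage of 10.389
#' stimulations per day (calibrated once against the base-case total cost;
#' see [calibrate_device_usage()]).
#'
#' @param p_response_initial_active Week-4 response probability, active arm.
#' @param p_response_with_late Overall active-arm response probability
#'   including late responders.
#' @param p_response_control Control-arm response probability.
#' @param p_discontinue Monthly probability of losing response.
#' @param diminishing_reduction Monthly proportional reduction of the loss
#'   rate in the diminishing-loss scenario.
#' @param utility_coefficients Numeric vector
#'   `c(intercept, response, device)` of the EQ-5D linear model.
#' @param resource_use Data frame with columns `medication`, `nvns_mean`,
#'   `nvns_sd`, `soc_mean`, `soc_sd`: 14-day use by arm.
#' @param n_active,n_control Arm sizes behind the resource summaries.
#' @param costs A [unit_costs()] object.
#' @param stimulations_per_day Device stimulations per day while on
#'   treatment.
#' @param cycle_days Cycle length in days (default 28).
#' @param n_cycles Number of cycles (default 13; 13 x 28 = 364 days).
#' @param wtp_threshold Willingness to pay per QALY gained, in euros.
#' @return An object of class `ce_parameters`.
#' @export
default_parameters <- function(p_response_initial_active = 18 / 45,
                               p_response_with_late = 0.489,
                               p_response_control = 0.083,
                               p_discontinue = 0.310,
                               diminishing_reduction = 0.10,
                               utility_coefficients = c(intercept = 0.523,
                                                        response = 0.2366,
                                                        device = 0.01246),
                               resource_use = NULL,
                               n_active = 45L,
                               n_control = 48L,
                               costs = unit_costs(),
                               stimulations_per_day = 10.389,
                               cycle_days = 28L,
                               n_cycles = 13L,
                               wtp_threshold = 20000) {
  if (is.null(resource_use)) {
    tg <- default_med_use_targets()
    resource_use <- data.frame(medication = tg$medication,
                               nvns_mean = tg$active_mean,
                               nvns_sd = tg$active_sd,
                               soc_mean = tg$control_mean,
                               soc_sd = tg$control_sd,
                               stringsAsFactors = FALSE)
  }
  for (nm in c("p_response_initial_active", "p_response_with_late",
               "p_response_control", "p_discontinue", "diminishing_reduction")) {
    assert_prob(get(nm), nm)
  }
  stopifnot(length(utility_coefficients) == 3L)
  u <- utilities_from_regression(unname(utility_coefficients))
  if (any(u < -0.2) || any(u > 1)) {
    stop("state utilities must lie in [-0.2, 1]", call. = FALSE)
  }
  stopifnot(all(c("medication", "nvns_mean", "soc_mean") %in% names(resource_use)),
            all(resource_use$nvns_mean >= 0), all(resource_use$soc_mean >= 0))
  if (!inherits(costs, "unit_costs")) stop("'costs' must be a unit_costs object",
                                           call. = FALSE)
  assert_positive(stimulations_per_day, "stimulations_per_day", strict = FALSE)
  cycle_days <- assert_count(cycle_days, "cycle_days", min = 1L)
  n_cycles <- assert_count(n_cycles, "n_cycles", min = 1L)
  if (cycle_days * n_cycles > 366L) {
    stop("cycle_days * n_cycles must not exceed 366 (1-year horizon)",
         call. = FALSE)
  }
  assert_positive(wtp_threshold, "wtp_threshold", strict = FALSE)
  structure(
    list(p_response_initial_active = p_response_initial_active,
         p_response_with_late = p_response_with_late,
         p_response_control = p_response_control,
         p_discontinue = p_discontinue,
         diminishing_reduction = diminishing_reduction,
         utility_coefficients = utility_coefficients,
         resource_use = resource_use,
         n_active = as.integer(n_active),
         n_control = as.integer(n_control),
         costs = costs,
         stimulations_per_day = stimulations_per_day,
         cycle_days = cycle_days,
         n_cycles = n_cycles,
         wtp_threshold = wtp_threshold),
    class = "ce_parameters"
  )
}

#' State utilities implied by a parameter set
#'
#' @param params A `ce_parameters` object.
#' @return Named utility vector, see [utilities_from_regression()].
#' @export
state_utilities <- function(params) {
  utilities_from_regression(unname(params$utility_coefficients))
}

SCENARIOS <- c("maintained", "constant_loss", "diminishing_loss",
               "no_soc_response")

#' Response-trajectory scenario
#'
#' @param kind One of `"maintained"` (base case: a one-time discontinuation
#'   at the cycle-1/2 boundary, response maintained thereafter),
#'   `"constant_loss"` (constant monthly loss rate), `"diminishing_loss"`
#'   (loss rate shrinking by a fixed proportion each month), or
#'   `"no_soc_response"` (as the base case, but no initial response in the
#'   control arm).
#' @param include_late_responders Include the 4 late responders as
#'   responders (default TRUE; FALSE reproduces the sensitivity analysis,
#'   where the post-cycle-1 response probability falls back to the week-4
#'   value).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = "maintained", include_late_responders = TRUE) {
  kind <- match.arg(kind, SCENARIOS)
  stopifnot(is.logical(include_late_responders),
            length(include_late_responders) == 1L)
  structure(list(kind = kind,
                 include_late_responders = include_late_responders),
            class = "scenario_spec")
}

#' Build the per-cycle state-occupancy trajectory for one arm
#'
#' Control arm: the responder fraction equals the control response
#' probability in cycle 1 and 0 thereafter (responders beyond the randomised
#' phase are modelled as non-responders); under `no_soc_response` it is 0 in
#' every cycle. Active arm: cycle 1 carries the week-4 responder fraction;
#' at cycle 2 late responders join (the fraction steps to the overall
#' response probability) and the discontinuation process applies -- a
#' one-time loss `p_discontinue` in the maintained/no-SoC-response
#' scenarios, or the first step of the recurring loss process in the loss
#' scenarios (constant hazard `p_discontinue`, or a hazard shrinking by
#' `diminishing_reduction` each subsequent month). The on-device fraction is
#' 1 in cycle 1 (all active patients stimulate during the randomised phase)
#' and equals the responder fraction thereafter; non-responders discontinue
#' the device.
#'
#' @param params A `ce_parameters` object.
#' @param scenario A [scenario_spec()].
#' @param arm `"active"` or `"control"`.
#' @return A data frame of class `trajectory` with columns `cycle`,
#'   `responder`, `non_responder`, `on_device` and attribute `arm`.
#' @export
build_trajectory <- function(params, scenario, arm) {
  stopifnot(inherits(params, "ce_parameters"), inherits(scenario, "scenario_spec"))
  if (!arm %in% c("active", "control")) {
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  }
  nc <- params$n_cycles
  if (arm == "control") {
    r1 <- if (scenario$kind == "no_soc_response") 0 else params$p_response_control
    responder <- c(r1, rep(0, nc - 1L))
    on_device <- rep(0, nc)
  } else {
    p_late <- if (scenario$include_late_responders) {
      params$p_response_with_late
    } else {
      params$p_response_initial_active
    }
    p <- params$p_discontinue
    r2 <- p_late * (1 - p)
    tail_r <- switch(
      scenario$kind,
      maintained      = rep(r2, nc - 1L),
      no_soc_response = rep(r2, nc - 1L),
      constant_loss   = r2 * (1 - p)^(0:(nc - 2L)),
      diminishing_loss = {
        r <- numeric(nc - 1L)
        r[1] <- r2
        if (nc > 2L) {
          for (t in 3:nc) {
            h <- p * (1 - params$diminishing_reduction)^(t - 2L)
            r[t - 1L] <- r[t - 2L] * (1 - h)
          }
        }
        r
      }
    )
    responder <- c(params$p_response_initial_active, tail_r)
    on_device <- c(1, tail_r)
  }
  out <- data.frame(cycle = seq_len(nc), responder = responder,
                    non_responder = 1 - responder, on_device = on_device)
  attr(out, "arm") <- arm
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Accumulate QALYs over a trajectory
#'
#' Per cycle, occupancy-weighted state utilities are accrued for
#' `cycle_days / 365.25` years; no half-cycle correction and no discounting
#' are applied over the 1-year horizon.
#'
#' @param traj A `trajectory`.
#' @param utilities Named utility vector from [state_utilities()].
#' @param cycle_days Cycle length in days.
#' @param arm `"active"` or `"control"`.
#' @return QALYs (years).
#' @export
accumulate_qalys <- function(traj, utilities, cycle_days, arm) {
  stopifnot(inherits(traj, "trajectory"))
  if (!arm %in% c("active", "control")) {
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  }
  u_resp <- if (arm == "active") utilities[["nvns_responder"]] else utilities[["soc_responder"]]
  u_non <- if (arm == "active") utilities[["nvns_nonresponder"]] else utilities[["soc_nonresponder"]]
  sum(traj$responder * u_resp + traj$non_responder * u_non) *
    cycle_days / DAYS_PER_YEAR
}

#' Accumulate itemised costs over a trajectory
#'
#' Medication doses per cycle are the state-weighted 14-day means scaled by
#' `cycle_days / 14`: active-arm responders use the nVNS-arm means,
#' non-responders the SoC-arm means, and in cycle 1 all active-arm patients
#' use the nVNS-arm means (the trial-observed arm-level consumption).
#' Control-arm patients always use the SoC-arm means. Device cost accrues as
#' `on_device * stimulations_per_day * cycle_days * cost_per_stimulation`.
#'
#' @param traj A `trajectory`.
#' @param params A `ce_parameters` object.
#' @param arm `"active"` or `"control"`.
#' @return Named numeric vector of cost components in euros:
#'   `zolmitriptan`, `sumatriptan`, `oxygen`, `device`.
#' @export
accumulate_costs <- function(traj, params, arm) {
  stopifnot(inherits(traj, "trajectory"), inherits(params, "ce_parameters"))
  if (!arm %in% c("active", "control")) {
    stop(sprintf("unknown arm '%s'", arm), call. = FALSE)
  }
  scale <- params$cycle_days / 14
  ru <- params$resource_use
  comp <- numeric(length(MEDICATIONS) + 1L)
  names(comp) <- c(MEDICATIONS, "device")
  for (i in seq_along(MEDICATIONS)) {
    med <- MEDICATIONS[i]
    row <- ru[ru$medication == med, ]
    unit <- params$costs[[med]]
    if (arm == "active") {
      mean_by_cycle <- traj$responder * row$nvns_mean +
        traj$non_responder * row$soc_mean
      mean_by_cycle[1] <- row$nvns_mean  # cycle 1: arm-level trial use
    } else {
      mean_by_cycle <- rep(row$soc_mean, nrow(traj))
    }
    comp[i] <- sum(mean_by_cycle * scale * unit)
  }
  comp["device"] <- sum(traj$on_device) * params$stimulations_per_day *
    params$cycle_days * params$costs$nvns_stimulation
  comp
}

arm_outcome <- function(traj, params, arm, utilities) {
  comp <- accumulate_costs(traj, params, arm)
  list(qaly = accumulate_qalys(traj, utilities, params$cycle_days, arm),
       cost_components = comp,
       cost_total = sum(comp))
}

#' Incremental cost-effectiveness ratio or dominance label
#'
#' @param cost1,qaly1 Cost and QALYs of the intervention.
#' @param cost0,qaly0 Cost and QALYs of the comparator.
#' @return A list with `label` (`"dominant"` if the intervention is cheaper
#'   and more effective, `"dominated"` if dearer and less effective,
#'   `"equivalent"` if both increments are zero, `"icer"` otherwise) and
#'   `value` (the ratio, NA unless `label == "icer"`).
#' @examples
#' icer(7096.69, 0.607, 7511.35, 0.522)$label  # "dominant"
#' @export
icer <- function(cost1, qaly1, cost0, qaly0) {
  dc <- cost1 - cost0
  dq <- qaly1 - qaly0
  if (dc < 0 && dq > 0) return(list(label = "dominant", value = NA_real_))
  if (dc > 0 && dq < 0) return(list(label = "dominated", value = NA_real_))
  if (dc == 0 && dq == 0) return(list(label = "equivalent", value = NA_real_))
  list(label = "icer", value = dc / dq)
}

#' Run the deterministic cohort model
#'
#' Builds both arms' trajectories under a scenario, accumulates QALYs and
#' itemised costs, and classifies the incremental result.
#'
#' @param params A `ce_parameters` object.
#' @param scenario A [scenario_spec()].
#' @return An object of class `ce_result`: a list with `active` and
#'   `control` arm outcomes (`qaly`, `cost_components`, `cost_total`),
#'   `incremental` (`cost`, `qaly`), and `icer`.
#' @examples
#' res <- run_deterministic(default_parameters(), scenario_spec("maintained"))
#' round(res$active$cost_total, 2)
#' @export
run_deterministic <- function(params, scenario = scenario_spec("maintained")) {
  u <- state_utilities(params)
  act <- arm_outcome(build_trajectory(params, scenario, "active"),
                     params, "active", u)
  ctl <- arm_outcome(build_trajectory(params, scenario, "control"),
                     params, "control", u)
  structure(
    list(scenario = scenario,
         active = act, control = ctl,
         incremental = list(cost = act$cost_total - ctl$cost_total,
                            qaly = act$qaly - ctl$qaly),
         icer = icer(act$cost_total, act$qaly, ctl$cost_total, ctl$qaly)),
    class = "ce_result"
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("1-year cohort model result (", x$scenario$kind, ")\n", sep = "")
  cat(sprintf("  nVNS + SoC : cost EUR %.2f, QALY %.3f\n",
              x$active$cost_total, x$active$qaly))
  cat(sprintf("  SoC alone  : cost EUR %.2f, QALY %.3f\n",
              x$control$cost_total, x$control$qaly))
  lab <- if (x$icer$label == "icer") {
    sprintf("ICER %.2f EUR/QALY", x$icer$value)
  } else {
    x$icer$label
  }
  cat(sprintf("  incremental: cost EUR %.2f, QALY %.3f (%s)\n",
              x$incremental$cost, x$incremental$qaly, lab))
  invisible(x)
}

#' Calibrate device usage against a target total cost
#'
#' The trial reports the per-stimulation cost but not the stimulation count.
#' Total active-arm cost is linear in the stimulations-per-day rate `s`, so
#' `s` is solved from `device_cost(s) = target - abortive_cost` under the
#' deterministic base-case trajectory. The shipped default (10.389/day) is
#' this back-calculation against the base-case total of EUR 7096.69.
#'
#' @param params A `ce_parameters` object.
#' @param target_total_cost Target 1-year active-arm total cost in euros.
#' @param scenario Scenario under which to calibrate (default base case).
#' @return Stimulations per day.
#' @export
calibrate_device_usage <- function(params, target_total_cost,
                                   scenario = scenario_spec("maintained")) {
  p0 <- params
  p0$stimulations_per_day <- 0
  traj <- build_trajectory(p0, scenario, "active")
  abortive <- sum(accumulate_costs(traj, p0, "active"))
  if (target_total_cost < abortive) {
    stop(sprintf(
      "infeasible target: %.2f is below the abortive-only cost %.2f",
      target_total_cost, abortive), call. = FALSE)
  }
  per_stim_day <- sum(traj$on_device) * params$cycle_days *
    params$costs$nvns_stimulation
  if (per_stim_day == 0) {
    if (target_total_cost == abortive) return(0)
    stop("device cost weight is zero; cannot calibrate", call. = FALSE)
  }
  (target_total_cost - abortive) / per_stim_day
}
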