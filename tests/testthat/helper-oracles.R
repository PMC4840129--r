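# Independent oracles used to cross-check the package's closed-form /
# cohort-level computations. These deliberately re-derive results from first
# principles (individual-level simulation, closed-form censored-normal
# moments, numeric integration) and do not call the code paths they check.

# Patient-level microsimulation of the 1-year model: each simulated patient
# walks through the same transition rules as the cohort (week-4 response,
# late response joining at cycle 2, one-off or recurring response loss),
# accruing per-cycle utilities and costs. Cohort occupancy fractions are the
# expectation of these individual paths, so means over many patients must
# agree with the cohort engine.
oracle_microsim <- function(params, kind, arm, n_patients, seed) {
  set.seed(seed)
  nc <- params$n_cycles
  cf <- unname(params$utility_coefficients)
  u_resp <- if (arm == "active") cf[1] + cf[2] + cf[3] else cf[1] + cf[2]
  u_non <- if (arm == "active") cf[1] + cf[3] else cf[1]

  resp <- matrix(FALSE, n_patients, nc)
  if (arm == "control") {
    r1 <- if (kind == "no_soc_response") 0 else params$p_response_control
    resp[, 1] <- stats::runif(n_patients) < r1
  } else {
    resp[, 1] <- stats::runif(n_patients) < params$p_response_initial_active
    ever <- stats::runif(n_patients) < params$p_response_with_late
    alive <- ever & (stats::runif(n_patients) < 1 - params$p_discontinue)
    resp[, 2] <- alive
    if (nc > 2L) {
      for (t in 3:nc) {
        h <- switch(kind,
                    maintained = 0, no_soc_response = 0,
                    constant_loss = params$p_discontinue,
                    diminishing_loss = params$p_discontinue *
                      (1 - params$diminishing_reduction)^(t - 2L))
        if (h > 0) alive <- alive & (stats::runif(n_patients) < 1 - h)
        resp[, t] <- alive
      }
    }
  }

  qaly <- rowSums(ifelse(resp, u_resp, u_non)) * params$cycle_days / 365.25

  ru <- params$resource_use
  scale <- params$cycle_days / 14
  nvns_cycle <- sum(ru$nvns_mean * unlist(params$costs[ru$medication])) * scale
  soc_cycle <- sum(ru$soc_mean * unlist(params$costs[ru$medication])) * scale
  dev_cycle <- params$stimulations_per_day * params$cycle_days *
    params$costs$nvns_stimulation
  if (arm == "control") {
    cost <- rep(nc * soc_cycle, n_patients)
  } else {
    # cycle 1: arm-level consumption and device use for everyone
    cost <- rep(nvns_cycle + dev_cycle, n_patients)
    for (t in 2:nc) {
      cost <- cost + ifelse(resp[, t], nvns_cycle + dev_cycle, soc_cycle)
    }
  }
  list(qaly = mean(qaly), cost = mean(cost))
}

# Closed-form mean of a normal clamped (censored) to [lo, hi].
censored_normal_mean <- function(mu, sd, lo = -0.2, hi = 1) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b)) +
    lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b))
}

# Expected OLS coefficients when the generated index is clamped: project the
# censored cell means onto the design, weighting by observed cell counts.
expected_clamped_coefs <- function(cf, noise_sd, counts) {
  grid <- expand.grid(responder = c(0, 1), device = c(0, 1))
  mu <- cf[1] + cf[2] * grid$responder + cf[3] * grid$device
  m <- vapply(mu, censored_normal_mean, numeric(1), sd = noise_sd)
  X <- cbind(1, grid$responder, grid$device)
  W <- diag(counts)
  as.numeric(solve(t(X) %*% W %*% X, t(X) %*% W %*% m))
}

# Mean of a normal truncated to [0, 1], by numeric integration.
truncnorm01_mean_numeric <- function(mu, sd) {
  z <- stats::integrate(function(x) stats::dnorm(x, mu, sd), 0, 1)$value
  stats::integrate(function(x) x * stats::dnorm(x, mu, sd), 0, 1)$value / z
}
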