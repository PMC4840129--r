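# Probabilistic sensitivity analysis: each uncertain input is declared as a
# distribution by family and moments, sampled per draw, and pushed through
# the deterministic cohort engine.

#' Beta distribution from mean and standard error
#'
#' Method of moments: `nu = mean * (1 - mean) / se^2 - 1`,
#' `alpha = mean * nu`, `beta = (1 - mean) * nu`. The resulting distribution
#' has exactly the requested mean and standard deviation.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, with `se^2 < mean * (1 - mean)`.
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' beta_from_moments(0.489, 0.074)
#' beta_from_moments(0.5, sqrt(1 / 12))  # alpha = beta = 1, the uniform
#' @export
beta_from_moments <- function(mean, se) {
  assert_prob(mean, "mean", allow_zero = FALSE, allow_one = FALSE)
  assert_positive(se, "se")
  if (se^2 >= mean * (1 - mean)) {
    stop("infeasible moments: se^2 must be < mean * (1 - mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma distribution from mean and standard error
#'
#' Method of moments: `shape = (mean / se)^2`, `scale = se^2 / mean`.
#'
#' @param mean Mean (> 0).
#' @param se Standard error (> 0).
#' @return Named vector `c(shape, scale)`.
#' @examples
#' gamma_from_moments(6.5, 1.65)
#' @export
gamma_from_moments <- function(mean, se) {
  assert_positive(mean, "mean")
  assert_positive(se, "se")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

# Single draws honouring the degenerate se = 0 case (the draw then equals
# the mean, so a zero-uncertainty analysis reproduces the deterministic run
# exactly).
draw_beta <- function(mean, se) {
  if (se == 0) return(mean)
  ab <- beta_from_moments(mean, se)
  stats::rbeta(1, ab[["alpha"]], ab[["beta"]])
}

draw_gamma <- function(mean, se) {
  if (se == 0) return(mean)
  gs <- gamma_from_moments(mean, se)
  stats::rgamma(1, shape = gs[["shape"]], scale = gs[["scale"]])
}

# Normal truncated to [0, 1] by rejection (a proper truncated distribution,
# not clipping; with mean 0.31 and SD 0.378 the truncation shifts the mean
# up to about 0.414).
draw_truncnorm01 <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

draw_mvnorm <- function(mu, sigma) {
  if (all(sigma == 0)) return(mu)
  as.numeric(MASS::mvrnorm(1, mu = mu, Sigma = sigma))
}

#' Distribution specifications for the probabilistic analysis
#'
#' Builds the full set of sampling distributions around a deterministic
#' parameter set: beta for the three response probabilities (standard errors
#' from the binomial Wald formula for the week-4 probabilities, 0.074 and
#' 0.039 for the overall ones), a normal truncated to \[0, 1\] for the
#' discontinuation probability (SE 0.378), gamma for the six per-arm
#' medication-use means (SE = SD / sqrt(n)), and a multivariate normal over
#' the three EQ-5D regression coefficients. Unit costs, device usage and the
#' cycle structure are fixed.
#'
#' When `include_late_responders = FALSE` the analysis uses a single
#' response-probability draw (mean 18/45) for both cycle 1 and the
#' post-cycle-1 fraction, reproducing the published sensitivity analysis.
#'
#' @param params A `ce_parameters` object (defaults to
#'   [default_parameters()]).
#' @param response_se_with_late,response_se_control Standard errors of the
#'   overall active-arm and the control-arm response probabilities
#'   (defaults 0.074, 0.039).
#' @param discontinuation_se Standard error of the discontinuation
#'   probability (default 0.378).
#' @param coef_covariance 3x3 covariance of the utility coefficients; the
#'   default is diagonal with SD 0.02 per coefficient, the fallback used
#'   when only printed summaries (not patient-level data) are available.
#'   Supply the `coefficient_covariance` of a fitted
#'   [fit_utility_regression()] to propagate the estimated covariance.
#' @param include_late_responders See above.
#' @param zero_uncertainty If TRUE all SEs are set to 0 (degenerate
#'   distributions; every draw equals the deterministic parameter set).
#' @return An object of class `psa_specs`.
#' @export
default_psa_specs <- function(params = default_parameters(),
                              response_se_with_late = 0.074,
                              response_se_control = 0.039,
                              discontinuation_se = 0.378,
                              coef_covariance = diag(0.02^2, 3),
                              include_late_responders = TRUE,
                              zero_uncertainty = FALSE) {
  stopifnot(inherits(params, "ce_parameters"))
  p0 <- params$p_response_initial_active
  se_init <- sqrt(p0 * (1 - p0) / params$n_active)
  coef_covariance <- as.matrix(coef_covariance)
  stopifnot(identical(dim(coef_covariance), c(3L, 3L)),
            isSymmetric(coef_covariance, tol = 1e-10))
  specs <- structure(
    list(base = params,
         response_initial = list(mean = p0, se = se_init),
         response_with_late = list(mean = params$p_response_with_late,
                                   se = response_se_with_late),
         response_control = list(mean = params$p_response_control,
                                 se = response_se_control),
         discontinuation = list(mean = params$p_discontinue,
                                se = discontinuation_se),
         resource_se = resource_standard_errors(params),
         coef_mean = unname(params$utility_coefficients),
         coef_covariance = coef_covariance,
         include_late_responders = isTRUE(include_late_responders)),
    class = "psa_specs"
  )
  if (zero_uncertainty) {
    specs$response_initial$se <- 0
    specs$response_with_late$se <- 0
    specs$response_control$se <- 0
    specs$discontinuation$se <- 0
    specs$resource_se$nvns_se <- rep(0, nrow(specs$resource_se))
    specs$resource_se$soc_se <- rep(0, nrow(specs$resource_se))
    specs$coef_covariance <- matrix(0, 3, 3)
  }
  specs
}

# SE = SD / sqrt(n) per medication and arm, from the arm-level summaries
# carried in the parameter set.
resource_standard_errors <- function(params) {
  ru <- params$resource_use
  data.frame(
    medication = ru$medication,
    nvns_se = if ("nvns_sd" %in% names(ru)) ru$nvns_sd / sqrt(params$n_active) else 0,
    soc_se = if ("soc_sd" %in% names(ru)) ru$soc_sd / sqrt(params$n_control) else 0,
    stringsAsFactors = FALSE
  )
}

#' Sample one parameter set from the declared distributions
#'
#' Reproducible given `(seed, draw_index)`: the RNG is seeded with
#' `seed + draw_index` before sampling, so draw `i` of a run can be
#' regenerated in isolation.
#'
#' @param specs A [default_psa_specs()] object.
#' @param seed Base seed (NULL to sample from the current RNG state).
#' @param draw_index Index of the draw.
#' @return A `ce_parameters` object.
#' @export
sample_parameters <- function(specs, seed = NULL, draw_index = 1L) {
  stopifnot(inherits(specs, "psa_specs"))
  if (!is.null(seed)) set.seed(as.integer(seed) + as.integer(draw_index))
  p <- specs$base
  if (specs$include_late_responders) {
    p$p_response_initial_active <- draw_beta(specs$response_initial$mean,
                                             specs$response_initial$se)
    p$p_response_with_late <- draw_beta(specs$response_with_late$mean,
                                        specs$response_with_late$se)
  } else {
    shared <- draw_beta(specs$response_initial$mean, specs$response_initial$se)
    p$p_response_initial_active <- shared
    p$p_response_with_late <- shared
  }
  p$p_response_control <- draw_beta(specs$response_control$mean,
                                    specs$response_control$se)
  p$p_discontinue <- draw_truncnorm01(specs$discontinuation$mean,
                                      specs$discontinuation$se)
  se <- specs$resource_se
  for (i in seq_len(nrow(se))) {
    j <- which(p$resource_use$medication == se$medication[i])
    p$resource_use$nvns_mean[j] <- draw_gamma(specs$base$resource_use$nvns_mean[j],
                                              se$nvns_se[i])
    p$resource_use$soc_mean[j] <- draw_gamma(specs$base$resource_use$soc_mean[j],
                                             se$soc_se[i])
  }
  cf <- draw_mvnorm(specs$coef_mean, specs$coef_covariance)
  p$utility_coefficients <- c(intercept = cf[1], response = cf[2], device = cf[3])
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n_sims` parameter sets, runs the deterministic cohort model for
#' each, and summarises cost-effectiveness uncertainty: mean costs and QALYs
#' per arm (the probabilistic estimates reported by the analysis), mean
#' increments, the dominance/ICER classification of the means, the fraction
#' of draws that are cost saving, and the fraction cost-effective at the
#' willingness-to-pay threshold.
#'
#' @param specs A [default_psa_specs()] object.
#' @param scenario A [scenario_spec()]; its `include_late_responders` flag
#'   is synchronised into the sampling.
#' @param n_sims Number of draws (default 1000).
#' @param seed Base seed.
#' @return An object of class `psa_result` with elements `draws` (one row
#'   per simulation), `summary`, `mean_components` (mean cost components per
#'   arm), `n_sims`, `seed`, `scenario`, `wtp_threshold`.
#' @export
run_psa <- function(specs, scenario = scenario_spec("maintained"),
                    n_sims = 1000L, seed = 1L) {
  stopifnot(inherits(specs, "psa_specs"))
  n_sims <- assert_count(n_sims, "n_sims", min = 1L)
  if (!identical(specs$include_late_responders,
                 scenario$include_late_responders)) {
    specs$include_late_responders <- scenario$include_late_responders
    if (!scenario$include_late_responders && specs$response_initial$se > 0) {
      # late responders excluded: single response probability at the week-4
      # mean with its Wald SE (unless uncertainty is switched off)
      p0 <- specs$base$p_response_initial_active
      specs$response_initial <- list(mean = p0,
                                     se = sqrt(p0 * (1 - p0) / specs$base$n_active))
    }
  }
  cols <- c("cost_active", "cost_control", "qaly_active", "qaly_control")
  draws <- matrix(NA_real_, n_sims, length(cols),
                  dimnames = list(NULL, cols))
  comp_active <- comp_control <- NULL
  for (i in seq_len(n_sims)) {
    res <- tryCatch(
      run_deterministic(sample_parameters(specs, seed, i), scenario),
      error = function(e) stop(sprintf("draw %d failed: %s", i,
                                       conditionMessage(e)), call. = FALSE)
    )
    draws[i, ] <- c(res$active$cost_total, res$control$cost_total,
                    res$active$qaly, res$control$qaly)
    if (is.null(comp_active)) {
      comp_active <- res$active$cost_components
      comp_control <- res$control$cost_components
    } else {
      comp_active <- comp_active + res$active$cost_components
      comp_control <- comp_control + res$control$cost_components
    }
  }
  draws <- as.data.frame(draws)
  draws$draw <- seq_len(n_sims)
  draws$inc_cost <- draws$cost_active - draws$cost_control
  draws$inc_qaly <- draws$qaly_active - draws$qaly_control
  wtp <- specs$base$wtp_threshold
  means <- colMeans(draws[cols])
  summ <- list(
    mean_cost_active = means[["cost_active"]],
    mean_cost_control = means[["cost_control"]],
    mean_qaly_active = means[["qaly_active"]],
    mean_qaly_control = means[["qaly_control"]],
    mean_inc_cost = mean(draws$inc_cost),
    mean_inc_qaly = mean(draws$inc_qaly),
    icer = icer(means[["cost_active"]], means[["qaly_active"]],
                means[["cost_control"]], means[["qaly_control"]]),
    fraction_cost_saving = mean(draws$inc_cost < 0),
    fraction_cost_effective = mean(wtp * draws$inc_qaly - draws$inc_cost > 0)
  )
  structure(
    list(draws = draws, summary = summ,
         mean_components = list(active = comp_active / n_sims,
                                control = comp_control / n_sims),
         n_sims = n_sims, seed = seed, scenario = scenario,
         wtp_threshold = wtp),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA (%s, %d simulations, seed %s)\n",
              x$scenario$kind, x$n_sims, format(x$seed)))
  cat(sprintf("  nVNS + SoC : mean cost EUR %.2f, mean QALY %.3f\n",
              s$mean_cost_active, s$mean_qaly_active))
  cat(sprintf("  SoC alone  : mean cost EUR %.2f, mean QALY %.3f\n",
              s$mean_cost_control, s$mean_qaly_control))
  lab <- if (s$icer$label == "icer") sprintf("ICER %.2f EUR/QALY", s$icer$value)
         else s$icer$label
  cat(sprintf("  %s; %.1f%% of draws cost saving; %.1f%% cost-effective at EUR %s/QALY\n",
              lab, 100 * s$fraction_cost_saving,
              100 * s$fraction_cost_effective,
              format(x$wtp_threshold, big.mark = ",")))
  invisible(x)
}

#' Export the cost-effectiveness plane
#'
#' One row per draw with the incremental QALY / incremental cost pair and
#' its quadrant; the willingness-to-pay line is attached as attributes
#' `wtp_threshold` (slope, EUR/QALY) and `wtp_intercept` (0).
#'
#' @param result A `psa_result`.
#' @return Data frame with columns `draw`, `inc_qaly`, `inc_cost`,
#'   `quadrant`, `cost_effective`.
#' @export
ce_plane_export <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  d <- result$draws
  quadrant <- ifelse(d$inc_qaly >= 0 & d$inc_cost <= 0, "south-east (dominant)",
              ifelse(d$inc_qaly >= 0 & d$inc_cost > 0, "north-east",
              ifelse(d$inc_cost > 0, "north-west (dominated)", "south-west")))
  out <- data.frame(draw = d$draw, inc_qaly = d$inc_qaly, inc_cost = d$inc_cost,
                    quadrant = quadrant,
                    cost_effective = result$wtp_threshold * d$inc_qaly - d$inc_cost > 0,
                    stringsAsFactors = FALSE)
  attr(out, "wtp_threshold") <- result$wtp_threshold
  attr(out, "wtp_intercept") <- 0
  out
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective (positive net
#' monetary benefit) as a function of the willingness-to-pay threshold.
#'
#' @param result A `psa_result`.
#' @param wtp_grid Thresholds in EUR/QALY.
#' @return Data frame with columns `wtp`, `probability_cost_effective`.
#' @export
ceac <- function(result, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(result, "psa_result"))
  d <- result$draws
  prob <- vapply(wtp_grid,
                 function(w) mean(w * d$inc_qaly - d$inc_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}
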