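# Parameter estimation: every probabilistic-analysis input (point estimate,
# standard error, sampling family) derived from trial data or from the
# published arm-level summaries.

new_estimated_parameter <- function(name, mean, se, family) {
  family <- match.arg(family,
                      c("beta", "gamma", "normal_truncated01", "mv_normal", "fixed"))
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  if (family == "beta" && se > 0 && (mean <= 0 || mean >= 1)) {
    stop("beta family requires mean in (0, 1)", call. = FALSE)
  }
  data.frame(name = name, mean = mean, se = se, family = family,
             stringsAsFactors = FALSE)
}

#' Estimate a response probability with its binomial standard error
#'
#' Wald estimate: `mean = successes / n`, `se = sqrt(mean * (1 - mean) / n)`,
#' sampled as a beta distribution in the probabilistic analysis.
#'
#' @param successes Number of responders.
#' @param n Arm size.
#' @param name Parameter name carried into the estimate table.
#' @return A one-row data frame with columns `name`, `mean`, `se`, `family`.
#' @examples
#' estimate_response_probability(22, 45)  # 0.489 (0.074)
#' estimate_response_probability(4, 48)   # 0.083 (0.039)
#' @export
estimate_response_probability <- function(successes, n, name = "response_probability") {
  n <- assert_count(n, "n", min = 1L)
  successes <- assert_count(successes, "successes", min = 0L)
  if (successes > n) stop("successes must not exceed n", call. = FALSE)
  p <- successes / n
  se <- sqrt(p * (1 - p) / n)
  fam <- if (se == 0) "fixed" else "beta"
  new_estimated_parameter(name, p, se, fam)
}

#' Estimate 14-day resource use with its standard error
#'
#' The mean number of uses over 14 days enters the model directly; its
#' standard error is `sd / sqrt(n)`, and uncertainty is propagated with a
#' gamma distribution (use counts are non-negative and right-skewed).
#'
#' @param mean_14d Mean uses per 14 days.
#' @param sd_14d Standard deviation of uses per 14 days.
#' @param n Number of patients the summary is based on.
#' @param name Parameter name.
#' @return A one-row data frame with columns `name`, `mean`, `se`, `family`.
#' @examples
#' estimate_resource_use(1.6, 5.5, 45)   # se 0.82
#' estimate_resource_use(6.5, 11.1, 45)  # se 1.65
#' @export
estimate_resource_use <- function(mean_14d, sd_14d, n, name = "resource_use") {
  n <- assert_count(n, "n", min = 1L)
  assert_positive(mean_14d, "mean_14d", strict = FALSE)
  assert_positive(sd_14d, "sd_14d", strict = FALSE)
  se <- sd_14d / sqrt(n)
  fam <- if (se == 0 || mean_14d == 0) "fixed" else "gamma"
  new_estimated_parameter(name, mean_14d, se, fam)
}

#' Fit the EQ-5D utility regression
#'
#' Ordinary least squares of the EQ-5D index on an intercept, a response
#' indicator (week-4 or late response), and a device (active-arm) indicator.
#' The coefficient covariance is the usual OLS estimate
#' `sigma^2 * (X'X)^-1` and feeds the multivariate-normal utility draws of
#' the probabilistic analysis.
#'
#' @param data A `trial_data` data frame.
#' @return An object of class `utility_regression`: a list with
#'   `intercept`, `coef_response`, `coef_device`, `coefficient_covariance`
#'   (3x3), and `n_obs`.
#' @export
fit_utility_regression <- function(data) {
  stopifnot(inherits(data, "data.frame"))
  if (nrow(data) < 10L) {
    stop("need at least 10 observations to fit the utility regression",
         call. = FALSE)
  }
  responder <- data$responder_week4 | data$late_responder
  device <- data$arm == "active"
  # every response-by-arm cell must be populated or the fit cannot separate
  # the response and device effects
  cells <- table(factor(responder, levels = c(FALSE, TRUE)),
                 factor(device, levels = c(FALSE, TRUE)))
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "design is rank deficient: no %s in the %s arm",
      if (idx[1] == 2L) "responders" else "non-responders",
      if (idx[2] == 2L) "active" else "control"), call. = FALSE)
  }
  fit <- stats::lm(eq5d_index ~ responder + device,
                   data = data.frame(eq5d_index = data$eq5d_index,
                                     responder = responder, device = device))
  cf <- unname(stats::coef(fit))
  # a zero-residual fit (noise-free synthetic data) triggers a harmless
  # "essentially perfect fit" warning from summary.lm
  covmat <- withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(intercept = cf[1], coef_response = cf[2], coef_device = cf[3],
         coefficient_covariance = unname(covmat),
         n_obs = nrow(data)),
    class = "utility_regression"
  )
}

#' Map regression coefficients to the four state utilities
#'
#' @param reg A `utility_regression`, or a numeric vector
#'   `c(intercept, coef_response, coef_device)`.
#' @return Named numeric vector with elements `soc_nonresponder`,
#'   `soc_responder`, `nvns_nonresponder`, `nvns_responder`.
#' @examples
#' utilities_from_regression(c(0.523, 0.2366, 0.01246))
#' @export
utilities_from_regression <- function(reg) {
  if (inherits(reg, "utility_regression")) {
    cf <- c(reg$intercept, reg$coef_response, reg$coef_device)
  } else {
    stopifnot(is.numeric(reg), length(reg) == 3L)
    cf <- unname(reg)
  }
  u <- c(soc_nonresponder  = cf[1],
         soc_responder     = cf[1] + cf[2],
         nvns_nonresponder = cf[1] + cf[3],
         nvns_responder    = cf[1] + cf[2] + cf[3])
  pmin(pmax(u, -0.2), 1)
}

#' Monthly response-loss probability from an exponential survival fit
#'
#' Given the fraction of responders retained over `dt_months`, the constant
#' hazard is `lambda = -log(retained_ratio) / dt_months` and the monthly loss
#' probability `1 - exp(-lambda)`.
#'
#' @param retained_ratio Fraction retaining response over the interval,
#'   in (0, 1].
#' @param dt_months Interval length in months.
#' @return Monthly loss probability.
#' @examples
#' fit_exponential_loss(0.69, 1)  # 0.31
#' fit_exponential_loss(0.25, 2)  # 0.5
#' @export
fit_exponential_loss <- function(retained_ratio, dt_months) {
  assert_positive(dt_months, "dt_months")
  if (!is.numeric(retained_ratio) || length(retained_ratio) != 1L ||
      is.na(retained_ratio) || retained_ratio > 1) {
    stop("'retained_ratio' must be a single value in (0, 1]", call. = FALSE)
  }
  if (retained_ratio <= 0) {
    stop("retained_ratio = 0 implies an infinite hazard", call. = FALSE)
  }
  lambda <- -log(retained_ratio) / dt_months
  1 - exp(-lambda)
}

#' Derive the full probabilistic-analysis parameter table from trial data
#'
#' Reproduces, from patient-level data, every uncertain model input: the two
#' response probabilities (beta), the monthly discontinuation probability
#' from the month-2 retention of week-4 responders (truncated normal; its
#' standard error is not derivable from published counts and is taken as an
#' input), per-arm 14-day medication use (gamma), and the EQ-5D regression
#' coefficients (multivariate normal).
#'
#' @param data A `trial_data` data frame.
#' @param discontinuation_se Standard error attached to the discontinuation
#'   probability (default 0.378).
#' @return A data frame (`name`, `mean`, `se`, `family`) with the fitted
#'   `utility_regression` attached as attribute `"regression"`.
#' @export
estimate_parameters <- function(data, discontinuation_se = 0.378) {
  stopifnot(inherits(data, "data.frame"))
  active <- data[data$arm == "active", , drop = FALSE]
  control <- data[data$arm == "control", , drop = FALSE]
  n_a <- nrow(active); n_c <- nrow(control)
  if (n_a == 0L || n_c == 0L) stop("both arms required", call. = FALSE)

  resp_a <- sum(active$responder_week4 | active$late_responder)
  resp_c <- sum(control$responder_week4)

  wk4 <- active$responder_week4
  if (!any(wk4)) stop("no week-4 responders in the active arm; cannot fit response loss",
                      call. = FALSE)
  retained <- mean(active$responder_extension_end[wk4])
  p_disc <- fit_exponential_loss(max(retained, 1e-12), 1)

  rows <- rbind(
    estimate_response_probability(resp_a, n_a, "p_response_nvns"),
    estimate_response_probability(resp_c, n_c, "p_response_soc"),
    new_estimated_parameter("p_discontinue", p_disc, discontinuation_se,
                            "normal_truncated01")
  )
  for (med in c("zolmitriptan", "sumatriptan", "oxygen")) {
    col <- paste0(med, "_14d")
    rows <- rbind(
      rows,
      estimate_resource_use(mean(active[[col]]), stats::sd(active[[col]]),
                            n_a, paste0(med, "_nvns")),
      estimate_resource_use(mean(control[[col]]), stats::sd(control[[col]]),
                            n_c, paste0(med, "_soc"))
    )
  }
  reg <- fit_utility_regression(data)
  rows <- rbind(
    rows,
    new_estimated_parameter("utility_intercept", reg$intercept,
                            sqrt(reg$coefficient_covariance[1, 1]), "mv_normal"),
    new_estimated_parameter("utility_response", reg$coef_response,
                            sqrt(reg$coefficient_covariance[2, 2]), "mv_normal"),
    new_estimated_parameter("utility_device", reg$coef_device,
                            sqrt(reg$coefficient_covariance[3, 3]), "mv_normal")
  )
  attr(rows, "regression") <- reg
  rows
}

#' Write / read an estimated-parameter table as CSV
#'
#' Columns `name`, `mean`, `se`, `family`; the regression attribute (if any)
#' is not serialised.
#'
#' @param params Estimate table from [estimate_parameters()].
#' @param path File path.
#' @export
write_parameter_table <- function(params, path) {
  stopifnot(all(c("name", "mean", "se", "family") %in% names(params)))
  utils::write.csv(params[c("name", "mean", "se", "family")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "mean", "se", "family") %in% names(out))) {
    stop("not an estimated-parameter CSV", call. = FALSE)
  }
  out
}
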