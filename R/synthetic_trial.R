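#' Default abortive medication use targets
#'
#' Mean and standard deviation of the number of uses of each abortive
#' medication over a 14-day observation window, by trial arm. These are the
#' arm-level summaries the generator reproduces: intranasal zolmitriptan,
#' subcutaneous sumatriptan, and inhaled oxygen for the nVNS + SoC arm
#' (n = 45) and the SoC-alone arm (n = 48).
#'
#' @return A data frame with columns `medication`, `active_mean`, `active_sd`,
#'   `control_mean`, `control_sd`.
#' @export
default_med_use_targets <- function() {
  data.frame(
    medication   = c("zolmitriptan", "sumatriptan", "oxygen"),
    active_mean  = c(1.6, 2.8, 6.5),
    active_sd    = c(5.5, 4.0, 11.1),
    control_mean = c(1.3, 7.5, 10.8),
    control_sd   = c(3.6, 9.6, 15.3),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic trial generator
#'
#' Describes the statistical structure of a PREVA-like two-arm trial:
#' arm sizes, response probabilities during the 4-week randomised phase,
#' the marginal probability of a late response (a response first seen during
#' the extension phase, active arm only), month-2 response retention, the
#' linear EQ-5D index model, and per-arm 14-day abortive-medication use
#' targets.
#'
#' `p_late_response_active` is the marginal probability of being a late
#' responder, so `p_response_active + p_late_response_active` is the overall
#' response probability; internally late response is drawn among week-4
#' non-responders at the implied conditional rate.
#'
#' @param n_active,n_control Arm sizes (defaults 45 and 48).
#' @param p_response_active Week-4 response probability, active arm
#'   (default 18/45).
#' @param p_late_response_active Marginal late-response probability, active
#'   arm (default 4/45).
#' @param p_response_control Week-4 response probability, control arm
#'   (default 4/48).
#' @param p_retain_month2 Probability that a week-4 responder still responds
#'   at the end of the extension phase one month later (default 0.69, the
#'   retention implied by a 0.310 monthly discontinuation probability).
#' @param eq5d_intercept,beta_response,beta_device Coefficients of the linear
#'   EQ-5D index model: baseline utility of a control-arm non-responder,
#'   increment for response, increment for device use (defaults 0.523,
#'   0.2366, 0.01246).
#' @param eq5d_noise_sd Residual standard deviation of the EQ-5D index
#'   (default 0.2). Indices are clamped to the plausible tariff range
#'   \[-0.2, 1\].
#' @param med_use_targets Data frame as returned by
#'   [default_med_use_targets()].
#' @param seed Integer seed making the generated data reproducible.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_active = 45L,
                         n_control = 48L,
                         p_response_active = 18 / 45,
                         p_late_response_active = 4 / 45,
                         p_response_control = 4 / 48,
                         p_retain_month2 = 0.69,
                         eq5d_intercept = 0.523,
                         beta_response = 0.2366,
                         beta_device = 0.01246,
                         eq5d_noise_sd = 0.2,
                         med_use_targets = default_med_use_targets(),
                         seed = 1L) {
  n_active <- assert_count(n_active, "n_active", min = 0L)
  n_control <- assert_count(n_control, "n_control", min = 0L)
  if (n_active + n_control == 0L) {
    stop("at least one arm must have patients", call. = FALSE)
  }
  assert_prob(p_response_active, "p_response_active")
  assert_prob(p_late_response_active, "p_late_response_active")
  assert_prob(p_response_control, "p_response_control")
  assert_prob(p_retain_month2, "p_retain_month2")
  if (p_response_active + p_late_response_active > 1) {
    stop("p_response_active + p_late_response_active must not exceed 1",
         call. = FALSE)
  }
  assert_positive(eq5d_noise_sd, "eq5d_noise_sd", strict = FALSE)
  stopifnot(is.data.frame(med_use_targets),
            all(c("medication", "active_mean", "active_sd",
                  "control_mean", "control_sd") %in% names(med_use_targets)))
  if (any(med_use_targets$active_sd <= 0) || any(med_use_targets$control_sd <= 0)) {
    stop("medication use SDs must be > 0", call. = FALSE)
  }
  if (any(med_use_targets$active_mean < 0) || any(med_use_targets$control_mean < 0)) {
    stop("medication use means must be >= 0", call. = FALSE)
  }
  structure(
    list(n_active = n_active, n_control = n_control,
         p_response_active = p_response_active,
         p_late_response_active = p_late_response_active,
         p_response_control = p_response_control,
         p_retain_month2 = p_retain_month2,
         eq5d_intercept = eq5d_intercept,
         beta_response = beta_response,
         beta_device = beta_device,
         eq5d_noise_sd = eq5d_noise_sd,
         med_use_targets = med_use_targets,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Count draws with a target mean/SD: negative binomial when overdispersed
# (SD^2 > mean), Poisson fallback otherwise (with a warning, since the
# requested SD cannot then be honoured).
draw_counts <- function(n, mean, sd, label) {
  if (n == 0L) return(integer(0))
  if (mean == 0) return(integer(n))
  v <- sd^2
  if (v > mean) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    warning(sprintf(
      "'%s': SD^2 (%.3f) <= mean (%.3f); negative-binomial moment matching infeasible, falling back to Poisson",
      label, v, mean), call. = FALSE)
    stats::rpois(n, mean)
  }
}

#' Generate synthetic patient-level trial data
#'
#' Draws one patient-level dataset with the structure the estimation and
#' cohort modules assume: arm assignment, week-4 response, late response
#' (active arm, among week-4 non-responders), response at the end of the
#' extension phase (week-4 responders retain with probability
#' `p_retain_month2`; late responders respond by definition), 14-day
#' abortive-medication counts (negative binomial, moment-matched per arm),
#' and an EQ-5D index from the linear model
#' `intercept + beta_response * responder + beta_device * active + noise`,
#' clamped to \[-0.2, 1\].
#'
#' @param config A [synth_config()] object.
#' @return A data frame of class `trial_data` with one row per patient and
#'   columns `patient_id`, `arm`, `responder_week4`, `late_responder`,
#'   `responder_extension_end`, `zolmitriptan_14d`, `sumatriptan_14d`,
#'   `oxygen_14d`, `eq5d_index`.
#' @examples
#' trial <- generate_trial(synth_config(seed = 1))
#' table(trial$arm)
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("'config' must be a synth_config object", call. = FALSE)
  }
  set.seed(config$seed)
  n_a <- config$n_active
  n_c <- config$n_control
  arm <- c(rep("active", n_a), rep("control", n_c))
  n <- n_a + n_c

  responder_week4 <- logical(n)
  late_responder <- logical(n)
  is_active <- arm == "active"
  responder_week4[is_active] <- stats::runif(n_a) < config$p_response_active
  responder_week4[!is_active] <- stats::runif(n_c) < config$p_response_control
  # marginal late-response probability -> conditional rate among week-4
  # non-responders
  if (config$p_late_response_active > 0 && config$p_response_active < 1) {
    p_cond <- config$p_late_response_active / (1 - config$p_response_active)
    cand <- is_active & !responder_week4
    late_responder[cand] <- stats::runif(sum(cand)) < min(p_cond, 1)
  }

  responder_extension_end <- logical(n)
  wk4 <- responder_week4
  responder_extension_end[wk4] <- stats::runif(sum(wk4)) < config$p_retain_month2
  responder_extension_end[late_responder] <- TRUE

  tg <- config$med_use_targets
  counts <- lapply(seq_len(nrow(tg)), function(i) {
    x <- integer(n)
    x[is_active] <- draw_counts(n_a, tg$active_mean[i], tg$active_sd[i],
                                paste0(tg$medication[i], " (active)"))
    x[!is_active] <- draw_counts(n_c, tg$control_mean[i], tg$control_sd[i],
                                 paste0(tg$medication[i], " (control)"))
    x
  })
  names(counts) <- paste0(tg$medication, "_14d")

  responder <- responder_week4 | late_responder
  eq5d <- config$eq5d_intercept +
    config$beta_response * responder +
    config$beta_device * is_active +
    stats::rnorm(n, 0, config$eq5d_noise_sd)
  eq5d <- pmin(pmax(eq5d, -0.2), 1)

  out <- data.frame(patient_id = seq_len(n), arm = arm,
                    responder_week4 = responder_week4,
                    late_responder = late_responder,
                    responder_extension_end = responder_extension_end,
                    stringsAsFactors = FALSE)
  for (nm in names(counts)) out[[nm]] <- counts[[nm]]
  out$eq5d_index <- eq5d
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Write / read trial data as flat CSV
#'
#' One row per patient; the header is fixed to the `trial_data` column set so
#' files round-trip exactly.
#'
#' @param data A `trial_data` data frame.
#' @param path File path.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "arm", "responder_week4", "late_responder",
              "responder_extension_end", "zolmitriptan_14d", "sumatriptan_14d",
              "oxygen_14d", "eq5d_index")
  missing <- setdiff(needed, names(out))
  if (length(missing)) {
    stop("not a trial-data CSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Write a generator configuration as key: value text
#'
#' @param config A [synth_config()] object.
#' @param path File path.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  scalar <- config[setdiff(names(config), "med_use_targets")]
  lines <- sprintf("%s: %s", names(scalar),
                   vapply(scalar, function(x) format(x, digits = 15), ""))
  tg <- config$med_use_targets
  med <- sprintf("med_use.%s: active %s (%s), control %s (%s)",
                 tg$medication, tg$active_mean, tg$active_sd,
                 tg$control_mean, tg$control_sd)
  writeLines(c(lines, med), path)
  invisible(path)
}
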