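# Reporting: regenerate the analysis' result tables (base case, alternative
# scenarios, late-responder sensitivity), the cost-effectiveness plane, and
# the cost-component breakdown, plus disk round-trips of the whole bundle.

#' Run configuration for the full analysis
#'
#' @param n_sims Simulations per scenario (default 1000).
#' @param seed Base seed.
#' @param wtp_threshold Willingness to pay, EUR/QALY.
#' @param scenarios Alternative scenarios to run next to the base case.
#' @param sensitivity_scenarios Scenarios re-run with late responders
#'   excluded.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_sims = 1000L, seed = 1L, wtp_threshold = 20000,
                       scenarios = c("constant_loss", "diminishing_loss",
                                     "no_soc_response"),
                       sensitivity_scenarios = c("maintained", "constant_loss",
                                                 "diminishing_loss")) {
  n_sims <- assert_count(n_sims, "n_sims", min = 1L)
  stopifnot(all(scenarios %in% SCENARIOS),
            all(sensitivity_scenarios %in% SCENARIOS))
  structure(list(n_sims = n_sims, seed = as.integer(seed),
                 wtp_threshold = wtp_threshold, scenarios = scenarios,
                 sensitivity_scenarios = sensitivity_scenarios),
            class = "run_config")
}

#' Generate a synthetic trial and write it to CSV
#'
#' Thin wrapper around [generate_trial()] + [write_trial_csv()] with run
#' logging (seed, configuration hash, package version).
#'
#' @param config A [synth_config()] object.
#' @param path Output CSV path.
#' @return The trial data, invisibly.
#' @export
simulate_trial_csv <- function(config = synth_config(), path) {
  log_run("simulate-trial", config$seed, config)
  trial <- generate_trial(config)
  write_trial_csv(trial, path)
  message(sprintf("wrote %d patients to %s", nrow(trial), path))
  invisible(trial)
}

log_run <- function(what, seed, config) {
  message(sprintf("[nvnscea %s] %s: seed %s, config hash %s",
                  as.character(utils::packageVersion("nvnscea")),
                  what, format(seed), config_hash(config)))
}

psa_summary_row <- function(scenario_label, psa) {
  s <- psa$summary
  lab <- if (s$icer$label == "icer") sprintf("%.2f", s$icer$value) else s$icer$label
  data.frame(
    scenario = scenario_label,
    arm = c("nvns_soc", "soc_alone"),
    mean_cost = round_cents(c(s$mean_cost_active, s$mean_cost_control)),
    mean_qaly = round(c(s$mean_qaly_active, s$mean_qaly_control), 3),
    icer = c(lab, ""),
    fraction_cost_saving = c(s$fraction_cost_saving, NA),
    stringsAsFactors = FALSE
  )
}

#' Run the complete analysis
#'
#' Runs the probabilistic analysis for the base case, the alternative
#' scenarios, and the late-responder sensitivity, and assembles the result
#' bundle: three summary tables (base case; alternative scenarios;
#' sensitivity), a long-format table for machine consumption, the base-case
#' cost-effectiveness plane, the acceptability curve, and the deterministic
#' base-case cost-component breakdown per arm.
#'
#' @param params A `ce_parameters` object.
#' @param config A [run_config()].
#' @param specs Optional [default_psa_specs()]; built from `params` if NULL.
#' @return A list of class `results_bundle`.
#' @export
run_all <- function(params = default_parameters(), config = run_config(),
                    specs = NULL) {
  stopifnot(inherits(params, "ce_parameters"), inherits(config, "run_config"))
  params$wtp_threshold <- config$wtp_threshold
  if (is.null(specs)) specs <- default_psa_specs(params)
  specs$base$wtp_threshold <- config$wtp_threshold
  log_run("run-all", config$seed, config)

  base <- run_psa(specs, scenario_spec("maintained"),
                  n_sims = config$n_sims, seed = config$seed)
  scen <- lapply(config$scenarios, function(k) {
    run_psa(specs, scenario_spec(k), n_sims = config$n_sims, seed = config$seed)
  })
  names(scen) <- config$scenarios
  sens <- lapply(config$sensitivity_scenarios, function(k) {
    run_psa(specs, scenario_spec(k, include_late_responders = FALSE),
            n_sims = config$n_sims, seed = config$seed)
  })
  names(sens) <- config$sensitivity_scenarios

  table_base <- psa_summary_row("base_case", base)
  table_scenarios <- do.call(rbind, Map(psa_summary_row, names(scen), scen))
  table_sensitivity <- do.call(
    rbind, Map(function(n, p) psa_summary_row(paste0(n, "_late_excluded"), p),
               names(sens), sens))
  rownames(table_scenarios) <- rownames(table_sensitivity) <- NULL

  det <- run_deterministic(params, scenario_spec("maintained"))
  breakdown <- data.frame(
    arm = rep(c("nvns_soc", "soc_alone"), each = 4L),
    component = rep(names(det$active$cost_components), 2L),
    cost = round_cents(c(det$active$cost_components,
                         det$control$cost_components)),
    stringsAsFactors = FALSE
  )

  all_tables <- rbind(table_base, table_scenarios, table_sensitivity)
  long <- do.call(rbind, lapply(seq_len(nrow(all_tables)), function(i) {
    r <- all_tables[i, ]
    data.frame(scenario = r$scenario, arm = r$arm,
               metric = c("mean_cost", "mean_qaly"),
               value = c(r$mean_cost, r$mean_qaly),
               stringsAsFactors = FALSE)
  }))

  structure(
    list(table_base = table_base,
         table_scenarios = table_scenarios,
         table_sensitivity = table_sensitivity,
         long = long,
         ce_plane = ce_plane_export(base),
         ceac = ceac(base),
         cost_breakdown = breakdown,
         psa = c(list(base_case = base), scen,
                 stats::setNames(sens, paste0(names(sens), "_late_excluded"))),
         meta = list(seed = config$seed, n_sims = config$n_sims,
                     wtp_threshold = config$wtp_threshold,
                     config_hash = config_hash(config),
                     package_version = as.character(utils::packageVersion("nvnscea")))),
    class = "results_bundle"
  )
}

#' Write / read a results bundle
#'
#' Writes the summary tables, the long-format table, the cost-effectiveness
#' plane, the acceptability curve and the cost breakdown as CSV, and the
#' run metadata plus per-scenario summaries as JSON. `read_results_bundle()`
#' restores the tables (not the raw per-draw objects) so that summaries
#' round-trip exactly.
#'
#' @param bundle A `results_bundle` from [run_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write`); a list of tables (`read`).
#' @export
write_results_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(bundle$table_base, "table_base_case.csv")
  wr(bundle$table_scenarios, "table_scenarios.csv")
  wr(bundle$table_sensitivity, "table_sensitivity.csv")
  wr(bundle$long, "results_long.csv")
  wr(bundle$ce_plane, "ce_plane.csv")
  wr(bundle$ceac, "ceac.csv")
  wr(bundle$cost_breakdown, "cost_breakdown.csv")
  summaries <- lapply(bundle$psa, function(p) {
    s <- p$summary
    list(scenario = p$scenario$kind,
         include_late_responders = p$scenario$include_late_responders,
         mean_cost_active = s$mean_cost_active,
         mean_cost_control = s$mean_cost_control,
         mean_qaly_active = s$mean_qaly_active,
         mean_qaly_control = s$mean_qaly_control,
         icer_label = s$icer$label,
         fraction_cost_saving = s$fraction_cost_saving,
         fraction_cost_effective = s$fraction_cost_effective)
  })
  jsonlite::write_json(list(meta = bundle$meta, summaries = summaries),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_results_bundle
#' @export
read_results_bundle <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(table_base = rd("table_base_case.csv"),
       table_scenarios = rd("table_scenarios.csv"),
       table_sensitivity = rd("table_sensitivity.csv"),
       long = rd("results_long.csv"),
       ce_plane = rd("ce_plane.csv"),
       ceac = rd("ceac.csv"),
       cost_breakdown = rd("cost_breakdown.csv"),
       meta = jsonlite::read_json(file.path(dir, "summary.json"))$meta)
}
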