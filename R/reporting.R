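# Report writers: CSV outputs with fixed column orders plus a JSON run
# manifest listing every file written.

write_manifest <- function(output_dir, files, config_path = NA_character_,
                           scenario_path = NA_character_, seed = NA_integer_) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("pracdelay")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_path, scenarios = scenario_path, seed = seed,
    output_dir = output_dir, files = files)
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Write a cohort trace and cost trace to CSV
#'
#' One row per cycle: the three occupancies, admission and death flows, then
#' per-resource discounted and undiscounted costs and the cumulative
#' discounted total.
#'
#' @param trace A `cohort_trace`.
#' @param costs The matching `cost_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, costs, path) {
  disc <- costs$by_resource_discounted
  undisc <- costs$by_resource_undiscounted
  colnames(disc) <- paste0(colnames(disc), "_discounted")
  colnames(undisc) <- paste0(colnames(undisc), "_undiscounted")
  df <- cbind(as.data.frame(trace), as.data.frame(disc), as.data.frame(undisc),
              cumulative_discounted = costs$cumulative_discounted)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the two-arm model and write per-arm traces plus a summary
#'
#' Drives the engine for both arms of a configuration and writes one trace
#' CSV per arm, a one-row `summary.csv` (totals, incremental, break-even
#' month) and a run manifest.
#'
#' @param spec A `model_spec`, or a path to a JSON config file.
#' @param output_dir Output directory (created if needed).
#' @param horizon_cycles,annual_rate Optional overrides applied before
#'   running (override any config value).
#' @return The `comparison_result`, invisibly.
#' @export
run_model_report <- function(spec, output_dir, horizon_cycles = NULL,
                             annual_rate = NULL) {
  config_path <- NA_character_
  if (is.character(spec)) {
    config_path <- spec
    spec <- read_model_spec(spec)
  }
  if (!is.null(horizon_cycles)) {
    spec <- apply_scenario(spec, scenario_transform("horizon override",
      list(list(path = "time.horizon_cycles", op = "set", value = horizon_cycles))))
  }
  if (!is.null(annual_rate)) {
    spec <- apply_scenario(spec, scenario_transform("discount override",
      list(list(path = "discount.annual_rate", op = "set", value = annual_rate))))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_arms(spec)
  files <- character(0)
  for (label in c("intervention", "standard_care")) {
    run <- cmp[[label]]
    f <- file.path(output_dir, paste0("trace_", label, ".csv"))
    write_trace_csv(run$trace, run$costs, f)
    files <- c(files, f)
  }
  summary_df <- data.frame(
    intervention_total = cmp$intervention_total,
    standard_care_total = cmp$standard_care_total,
    incremental_total = cmp$incremental_total,
    break_even_month = cmp$break_even_month)
  f <- file.path(output_dir, "summary.csv")
  utils::write.csv(summary_df, f, row.names = FALSE)
  files <- c(files, f)
  write_manifest(output_dir, files, config_path = config_path)
  invisible(cmp)
}

#' Run a scenario suite and write the sensitivity table
#'
#' @param spec A `model_spec` or config path.
#' @param scenarios A list of [scenario_transform()], a path to a scenario
#'   JSON file, or NULL for the packaged default set.
#' @param output_dir Output directory.
#' @return The `sensitivity_table`, invisibly.
#' @export
run_sensitivity_report <- function(spec, scenarios = NULL, output_dir) {
  config_path <- scenario_path <- NA_character_
  if (is.character(spec)) {
    config_path <- spec
    spec <- read_model_spec(spec)
  }
  if (is.null(scenarios)) {
    transforms <- default_scenarios()
  } else if (is.character(scenarios)) {
    scenario_path <- scenarios
    transforms <- read_scenarios(scenarios)
  } else {
    transforms <- scenarios
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- run_sensitivity_suite(spec, transforms)
  f <- file.path(output_dir, "sensitivity.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  write_manifest(output_dir, f, config_path = config_path,
                 scenario_path = scenario_path)
  invisible(tab)
}

#' Compute and write the budget-impact table
#'
#' Computes per-person results from the spec, scales them to the population
#' estimate and writes the seven-column budget-impact CSV (population,
#' intervention cost, 12-month savings and admissions delayed, horizon
#' savings and admissions delayed).
#'
#' @param spec A `model_spec` or config path.
#' @param population A [population_estimate()] or a single central estimate.
#' @param output_dir Output directory.
#' @return The `budget_impact_table`, invisibly.
#' @export
run_budget_impact_report <- function(spec, population, output_dir) {
  config_path <- NA_character_
  if (is.character(spec)) {
    config_path <- spec
    spec <- read_model_spec(spec)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- budget_impact(per_person_results(spec), population)
  cols <- c("level", "population", "intervention_cost_m", "net_savings_12mo_m",
            "prac_delayed_12mo", "net_savings_horizon_m", "prac_delayed_horizon")
  f <- file.path(output_dir, "budget_impact.csv")
  utils::write.csv(tab[, cols], f, row.names = FALSE)
  write_manifest(output_dir, f, config_path = config_path)
  invisible(tab)
}
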