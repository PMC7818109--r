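#' A named, composable parameter modification
#'
#' A scenario is a list of edits, each `(path, op, value)` with
#' `op` one of `"multiply"`, `"set"`, `"add"`. Paths are dot-separated
#' (`"discount.annual_rate"`, `"prac_daily_cost"`,
#' `"mortality.state_hazard_multipliers.prac"`); `"arms.intervention"`,
#' `"arms.standard_care"` and the wildcard `"arms.*"` address arms, and
#' `"costs.<name>"` addresses one of an arm's resource costs. The special
#' path `"admission_prob_difference"` with op `"multiply"` rescales the gap
#' in admission probability between the arms, holding standard care fixed:
#' `p_int' = p_sc - k * (p_sc - p_int)`, clamped to `[0, 1]`.
#'
#' @param name Scenario label.
#' @param edits List of `list(path=, op=, value=)` edits.
#' @return A `scenario_transform`.
#' @export
scenario_transform <- function(name, edits) {
  stopifnot(is.character(name), length(name) == 1L)
  for (e in edits) {
    if (!all(c("path", "op", "value") %in% names(e)) ||
        !e$op %in% c("multiply", "set", "add")) {
      stop("each edit needs path, op (multiply|set|add) and value", call. = FALSE)
    }
  }
  structure(list(name = name, edits = edits), class = "scenario_transform")
}

apply_op <- function(current, op, value) {
  switch(op, multiply = current * value, set = value, add = current + value)
}

# Apply one edit to the plain-list view of a spec.
apply_edit <- function(cfg, path, op, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts[1], "admission_prob_difference")) {
    if (op != "multiply") stop("admission_prob_difference only supports multiply",
                               call. = FALSE)
    labels <- vapply(cfg$arms, `[[`, character(1), "label")
    i_int <- which(labels == "intervention")
    i_sc <- which(labels == "standard_care")
    p_sc <- cfg$arms[[i_sc]]$transition$monthly_admission_prob
    p_int <- cfg$arms[[i_int]]$transition$monthly_admission_prob
    cfg$arms[[i_int]]$transition$monthly_admission_prob <-
      min(1, max(0, p_sc - value * (p_sc - p_int)))
    return(cfg)
  }
  if (identical(parts[1], "arms")) {
    sel <- parts[2]
    rest <- parts[-(1:2)]
    labels <- vapply(cfg$arms, `[[`, character(1), "label")
    idx <- if (identical(sel, "*")) seq_along(cfg$arms) else which(labels == sel)
    if (length(idx) == 0L) stop("no arm matches path: ", path, call. = FALSE)
    for (i in idx) {
      cfg$arms[[i]] <- apply_edit_within(cfg$arms[[i]], rest, op, value, path)
    }
    return(cfg)
  }
  apply_edit_within(cfg, parts, op, value, path)
}

apply_edit_within <- function(node, parts, op, value, full_path) {
  if (length(parts) == 0L) stop("path does not reach a value: ", full_path,
                                call. = FALSE)
  key <- parts[1]
  if (identical(key, "costs")) {
    nm <- parts[2]
    rest <- parts[-(1:2)]
    cost_names <- vapply(node$costs, `[[`, character(1), "name")
    j <- which(cost_names == nm)
    if (length(j) != 1L) stop("no resource cost named '", nm, "' on path: ",
                              full_path, call. = FALSE)
    node$costs[[j]] <- apply_edit_within(node$costs[[j]], rest, op, value, full_path)
    return(node)
  }
  if (!key %in% names(node)) stop("path does not resolve: ", full_path, call. = FALSE)
  if (length(parts) == 1L) {
    if (!is.numeric(node[[key]])) stop("path target is not numeric: ", full_path,
                                       call. = FALSE)
    node[[key]] <- apply_op(node[[key]], op, value)
  } else {
    node[[key]] <- apply_edit_within(node[[key]], parts[-1], op, value, full_path)
  }
  node
}

#' Apply a scenario transform to a model spec
#'
#' Pure: returns a new, fully re-validated spec; the input is unmodified.
#' Multivariate scenarios are simply the sequential application of their
#' edits, so transforms compose.
#'
#' @param spec A `model_spec`.
#' @param transform A [scenario_transform()].
#' @return The transformed, validated `model_spec`.
#' @export
apply_scenario <- function(spec, transform) {
  stopifnot(inherits(transform, "scenario_transform"))
  cfg <- spec_to_config_list(validate_model_spec(spec))
  for (e in transform$edits) cfg <- apply_edit(cfg, e$path, e$op, e$value)
  config_list_to_spec(cfg)
}

#' Run a suite of sensitivity scenarios
#'
#' Runs [compare_arms()] on the base spec and on each transformed spec,
#' returning one row per scenario in the four-column layout of a univariate /
#' multivariate sensitivity table.
#'
#' @param spec Base-case `model_spec`.
#' @param transforms List of [scenario_transform()] objects.
#' @return A `sensitivity_table` data frame with columns `scenario`,
#'   `intervention_total`, `standard_care_total`, `incremental`.
#' @export
run_sensitivity_suite <- function(spec, transforms = list()) {
  specs <- c(list(spec), lapply(transforms, function(tr) apply_scenario(spec, tr)))
  names_ <- c("Base case", vapply(transforms, `[[`, character(1), "name"))
  rows <- lapply(specs, function(s) {
    cmp <- compare_arms(s)
    data.frame(intervention_total = cmp$intervention_total,
               standard_care_total = cmp$standard_care_total,
               incremental = cmp$incremental_total)
  })
  out <- cbind(data.frame(scenario = names_), do.call(rbind, rows))
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Read scenario transforms from a JSON file
#'
#' The file holds a list of `{name, edits: [{path, op, value}]}` objects.
#'
#' @param path JSON file path.
#' @return List of [scenario_transform()] objects.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(sc) scenario_transform(sc$name, sc$edits))
}

#' The packaged univariate/multivariate scenario set
#'
#' The 25 deterministic scenarios shipped with the package (time horizon,
#' discount rate, cost halving/doubling, admission-probability difference,
#' cohort age, excess-mortality and P-RAC-mortality levers, and their
#' combinations), stored as data under `extdata` for auditability.
#'
#' @return List of [scenario_transform()] objects.
#' @export
default_scenarios <- function() {
  read_scenarios(system.file("extdata", "scenarios_default.json",
                             package = "pracdelay", mustWork = TRUE))
}
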