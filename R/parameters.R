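# Model states are fixed by the model structure: people live in the community,
# move (irreversibly) into permanent residential aged care, or die.
MODEL_STATES <- c("community", "prac", "dead")
ARM_LABELS <- c("intervention", "standard_care")
CONFIG_SCHEMA_VERSION <- 1L

fail_validation <- function(key, msg) {
  stop(sprintf("invalid model input `%s`: %s", key, msg), call. = FALSE)
}

check_prob <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    fail_validation(key, "must be a single probability in [0, 1]")
  }
  invisible(x)
}

#' Time settings for the cohort model
#'
#' @param cycle_length_months Cycle length in months (base case 1).
#' @param horizon_cycles Number of cycles to run (base case 60, i.e. 5 years
#'   of monthly cycles).
#' @param half_cycle_correction Apply trapezoidal half-cycle correction to
#'   recurring cost accrual?
#' @return A `time_settings` object.
#' @export
time_settings <- function(cycle_length_months = 1L, horizon_cycles = 60L,
                          half_cycle_correction = TRUE) {
  if (!is.numeric(horizon_cycles) || horizon_cycles < 1 ||
      horizon_cycles != floor(horizon_cycles)) {
    fail_validation("time.horizon_cycles", "must be a positive integer")
  }
  if (!is.numeric(cycle_length_months) || cycle_length_months < 1 ||
      cycle_length_months != floor(cycle_length_months)) {
    fail_validation("time.cycle_length_months", "must be a positive integer")
  }
  structure(
    list(cycle_length_months = as.integer(cycle_length_months),
         horizon_cycles = as.integer(horizon_cycles),
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "time_settings"
  )
}

#' Discount settings
#'
#' @param annual_rate Annual discount rate as a fraction (base case 0.05).
#' @return A `discount_settings` object.
#' @export
discount_settings <- function(annual_rate = 0.05) {
  if (!is.numeric(annual_rate) || length(annual_rate) != 1L ||
      is.na(annual_rate) || annual_rate < 0 || annual_rate >= 1) {
    fail_validation("discount.annual_rate", "must be in [0, 1)")
  }
  structure(list(annual_rate = annual_rate), class = "discount_settings")
}

#' Life table of annual death probabilities
#'
#' An ordered map from integer age (years) to the annual probability of death
#' at that age, plus a `max_age` beyond which the death probability is treated
#' as 1.
#'
#' @param age Integer ages in years, unique and ascending.
#' @param annual_death_prob Annual death probabilities, one per age, in `[0, 1]`.
#' @param max_age Age (years) at and beyond which death is certain. Defaults
#'   to one year past the last tabulated age.
#' @return A `life_table` object.
#' @export
life_table <- function(age, annual_death_prob, max_age = max(age) + 1L) {
  if (length(age) == 0L) fail_validation("life_table", "must have at least one row")
  if (length(age) != length(annual_death_prob)) {
    fail_validation("life_table", "age and annual_death_prob lengths differ")
  }
  if (anyNA(age) || anyNA(annual_death_prob)) {
    fail_validation("life_table", "entries must be non-missing and numeric")
  }
  if (any(age != floor(age))) fail_validation("life_table.age", "ages must be integers")
  if (anyDuplicated(age) || is.unsorted(age, strictly = TRUE)) {
    fail_validation("life_table.age", "ages must be unique and ascending")
  }
  if (any(annual_death_prob < 0) || any(annual_death_prob > 1)) {
    fail_validation("life_table.annual_death_prob", "probabilities must lie in [0, 1]")
  }
  structure(
    list(age = as.integer(age), annual_death_prob = as.numeric(annual_death_prob),
         max_age = as.integer(max_age)),
    class = "life_table"
  )
}

#' Look up the annual death probability at an age
#'
#' Ages between rows use the floor-age row, matching annual actuarial tables;
#' ages at or beyond `max_age` return 1; ages below the tabulated range are an
#' error.
#'
#' @param lt A [life_table()].
#' @param age Age in years (may be fractional).
#' @return Annual death probability.
#' @export
life_table_lookup <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  a <- floor(age)
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    if (a[i] >= lt$max_age) {
      out[i] <- 1
    } else if (a[i] > max(lt$age)) {
      out[i] <- lt$annual_death_prob[length(lt$age)]
    } else {
      j <- match(a[i], lt$age)
      if (is.na(j)) {
        fail_validation("age", sprintf("age %s below the life-table range", a[i]))
      }
      out[i] <- lt$annual_death_prob[j]
    }
  }
  out
}

#' Mortality model: relative risk and per-state hazard multipliers
#'
#' @param dementia_relative_risk Multiplier applied to the all-cause mortality
#'   hazard to represent dementia-specific excess mortality. The default 2.0
#'   is a SYNTHETIC placeholder (see [synthetic_constants()]); configure it.
#' @param state_hazard_multipliers Named numeric vector with elements
#'   `community` and `prac` (both 1 in the base case) multiplying the hazard
#'   in each alive state.
#' @return A `mortality_model` object.
#' @export
mortality_model <- function(dementia_relative_risk = 2.0,
                            state_hazard_multipliers = c(community = 1, prac = 1)) {
  if (!is.numeric(dementia_relative_risk) || dementia_relative_risk <= 0) {
    fail_validation("mortality.dementia_relative_risk", "must be > 0")
  }
  m <- state_hazard_multipliers
  if (!is.numeric(m) || !all(c("community", "prac") %in% names(m)) ||
      any(m[c("community", "prac")] <= 0)) {
    fail_validation("mortality.state_hazard_multipliers",
                    "must be named numerics > 0 for community and prac")
  }
  structure(
    list(dementia_relative_risk = dementia_relative_risk,
         state_hazard_multipliers = c(community = unname(m[["community"]]),
                                      prac = unname(m[["prac"]]))),
    class = "mortality_model"
  )
}

#' Per-arm transition inputs
#'
#' @param monthly_admission_prob Monthly probability of Community to P-RAC
#'   admission (e.g. 0.05 standard care / 0.02 intervention in the dyadic
#'   carer-training model; 0.03 / 0.01 in the frailty-intervention model).
#' @return A `transition_inputs` object.
#' @export
transition_inputs <- function(monthly_admission_prob) {
  check_prob(monthly_admission_prob, "transition.monthly_admission_prob")
  structure(list(monthly_admission_prob = monthly_admission_prob),
            class = "transition_inputs")
}

#' A recurring or one-off resource cost
#'
#' @param name Resource label (e.g. "hospitalisation", "respite_rac",
#'   "home_care_package", "gp", "allied_health", "pharmaceuticals").
#' @param state State in which the cost accrues: "community" or "prac".
#' @param monthly_cost Cost per person-month in that state, 2018 AUD.
#' @param is_one_off One-off costs accrue once at cycle 0 to the Community
#'   occupants (must attach to the community state).
#' @return A `resource_cost` object.
#' @export
resource_cost <- function(name, state, monthly_cost, is_one_off = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    fail_validation("costs.name", "must be a non-empty string")
  }
  if (!state %in% c("community", "prac")) {
    fail_validation(paste0("costs.", name, ".state"),
                    "unknown state label (must be 'community' or 'prac')")
  }
  if (!is.numeric(monthly_cost) || length(monthly_cost) != 1L ||
      is.na(monthly_cost) || monthly_cost < 0) {
    fail_validation(paste0("costs.", name, ".monthly_cost"), "must be >= 0")
  }
  if (isTRUE(is_one_off) && state != "community") {
    fail_validation(paste0("costs.", name, ".is_one_off"),
                    "one-off costs must attach to the community state")
  }
  structure(list(name = name, state = state, monthly_cost = monthly_cost,
                 is_one_off = isTRUE(is_one_off)),
            class = "resource_cost")
}

#' Parameters for one model arm
#'
#' @param label "intervention" or "standard_care".
#' @param transition A [transition_inputs()].
#' @param costs List of [resource_cost()] objects (community and P-RAC
#'   recurring costs other than the P-RAC accommodation itself, which is
#'   derived from the spec-level daily cost).
#' @param program_cost One-off program cost in 2018 AUD, accrued at cycle 0
#'   ($3,755 for the dyadic training program, $1,834 for the frailty
#'   intervention; 0 for standard-care arms).
#' @return An `arm_parameters` object.
#' @export
arm_parameters <- function(label, transition, costs = list(), program_cost = 0) {
  if (!label %in% ARM_LABELS) {
    fail_validation("arm.label", "must be 'intervention' or 'standard_care'")
  }
  stopifnot(inherits(transition, "transition_inputs"))
  if (!all(vapply(costs, inherits, logical(1), "resource_cost"))) {
    fail_validation("arm.costs", "must be a list of resource_cost objects")
  }
  nm <- vapply(costs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) fail_validation("arm.costs", "resource names must be unique")
  if (!is.numeric(program_cost) || program_cost < 0) {
    fail_validation("arm.program_cost", "must be >= 0")
  }
  structure(list(label = label, transition = transition, costs = costs,
                 program_cost = program_cost),
            class = "arm_parameters")
}

#' Full two-arm model specification
#'
#' Bundles everything the engine needs: time and discount settings, life table
#' and mortality model (shared across arms), cohort start age, the two arms,
#' and the P-RAC accommodation cost expressed per day.
#'
#' @param time A [time_settings()].
#' @param discount A [discount_settings()].
#' @param life_table A [life_table()].
#' @param mortality A [mortality_model()].
#' @param cohort_start_age Cohort age in years at model entry.
#' @param arms List of exactly two [arm_parameters()] with distinct labels
#'   `intervention` and `standard_care`.
#' @param prac_daily_cost P-RAC accommodation cost per day, 2018 AUD ($237).
#' @param days_per_month Days-per-month conversion for the daily P-RAC cost;
#'   calendar average 365.25/12 by default.
#' @return A validated `model_spec` object.
#' @export
model_spec <- function(time, discount, life_table, mortality, cohort_start_age,
                       arms, prac_daily_cost = 237, days_per_month = 365.25 / 12) {
  spec <- structure(
    list(schema_version = CONFIG_SCHEMA_VERSION, time = time, discount = discount,
         life_table = life_table, mortality = mortality,
         cohort_start_age = cohort_start_age, arms = arms,
         prac_daily_cost = prac_daily_cost, days_per_month = days_per_month),
    class = "model_spec"
  )
  validate_model_spec(spec)
}

#' Validate a model specification
#'
#' Checks every structural invariant: component classes, exactly two distinct
#' arm labels, non-negative costs, start age within the life-table range.
#'
#' @param spec A `model_spec`.
#' @return The spec, invisibly returned visible for chaining.
#' @export
validate_model_spec <- function(spec) {
  if (!inherits(spec, "model_spec")) fail_validation("spec", "not a model_spec")
  stopifnot(inherits(spec$time, "time_settings"),
            inherits(spec$discount, "discount_settings"),
            inherits(spec$life_table, "life_table"),
            inherits(spec$mortality, "mortality_model"))
  labels <- vapply(spec$arms, `[[`, character(1), "label")
  if (length(spec$arms) != 2L || !setequal(labels, ARM_LABELS)) {
    fail_validation("arms", "exactly two arms labelled intervention and standard_care required")
  }
  if (!all(vapply(spec$arms, inherits, logical(1), "arm_parameters"))) {
    fail_validation("arms", "must be arm_parameters objects")
  }
  if (!is.numeric(spec$prac_daily_cost) || spec$prac_daily_cost < 0) {
    fail_validation("prac_daily_cost", "must be >= 0")
  }
  if (!is.numeric(spec$days_per_month) || spec$days_per_month <= 0) {
    fail_validation("days_per_month", "must be > 0")
  }
  a <- spec$cohort_start_age
  if (!is.numeric(a) || length(a) != 1L || is.na(a)) {
    fail_validation("cohort_start_age", "must be a single number")
  }
  if (floor(a) < min(spec$life_table$age)) {
    fail_validation("cohort_start_age", "below the life-table age range")
  }
  spec
}

#' Fetch one arm of a spec by label
#'
#' @param spec A `model_spec`.
#' @param label "intervention" or "standard_care".
#' @return The matching `arm_parameters`.
#' @export
spec_arm <- function(spec, label) {
  label <- match.arg(label, ARM_LABELS)
  for (arm in spec$arms) if (arm$label == label) return(arm)
  stop("arm not found: ", label, call. = FALSE)
}

# ---- configuration I/O (JSON with a schema_version key) ----

spec_to_config_list <- function(spec) {
  list(
    schema_version = CONFIG_SCHEMA_VERSION,
    time = unclass(spec$time),
    discount = unclass(spec$discount),
    life_table = list(age = spec$life_table$age,
                      annual_death_prob = spec$life_table$annual_death_prob,
                      max_age = spec$life_table$max_age),
    mortality = list(
      dementia_relative_risk = spec$mortality$dementia_relative_risk,
      state_hazard_multipliers = as.list(spec$mortality$state_hazard_multipliers)),
    cohort_start_age = spec$cohort_start_age,
    prac_daily_cost = spec$prac_daily_cost,
    days_per_month = spec$days_per_month,
    arms = lapply(spec$arms, function(arm) list(
      label = arm$label,
      transition = unclass(arm$transition),
      program_cost = arm$program_cost,
      costs = lapply(arm$costs, unclass)))
  )
}

config_list_to_spec <- function(cfg) {
  need <- function(x, key) {
    if (is.null(x)) fail_validation(key, "missing field")
    x
  }
  arms <- lapply(need(cfg$arms, "arms"), function(a) {
    arm_parameters(
      label = need(a$label, "arm.label"),
      transition = transition_inputs(
        need(a$transition$monthly_admission_prob, "transition.monthly_admission_prob")),
      costs = lapply(a$costs, function(rc) {
        resource_cost(need(rc$name, "costs.name"), need(rc$state, "costs.state"),
                      need(rc$monthly_cost, "costs.monthly_cost"),
                      isTRUE(rc$is_one_off))
      }),
      program_cost = need(a$program_cost, "arm.program_cost"))
  })
  shm <- need(cfg$mortality$state_hazard_multipliers, "mortality.state_hazard_multipliers")
  model_spec(
    time = time_settings(need(cfg$time$cycle_length_months, "time.cycle_length_months"),
                         need(cfg$time$horizon_cycles, "time.horizon_cycles"),
                         need(cfg$time$half_cycle_correction, "time.half_cycle_correction")),
    discount = discount_settings(need(cfg$discount$annual_rate, "discount.annual_rate")),
    life_table = life_table(need(cfg$life_table$age, "life_table.age"),
                            need(cfg$life_table$annual_death_prob,
                                 "life_table.annual_death_prob"),
                            need(cfg$life_table$max_age, "life_table.max_age")),
    mortality = mortality_model(
      need(cfg$mortality$dementia_relative_risk, "mortality.dementia_relative_risk"),
      c(community = need(shm$community, "state_hazard_multipliers.community"),
        prac = need(shm$prac, "state_hazard_multipliers.prac"))),
    cohort_start_age = need(cfg$cohort_start_age, "cohort_start_age"),
    arms = arms,
    prac_daily_cost = need(cfg$prac_daily_cost, "prac_daily_cost"),
    days_per_month = need(cfg$days_per_month, "days_per_month"))
}

#' Read a model specification from a JSON configuration file
#'
#' @param path Path to a JSON configuration (as written by
#'   [write_model_spec()]).
#' @return A validated `model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  config_list_to_spec(cfg)
}

#' Write a model specification to a JSON configuration file
#'
#' Numeric fields are written at full precision so that write-then-read
#' round-trips exactly.
#'
#' @param spec A `model_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  jsonlite::write_json(spec_to_config_list(spec), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a life table from CSV
#'
#' Expects header `age,annual_death_prob`, one row per integer age.
#'
#' @param path CSV path.
#' @param max_age Optional certain-death age; defaults to one year past the
#'   last row.
#' @return A `life_table`.
#' @export
read_life_table <- function(path, max_age = NULL) {
  if (!file.exists(path)) stop("life-table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) fail_validation("life_table", "file has no rows")
  if (!all(c("age", "annual_death_prob") %in% names(df))) {
    fail_validation("life_table", "CSV must have columns age, annual_death_prob")
  }
  bad <- which(!is.finite(df$age) | !is.finite(df$annual_death_prob) |
                 df$annual_death_prob < 0 | df$annual_death_prob > 1)
  if (length(bad)) {
    fail_validation("life_table",
                    sprintf("non-numeric or out-of-range entry at row %d", bad[1]))
  }
  if (is.null(max_age)) max_age <- max(df$age) + 1L
  life_table(df$age, df$annual_death_prob, max_age = max_age)
}

#' Write a life table to CSV
#'
#' @param lt A `life_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(data.frame(age = lt$age, annual_death_prob = lt$annual_death_prob),
                   path, row.names = FALSE)
  invisible(path)
}
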