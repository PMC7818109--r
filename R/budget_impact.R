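round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Eligible-population estimate with plausible bounds
#'
#' @param central Central estimate of the eligible population (persons), e.g.
#'   31,800 for the dyadic carer-training program and 158,900 for the frailty
#'   intervention.
#' @param low,high Lower/upper bounds; default central +/- 10%, rounded to the
#'   nearest 100 persons.
#' @return A `population_estimate`.
#' @export
population_estimate <- function(central,
                                low = round_half_up(central * 0.9, -2),
                                high = round_half_up(central * 1.1, -2)) {
  if (!is.numeric(central) || central <= 0) {
    stop("population must be positive", call. = FALSE)
  }
  if (!(low <= central && central <= high) || low <= 0) {
    stop("population bounds must satisfy 0 < low <= central <= high", call. = FALSE)
  }
  structure(list(central = central, low = low, high = high),
            class = "population_estimate")
}

#' Per-person model quantities feeding the budget impact
#'
#' @param program_cost One-off program cost per person (AUD).
#' @param incremental_12mo,incremental_horizon Per-person incremental
#'   discounted cost at 12 months and at the full horizon (negative =
#'   savings).
#' @param delta_cum_admission_12mo,delta_cum_admission_horizon Difference in
#'   cumulative P-RAC admission fraction (standard care minus intervention)
#'   at 12 months and at the horizon; optional (NA if not computed).
#' @return A `per_person_impact` list.
#' @export
per_person_impact <- function(program_cost, incremental_12mo, incremental_horizon,
                              delta_cum_admission_12mo = NA_real_,
                              delta_cum_admission_horizon = NA_real_) {
  stopifnot(is.numeric(program_cost), program_cost >= 0)
  structure(list(program_cost = program_cost,
                 incremental_12mo = incremental_12mo,
                 incremental_horizon = incremental_horizon,
                 delta_cum_admission_12mo = delta_cum_admission_12mo,
                 delta_cum_admission_horizon = delta_cum_admission_horizon),
            class = "per_person_impact")
}

#' Compute per-person budget-impact inputs from a model spec
#'
#' Runs the two-arm comparison at the spec's horizon and again truncated to
#' 12 months, extracting per-person incremental discounted costs and the
#' difference in cumulative admission flows (standard care minus
#' intervention, i.e. admissions delayed per modelled person). Cumulative
#' admissions sum the per-cycle Community to P-RAC flow, which counts people
#' who later die in P-RAC, unlike horizon occupancy.
#'
#' @param spec A `model_spec`.
#' @return A [per_person_impact()].
#' @export
per_person_results <- function(spec) {
  cmp <- compare_arms(spec)
  t12 <- min(12L %/% spec$time$cycle_length_months, spec$time$horizon_cycles)
  cum_adm <- function(run) cumsum(run$trace$new_admissions)
  d_adm <- cum_adm(cmp$standard_care) - cum_adm(cmp$intervention)
  inc_cum <- cmp$cumulative_intervention - cmp$cumulative_standard_care
  per_person_impact(
    program_cost = spec_arm(spec, "intervention")$program_cost,
    incremental_12mo = inc_cum[t12 + 1L],
    incremental_horizon = cmp$incremental_total,
    delta_cum_admission_12mo = d_adm[t12 + 1L],
    delta_cum_admission_horizon = d_adm[spec$time$horizon_cycles + 1L])
}

#' Scale per-person results to national totals
#'
#' Multiplies the per-person quantities by the central, low and high
#' population estimates. Money columns are also reported in millions of AUD
#' rounded half-up to the nearest million. Net savings are the magnitude of
#' the (negative) incremental cost.
#'
#' @param per_person A [per_person_impact()].
#' @param pop A [population_estimate()].
#' @return A `budget_impact_table` data frame with one row per population
#'   level (`central`, `high`, `low`) and columns `population`,
#'   `intervention_cost_total`, `net_savings_12mo`, `prac_delayed_12mo`,
#'   `net_savings_horizon`, `prac_delayed_horizon`, plus `_m` millions
#'   columns for the money totals.
#' @export
budget_impact <- function(per_person, pop) {
  stopifnot(inherits(per_person, "per_person_impact"))
  if (!inherits(pop, "population_estimate")) pop <- population_estimate(pop)
  n <- c(central = pop$central, high = pop$high, low = pop$low)
  if (any(n <= 0)) stop("population must be positive", call. = FALSE)
  cost <- n * per_person$program_cost
  sav12 <- n * abs(per_person$incremental_12mo)
  savh <- n * abs(per_person$incremental_horizon)
  out <- data.frame(
    level = names(n),
    population = unname(n),
    intervention_cost_total = unname(cost),
    net_savings_12mo = unname(sav12),
    prac_delayed_12mo = unname(round_half_up(n * per_person$delta_cum_admission_12mo)),
    net_savings_horizon = unname(savh),
    prac_delayed_horizon = unname(round_half_up(n * per_person$delta_cum_admission_horizon)),
    intervention_cost_m = unname(round_half_up(cost / 1e6)),
    net_savings_12mo_m = unname(round_half_up(sav12 / 1e6)),
    net_savings_horizon_m = unname(round_half_up(savh / 1e6))
  )
  class(out) <- c("budget_impact_table", "data.frame")
  out
}
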