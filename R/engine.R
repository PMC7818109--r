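#' Per-cycle transition matrix for one arm
#'
#' Rows are from-states in the order community, prac, dead. Within a cycle,
#' death is applied first and admission applies to survivors, so the
#' Community row is `((1-q_c)(1-p_a), (1-q_c) p_a, q_c)`; P-RAC residents can
#' only die (`(0, 1-q_p, q_p)`); Death is absorbing.
#'
#' @param cycle Cycle index (1-based; the transition from cycle `cycle - 1`).
#' @param arm An `arm_parameters`.
#' @param mortality Mortality schedule from [build_mortality_schedule()].
#' @return A 3x3 row-stochastic matrix.
#' @export
build_transition_matrix <- function(cycle, arm, mortality) {
  stopifnot(cycle >= 1, cycle <= nrow(mortality))
  p_a <- arm$transition$monthly_admission_prob
  q_c <- mortality[cycle, "community"]
  q_p <- mortality[cycle, "prac"]
  m <- matrix(c(
    (1 - q_c) * (1 - p_a), (1 - q_c) * p_a, q_c,
    0,                     1 - q_p,         q_p,
    0,                     0,               1),
    nrow = 3, byrow = TRUE,
    dimnames = list(MODEL_STATES, MODEL_STATES))
  m
}

#' Run the cohort trace for one arm
#'
#' The whole cohort enters in the Community state; each cycle multiplies the
#' occupancy vector by that cycle's transition matrix. Also records the
#' per-cycle Community to P-RAC admission flow and the death flow, which feed
#' the budget-impact "admissions delayed" accounting.
#'
#' @param arm An `arm_parameters`.
#' @param spec The `model_spec` the arm belongs to.
#' @param mortality Optional precomputed mortality schedule.
#' @return A `cohort_trace`: data frame with columns `cycle` (0..horizon),
#'   `community`, `prac`, `dead`, `new_admissions`, `deaths`.
#' @export
run_cohort <- function(arm, spec, mortality = build_mortality_schedule(spec)) {
  t_cycles <- spec$time$horizon_cycles
  occ <- matrix(0, nrow = t_cycles + 1L, ncol = 3,
                dimnames = list(NULL, MODEL_STATES))
  occ[1L, ] <- c(1, 0, 0)
  admissions <- deaths <- numeric(t_cycles + 1L)
  for (t in seq_len(t_cycles)) {
    tm <- build_transition_matrix(t, arm, mortality)
    prev <- occ[t, ]
    occ[t + 1L, ] <- prev %*% tm
    admissions[t + 1L] <- prev[["community"]] * tm["community", "prac"]
    deaths[t + 1L] <- prev[["community"]] * tm["community", "dead"] +
      prev[["prac"]] * tm["prac", "dead"]
  }
  out <- data.frame(cycle = 0:t_cycles, occ, new_admissions = admissions,
                    deaths = deaths)
  class(out) <- c("cohort_trace", "data.frame")
  out
}

# Recurring monthly cost totals per state for an arm, including the P-RAC
# accommodation derived from the spec-level daily cost.
arm_state_monthly_costs <- function(arm, spec) {
  resources <- c(
    lapply(arm$costs[!vapply(arm$costs, `[[`, logical(1), "is_one_off")],
           function(rc) rc),
    list(resource_cost("prac_accommodation", "prac",
                       spec$prac_daily_cost * spec$days_per_month)))
  resources
}

#' Accrue discounted and undiscounted costs along a cohort trace
#'
#' Recurring costs use half-cycle-corrected (trapezoidal) state occupancy —
#' the average of cycle-start and cycle-end occupancy — discounted at the
#' cycle-end time. The P-RAC accommodation cost is `prac_daily_cost *
#' days_per_month` per person-month. The one-off program cost accrues once at
#' cycle 0 to the Community occupants, undiscounted and without half-cycle
#' correction; other `is_one_off` resources behave the same way.
#'
#' @param trace A `cohort_trace` produced under `spec` for `arm`.
#' @param arm The `arm_parameters` the trace was run with.
#' @param spec The `model_spec`.
#' @return A `cost_trace` list: `by_resource_discounted` /
#'   `by_resource_undiscounted` ((horizon+1) x resource matrices),
#'   `cycle_total_discounted`, `cumulative_discounted`, `total_discounted`,
#'   `total_undiscounted`, `resource_totals_discounted`.
#' @export
accrue_costs <- function(trace, arm, spec) {
  t_cycles <- spec$time$horizon_cycles
  if (nrow(trace) != t_cycles + 1L) {
    stop("trace length does not match spec horizon", call. = FALSE)
  }
  months_per_cycle <- spec$time$cycle_length_months
  hcc <- spec$time$half_cycle_correction
  recurring <- arm_state_monthly_costs(arm, spec)
  one_offs <- arm$costs[vapply(arm$costs, `[[`, logical(1), "is_one_off")]
  res_names <- c("program", vapply(one_offs, `[[`, character(1), "name"),
                 vapply(recurring, `[[`, character(1), "name"))
  n_res <- length(res_names)

  undisc <- disc <- matrix(0, nrow = t_cycles + 1L, ncol = n_res,
                           dimnames = list(NULL, res_names))
  # one-off accruals at cycle 0, to community occupants (occupancy 1 at entry)
  undisc[1L, "program"] <- arm$program_cost * trace$community[1L]
  for (rc in one_offs) undisc[1L, rc$name] <- rc$monthly_cost * trace$community[1L]
  disc[1L, ] <- undisc[1L, ]  # t = 0: discount factor 1, no HCC on one-offs

  t_idx <- seq_len(t_cycles)
  dfac <- discount_factor(spec$discount$annual_rate, t_idx * months_per_cycle)
  for (rc in recurring) {
    s <- rc$state
    occ_end <- trace[[s]][t_idx + 1L]
    w <- if (hcc) (trace[[s]][t_idx] + occ_end) / 2 else occ_end
    amount <- rc$monthly_cost * months_per_cycle * w
    undisc[t_idx + 1L, rc$name] <- amount
    disc[t_idx + 1L, rc$name] <- amount * dfac
  }

  cycle_disc <- rowSums(disc)
  out <- list(
    by_resource_discounted = disc,
    by_resource_undiscounted = undisc,
    cycle_total_discounted = cycle_disc,
    cumulative_discounted = cumsum(cycle_disc),
    total_discounted = sum(disc),
    total_undiscounted = sum(undisc),
    resource_totals_discounted = colSums(disc)
  )
  class(out) <- "cost_trace"
  out
}

#' Run one arm end to end
#'
#' @param spec A `model_spec`.
#' @param label Arm label.
#' @param mortality Optional precomputed mortality schedule.
#' @return List with the arm, its `cohort_trace` and `cost_trace`.
#' @export
run_arm <- function(spec, label, mortality = build_mortality_schedule(spec)) {
  arm <- spec_arm(spec, label)
  trace <- run_cohort(arm, spec, mortality)
  costs <- accrue_costs(trace, arm, spec)
  list(arm = arm, trace = trace, costs = costs)
}

#' Compare the intervention arm against standard care
#'
#' Computes the incremental discounted total (intervention minus standard
#' care; negative values are savings), the break-even cycle — the first cycle
#' at which the intervention's cumulative discounted cost no longer exceeds
#' standard care's (a tie counts) — and the per-resource incremental
#' breakdown.
#'
#' @param spec A `model_spec`.
#' @return A `comparison_result` list: `incremental_total`,
#'   `break_even_cycle` (NA if never), `break_even_month`, per-arm totals and
#'   cumulative series, `incremental_by_resource`, and both arm runs.
#' @export
compare_arms <- function(spec) {
  validate_model_spec(spec)
  mortality <- build_mortality_schedule(spec)
  int <- run_arm(spec, "intervention", mortality)
  sc <- run_arm(spec, "standard_care", mortality)
  cum_int <- int$costs$cumulative_discounted
  cum_sc <- sc$costs$cumulative_discounted
  t_cycles <- spec$time$horizon_cycles
  be <- which(cum_int[-1L] <= cum_sc[-1L])[1L]  # cycles 1..horizon
  res_names <- union(names(int$costs$resource_totals_discounted),
                     names(sc$costs$resource_totals_discounted))
  get0n <- function(x, nm) ifelse(nm %in% names(x), x[nm], 0)
  inc_res <- get0n(int$costs$resource_totals_discounted, res_names) -
    get0n(sc$costs$resource_totals_discounted, res_names)
  names(inc_res) <- res_names
  out <- list(
    incremental_total = int$costs$total_discounted - sc$costs$total_discounted,
    break_even_cycle = if (is.na(be)) NA_integer_ else as.integer(be),
    break_even_month = if (is.na(be)) NA_integer_
      else as.integer(be) * spec$time$cycle_length_months,
    intervention_total = int$costs$total_discounted,
    standard_care_total = sc$costs$total_discounted,
    cumulative_intervention = cum_int,
    cumulative_standard_care = cum_sc,
    incremental_by_resource = inc_res,
    intervention = int,
    standard_care = sc
  )
  class(out) <- "comparison_result"
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Two-arm Markov cohort cost comparison (discounted 2018 AUD per person)\n")
  cat(sprintf("  intervention total:  %12.0f\n", x$intervention_total))
  cat(sprintf("  standard care total: %12.0f\n", x$standard_care_total))
  cat(sprintf("  incremental:         %12.0f  (negative = savings)\n",
              x$incremental_total))
  if (is.na(x$break_even_cycle)) {
    cat("  break-even: never within the horizon\n")
  } else {
    cat(sprintf("  break-even: cycle %d (month %d)\n",
                x$break_even_cycle, x$break_even_month))
  }
  invisible(x)
}
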