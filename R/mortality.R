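#' Monthly death probability at an age, adjusted for excess mortality
#'
#' Converts the annual life-table probability to a monthly probability on the
#' hazard (log-survival) scale, applying the dementia relative risk and a
#' per-state hazard multiplier:
#' `q_month = 1 - exp(log(1 - q_annual) * rr * state_multiplier / 12)`.
#' Applying multipliers on the hazard scale keeps the result in `[0, 1]` for
#' any relative risk, which a probability-scale multiplication does not.
#' Ages at or beyond the life table's `max_age` return 1.
#'
#' @param age Age in years (fractional allowed; the floor-age row is used).
#' @param life_table A [life_table()].
#' @param rr Dementia relative risk on the mortality hazard (> 0).
#' @param state_multiplier Per-state hazard multiplier (> 0).
#' @return Monthly death probability in `[0, 1]`.
#' @export
monthly_death_prob <- function(age, life_table, rr = 1, state_multiplier = 1) {
  stopifnot(rr > 0, state_multiplier > 0)
  q_annual <- life_table_lookup(life_table, age)
  ifelse(q_annual >= 1, 1,
         pmin(1, 1 - exp(log(1 - q_annual) * rr * state_multiplier / 12)))
}

#' Build the per-cycle, per-state mortality schedule for a spec
#'
#' One monthly death probability per (cycle, alive state). The cohort ages by
#' one month per cycle; the probability governing cycle `t` (the transition
#' from cycle `t-1` to `t`) uses the cohort age at the start of that cycle.
#' Mortality is shared by both model arms.
#'
#' @param spec A `model_spec`.
#' @return A `horizon_cycles` x 2 matrix with columns `community` and `prac`;
#'   row `t` is the death probability during cycle `t`.
#' @export
build_mortality_schedule <- function(spec) {
  validate_model_spec(spec)
  t_cycles <- spec$time$horizon_cycles
  months_per_cycle <- spec$time$cycle_length_months
  ages <- spec$cohort_start_age + (seq_len(t_cycles) - 1L) * months_per_cycle / 12
  mult <- spec$mortality$state_hazard_multipliers
  rr <- spec$mortality$dementia_relative_risk
  sched <- cbind(
    community = monthly_death_prob(ages, spec$life_table, rr, mult[["community"]]),
    prac = monthly_death_prob(ages, spec$life_table, rr, mult[["prac"]])
  )
  # a cycle longer than a month compounds the monthly probability
  if (months_per_cycle != 1L) sched <- 1 - (1 - sched)^months_per_cycle
  sched
}
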