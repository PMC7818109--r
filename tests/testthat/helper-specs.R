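# Shared fixtures: controlled specs with known analytic behaviour, randomized
# valid specs for property tests, and an independent Fisher enumeration oracle.

# A spec with a flat life table (constant annual death probability), so the
# trace has closed-form occupancies when mortality is zero.
flat_spec <- function(q_annual = 0, p_sc = 0.05, p_int = 0.02,
                      horizon = 60L, annual_rate = 0.05, hcc = TRUE,
                      program_cost = 3755, community_cost = 0, prac_extra_cost = 0,
                      prac_daily_cost = 237, rr = 1,
                      state_mult = c(community = 1, prac = 1), start_age = 70) {
  ages <- 60:120
  lt <- life_table(ages, rep(q_annual, length(ages)), max_age = 121L)
  mk_costs <- function() {
    costs <- list()
    if (community_cost > 0) {
      costs <- c(costs, list(resource_cost("community_bundle", "community",
                                           community_cost)))
    }
    if (prac_extra_cost > 0) {
      costs <- c(costs, list(resource_cost("prac_bundle", "prac", prac_extra_cost)))
    }
    costs
  }
  model_spec(
    time = time_settings(1L, horizon, hcc),
    discount = discount_settings(annual_rate),
    life_table = lt,
    mortality = mortality_model(rr, state_mult),
    cohort_start_age = start_age,
    arms = list(
      arm_parameters("intervention", transition_inputs(p_int), mk_costs(),
                     program_cost),
      arm_parameters("standard_care", transition_inputs(p_sc), mk_costs(), 0)),
    prac_daily_cost = prac_daily_cost)
}

# Randomized but always-valid spec for property tests and oracle equivalence.
random_valid_spec <- function(seed) {
  set.seed(seed)
  p_sc <- stats::runif(1, 0.02, 0.08)
  p_int <- stats::runif(1, 0.005, p_sc)
  consts <- synthetic_constants()
  lt <- make_synthetic_life_table(
    gompertz_params(a = stats::runif(1, 2e-5, 1e-4),
                    b = stats::runif(1, 0.07, 0.11), 60L, 110L))
  mk_costs <- function() list(
    resource_cost("hospitalisation", "community", stats::runif(1, 100, 600)),
    resource_cost("respite_rac", "community", stats::runif(1, 50, 300)),
    resource_cost("home_care_package", "community", stats::runif(1, 500, 2000)),
    resource_cost("hospitalisation_prac", "prac", stats::runif(1, 50, 300)),
    resource_cost("pharmaceuticals", "prac", stats::runif(1, 50, 200)))
  model_spec(
    time = time_settings(1L, sample(24:60, 1), TRUE),
    discount = discount_settings(stats::runif(1, 0, 0.08)),
    life_table = lt,
    mortality = mortality_model(stats::runif(1, 1, 3),
                                c(community = 1, prac = stats::runif(1, 1, 2))),
    cohort_start_age = stats::runif(1, 70, 85),
    arms = list(
      arm_parameters("intervention", transition_inputs(p_int), mk_costs(),
                     stats::runif(1, 1000, 5000)),
      arm_parameters("standard_care", transition_inputs(p_sc), mk_costs(), 0)),
    prac_daily_cost = stats::runif(1, 150, 300))
}

# Critical value for K simultaneous Monte-Carlo z comparisons holding the
# family-wise false-alarm rate at the single-comparison 3-sigma level
# (two-sided Bonferroni). K = 1 recovers 3.
mc_z_crit <- function(k) {
  alpha <- 2 * stats::pnorm(-3)
  stats::qnorm(1 - alpha / (2 * k))
}

# Independent Fisher oracle: full enumeration over all 2x2 tables with the
# observed margins, probabilities from binomial coefficients only.
enum_fisher <- function(x1, n1, x2, n2, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  k <- x1 + x2
  support <- max(0, k - n2):min(n1, k)
  probs <- vapply(support, function(a) {
    choose(n1, a) * choose(n2, k - a) / choose(n1 + n2, k)
  }, numeric(1))
  if (sidedness == "one") {
    expected <- k * n1 / (n1 + n2)
    if (x1 <= expected) sum(probs[support <= x1]) else sum(probs[support >= x1])
  } else {
    p_obs <- probs[match(x1, support)]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}
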