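#' Synthetic fill-in constants
#'
#' The published description of the two programs prints the program costs
#' ($3,755 dyadic training, $1,834 frailty intervention), the P-RAC daily
#' cost ($237), the monthly admission probabilities (0.05/0.02 and
#' 0.03/0.01), the 5% annual discount rate and the 5-year monthly-cycle
#' horizon. Everything else a runnable model needs — cohort start ages, the
#' dementia mortality relative risk, the life table and community/P-RAC
#' resource-use costs — lives in supplementary tables and is represented here
#' by documented SYNTHETIC values, centralised so no test mistakes them for
#' published inputs. All costs are monthly 2018 AUD.
#'
#' @return Named list of the synthetic defaults.
#' @export
synthetic_constants <- function() {
  list(
    # SYNTHETIC: start ages (plausible for the two study populations)
    cohort_start_age = c(GTSAH = 78, FIT = 83),
    # SYNTHETIC: dementia mortality relative risk on the hazard scale
    dementia_relative_risk = 2.0,
    # SYNTHETIC: Gompertz life-table parameters (per-year baseline and shape)
    gompertz = list(a = 5e-5, b = 0.095, age_min = 60L, age_max = 110L),
    # SYNTHETIC: community-state monthly resource costs
    community_costs = c(hospitalisation = 400, respite_rac = 150,
                        home_care_package = 1200, gp = 60, allied_health = 80),
    # SYNTHETIC: P-RAC-state monthly resource costs other than accommodation
    prac_costs = c(hospitalisation_prac = 150, clinician_attendances = 100,
                   pharmaceuticals = 120)
  )
}

#' Gompertz mortality parameters
#'
#' @param a Baseline annual hazard at age 0 (> 0).
#' @param b Shape: log-hazard increase per year of age (> 0 for a table that
#'   increases with age).
#' @param age_min,age_max Age range (years) to tabulate.
#' @return A `gompertz_params` object.
#' @export
gompertz_params <- function(a = 5e-5, b = 0.095, age_min = 60L, age_max = 110L) {
  stopifnot(a > 0, b >= 0, age_min <= age_max)
  structure(list(a = a, b = b, age_min = as.integer(age_min),
                 age_max = as.integer(age_max)),
            class = "gompertz_params")
}

#' Build a synthetic Gompertz life table
#'
#' Annual death probability `q(age) = 1 - exp(-a * exp(b * age))`, tabulated
#' per integer age. Probabilities reaching 1 inside the range are capped just
#' below 1 with a warning (the `max_age` rule handles certain death).
#'
#' @param params A [gompertz_params()].
#' @return A [life_table()] with `max_age = age_max + 1`.
#' @export
make_synthetic_life_table <- function(params = gompertz_params()) {
  stopifnot(inherits(params, "gompertz_params"))
  ages <- params$age_min:params$age_max
  q <- 1 - exp(-params$a * exp(params$b * ages))
  if (any(q >= 1)) {
    warning("Gompertz parameters give q >= 1 inside the age range; capping")
    q <- pmin(q, 1 - 1e-12)
  }
  life_table(ages, q, max_age = params$age_max + 1L)
}

default_arm <- function(label, p_admission, program_cost, consts) {
  costs <- c(
    mapply(function(nm, c_) resource_cost(nm, "community", c_),
           names(consts$community_costs), consts$community_costs,
           SIMPLIFY = FALSE, USE.NAMES = FALSE),
    mapply(function(nm, c_) resource_cost(nm, "prac", c_),
           names(consts$prac_costs), consts$prac_costs,
           SIMPLIFY = FALSE, USE.NAMES = FALSE))
  arm_parameters(label, transition_inputs(p_admission), costs, program_cost)
}

#' Default model specification for either program
#'
#' Builds a fully populated, deterministic two-arm spec anchored to every
#' printed model input — program costs ($3,755 dyad / $1,834), $237/day
#' P-RAC accommodation, monthly admission probabilities (0.05 standard care
#' vs 0.02 intervention for the dyadic training model; 0.03 vs 0.01 for the
#' frailty-intervention model), 5% annual discounting, 60 monthly cycles —
#' with [synthetic_constants()] filling in the unpublished inputs.
#'
#' @param program "GTSAH" (dyadic carer training) or "FIT" (frailty
#'   intervention).
#' @return A validated `model_spec`.
#' @export
make_default_spec <- function(program = c("GTSAH", "FIT")) {
  program <- match.arg(program)
  consts <- synthetic_constants()
  probs <- switch(program,
                  GTSAH = c(sc = 0.05, int = 0.02),
                  FIT = c(sc = 0.03, int = 0.01))
  program_cost <- switch(program, GTSAH = 3755, FIT = 1834)
  model_spec(
    time = time_settings(1L, 60L, TRUE),
    discount = discount_settings(0.05),
    life_table = make_synthetic_life_table(do.call(gompertz_params, consts$gompertz)),
    mortality = mortality_model(consts$dementia_relative_risk,
                                c(community = 1, prac = 1)),
    cohort_start_age = consts$cohort_start_age[[program]],
    arms = list(
      default_arm("intervention", probs[["int"]], program_cost, consts),
      default_arm("standard_care", probs[["sc"]], 0, consts)),
    prac_daily_cost = 237,
    days_per_month = 365.25 / 12)
}

#' Individual-level microsimulation of one arm
#'
#' Simulates `n` independent individuals walking the same per-cycle
#' transition matrices the cohort engine uses, accruing the same
#' half-cycle-corrected discounted costs. By the law of large numbers the
#' mean occupancy, mean cumulative admissions and mean discounted cost
#' converge to the cohort-trace values, which makes this the package's
#' independent validation oracle for the deterministic engine.
#'
#' @param spec A `model_spec`.
#' @param arm_label Arm to simulate.
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed; all randomness flows from it (a local RNG state,
#'   the global RNG is untouched).
#' @param keep_paths Store the full per-individual state paths? Defaults to
#'   TRUE only for small `n`.
#' @return A `simulated_cohort` list: `n`, `seed`, `occupancy` (mean
#'   occupancy matrix, cycles 0..T), `mean_cost`, `se_cost`,
#'   `mean_cum_admissions` (per cycle), `admission_cycle` / `death_cycle`
#'   (per individual, NA if never), `cost` (per individual), and `paths`
#'   when kept.
#' @export
microsimulate <- function(spec, arm_label, n, seed, keep_paths = n <= 5000) {
  validate_model_spec(spec)
  stopifnot(n >= 1)
  arm <- spec_arm(spec, arm_label)
  mortality <- build_mortality_schedule(spec)
  t_cycles <- spec$time$horizon_cycles
  months_per_cycle <- spec$time$cycle_length_months
  hcc <- spec$time$half_cycle_correction

  recurring <- arm_state_monthly_costs(arm, spec)
  state_cost <- c(community = 0, prac = 0)
  for (rc in recurring) {
    state_cost[[rc$state]] <- state_cost[[rc$state]] + rc$monthly_cost
  }
  one_off_total <- arm$program_cost +
    sum(vapply(arm$costs[vapply(arm$costs, `[[`, logical(1), "is_one_off")],
               `[[`, numeric(1), "monthly_cost"))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  state <- rep.int(1L, n)  # 1 community, 2 prac, 3 dead
  cost <- rep.int(one_off_total, n)
  occupancy <- matrix(0, nrow = t_cycles + 1L, ncol = 3,
                      dimnames = list(NULL, MODEL_STATES))
  occupancy[1L, ] <- c(1, 0, 0)
  cum_adm <- numeric(t_cycles + 1L)
  admission_cycle <- death_cycle <- rep(NA_integer_, n)
  paths <- if (keep_paths) matrix(1L, nrow = n, ncol = t_cycles + 1L) else NULL
  p_a <- arm$transition$monthly_admission_prob
  adm_total <- 0

  for (t in seq_len(t_cycles)) {
    q <- mortality[t, ]
    if (months_per_cycle != 1L) q <- 1 - (1 - q)^months_per_cycle
    prev <- state
    in_comm <- prev == 1L
    in_prac <- prev == 2L
    u_death <- stats::runif(n)
    died <- (in_comm & u_death < q[["community"]]) |
      (in_prac & u_death < q[["prac"]])
    admitted <- in_comm & !died & (stats::runif(n) < p_a)
    state[died] <- 3L
    state[admitted] <- 2L
    admission_cycle[admitted] <- t
    death_cycle[died & is.na(death_cycle)] <- t
    adm_total <- adm_total + sum(admitted) / n
    cum_adm[t + 1L] <- adm_total
    occupancy[t + 1L, ] <- tabulate(state, 3L) / n
    if (keep_paths) paths[, t + 1L] <- state

    dfac <- discount_factor(spec$discount$annual_rate, t * months_per_cycle)
    w_comm <- if (hcc) ((prev == 1L) + (state == 1L)) / 2 else (state == 1L)
    w_prac <- if (hcc) ((prev == 2L) + (state == 2L)) / 2 else (state == 2L)
    cost <- cost + dfac * months_per_cycle *
      (state_cost[["community"]] * w_comm + state_cost[["prac"]] * w_prac)
  }

  structure(list(n = n, seed = seed, arm_label = arm$label,
                 occupancy = occupancy, mean_cost = mean(cost),
                 se_cost = stats::sd(cost) / sqrt(n),
                 mean_cum_admissions = cum_adm,
                 admission_cycle = admission_cycle, death_cycle = death_cycle,
                 cost = cost, paths = paths),
            class = "simulated_cohort")
}

#' Synthetic per-participant subgroup records
#'
#' Draws per-arm binary 12-month P-RAC admissions and total care days
#' matching target first and second moments. Care days follow a
#' zero-inflated lognormal: zero with probability `1 - p12`, lognormal
#' otherwise, with the lognormal moments solved so the overall mean and SD
#' match the targets in expectation.
#'
#' @param n_sc,n_int Arm sizes (defaults 29 and 19).
#' @param p12_sc,p12_int 12-month admission probabilities (defaults 9/29 and
#'   2/19).
#' @param care_day_moments List with elements `sc` and `intervention`, each
#'   `c(mean=, sd=)` of total care days (defaults 54/99 and 15/64).
#' @param seed Integer seed.
#' @return Data frame with columns `arm`, `admitted` (0/1), `care_days`.
#' @export
make_subgroup_sample <- function(n_sc = 29L, n_int = 19L,
                                 p12_sc = 9 / 29, p12_int = 2 / 19,
                                 care_day_moments = list(
                                   sc = c(mean = 54, sd = 99),
                                   intervention = c(mean = 15, sd = 64)),
                                 seed = 1L) {
  stopifnot(p12_sc >= 0, p12_sc <= 1, p12_int >= 0, p12_int <= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  draw_arm <- function(arm, n, p12, mom) {
    admitted <- as.integer(stats::runif(n) < p12)
    care <- numeric(n)
    m <- mom[["mean"]]
    s <- mom[["sd"]]
    if (m > 0) {
      if (p12 <= 0) stop("positive mean care days with zero admission probability",
                         call. = FALSE)
      mu_pos <- m / p12                       # mean among the admitted
      ex2_pos <- (s^2 + m^2) / p12            # second moment among the admitted
      var_pos <- ex2_pos - mu_pos^2
      if (var_pos < 0) {
        stop("impossible care-day moments: need p12 >= mean^2 / (sd^2 + mean^2)",
             call. = FALSE)
      }
      sdlog2 <- log(1 + var_pos / mu_pos^2)
      meanlog <- log(mu_pos) - sdlog2 / 2
      k <- sum(admitted)
      if (k > 0) {
        care[admitted == 1L] <- stats::rlnorm(k, meanlog, sqrt(sdlog2))
      }
    }
    data.frame(arm = arm, admitted = admitted, care_days = care)
  }
  rbind(draw_arm("standard_care", n_sc, p12_sc, care_day_moments$sc),
        draw_arm("intervention", n_int, p12_int, care_day_moments$intervention))
}
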