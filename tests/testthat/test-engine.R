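test_that("transition matrices compose death-first admission-to-survivors", {
  spec <- flat_spec(q_annual = 0)
  sched <- build_mortality_schedule(spec)
  m <- build_transition_matrix(1, spec_arm(spec, "standard_care"), sched)
  expect_equal(unname(m["community", ]), c(0.95, 0.05, 0))
  expect_equal(unname(m["dead", ]), c(0, 0, 1))
  expect_equal(unname(m["prac", "community"]), 0)

  # with q = 0.01, p = 0.05: (0.9405, 0.0495, 0.01)
  arm <- arm_parameters("standard_care", transition_inputs(0.05))
  sched2 <- matrix(0.01, nrow = 1, ncol = 2,
                   dimnames = list(NULL, c("community", "prac")))
  m2 <- build_transition_matrix(1, arm, sched2)
  expect_equal(unname(m2["community", ]), c(0.9405, 0.0495, 0.01), tolerance = 1e-12)

  # zero admission gives an identity community row when mortality is off
  arm0 <- arm_parameters("intervention", transition_inputs(0))
  m3 <- build_transition_matrix(1, arm0, sched)
  expect_equal(unname(m3["community", ]), c(1, 0, 0))
})

test_that("cohort traces start at (1,0,0), conserve occupancy and match closed forms", {
  spec <- flat_spec(q_annual = 0, p_sc = 0.05)
  trace <- run_cohort(spec_arm(spec, "standard_care"), spec)
  expect_equal(nrow(trace), 61L)
  expect_equal(unname(unlist(trace[1, c("community", "prac", "dead")])), c(1, 0, 0))
  expect_equal(trace$community[13], 0.95^12, tolerance = 1e-12)
  expect_equal(trace$community[13], 0.5404, tolerance = 1e-4)

  # occupancy conservation and flow bounds across randomized specs
  for (seed in 1:8) {
    s <- random_valid_spec(seed)
    for (label in c("intervention", "standard_care")) {
      tr <- run_cohort(spec_arm(s, label), s)
      expect_true(all(abs(rowSums(tr[, c("community", "prac", "dead")]) - 1) < 1e-9))
      expect_true(all(tr$new_admissions[-1] <= tr$community[-nrow(tr)] + 1e-12))
      expect_true(all(diff(tr$dead) >= -1e-12))  # death is absorbing
    }
  }
})

test_that("cost accrual follows HCC weighting, cycle-end discounting and the daily P-RAC cost", {
  # single recurring community cost, occupancy stays 1, no discounting
  spec <- flat_spec(q_annual = 0, p_sc = 0, p_int = 0, horizon = 1L,
                    annual_rate = 0, program_cost = 0, community_cost = 100)
  run <- run_arm(spec, "intervention")
  expect_equal(run$costs$total_discounted, 100, tolerance = 1e-12)

  # all costs zero: total zero
  z <- flat_spec(q_annual = 0, program_cost = 0, prac_daily_cost = 0)
  expect_equal(run_arm(z, "intervention")$costs$total_discounted, 0)

  # program cost only accrues once, undiscounted, at any discount rate
  for (r in c(0, 0.05, 0.2)) {
    s <- flat_spec(q_annual = 0, p_sc = 0, p_int = 0, annual_rate = r,
                   program_cost = 3755, prac_daily_cost = 0)
    expect_equal(run_arm(s, "intervention")$costs$total_discounted, 3755,
                 tolerance = 1e-9)
  }

  # P-RAC accommodation = daily cost x days per month; everyone admitted at
  # cycle 1 with certainty-free mortality accrues half a month (HCC) then full
  s <- flat_spec(q_annual = 0, p_sc = 1, p_int = 1, horizon = 2L,
                 annual_rate = 0, program_cost = 0)
  run <- run_arm(s, "standard_care")
  monthly <- 237 * 365.25 / 12
  expect_equal(unname(run$costs$by_resource_discounted[2, "prac_accommodation"]),
               monthly / 2, tolerance = 1e-9)
  expect_equal(unname(run$costs$by_resource_discounted[3, "prac_accommodation"]),
               monthly, tolerance = 1e-9)

  # discounted totals never exceed undiscounted; cumulative series non-decreasing
  for (seed in 1:5) {
    sp <- random_valid_spec(seed)
    cr <- run_arm(sp, "standard_care")$costs
    expect_lte(cr$total_discounted, cr$total_undiscounted + 1e-9)
    expect_true(all(diff(cr$cumulative_discounted) >= -1e-9))
  }
})

test_that("a cohort forced into the Dead state accrues nothing", {
  spec <- flat_spec(q_annual = 0.999999, p_sc = 0.05, horizon = 24L,
                    program_cost = 0, community_cost = 500, prac_extra_cost = 200)
  spec$life_table <- life_table(60:120, rep(1, 61), max_age = 61L)
  spec <- validate_model_spec(spec)  # start age 70 >= max_age: death certain
  run <- run_arm(spec, "standard_care")
  expect_equal(run$trace$dead[-1], rep(1, 24))
  # only the first cycle's half-membership (HCC) can accrue
  expect_true(all(run$costs$cycle_total_discounted[-(1:2)] == 0))
})

test_that("arm comparison finds incremental totals and break-even cycles", {
  # identical arms, no program cost: tie from cycle 1
  s <- flat_spec(q_annual = 0.05, p_sc = 0.03, p_int = 0.03, program_cost = 0,
                 community_cost = 300)
  cmp <- compare_arms(s)
  expect_equal(cmp$incremental_total, 0, tolerance = 1e-9)
  expect_equal(cmp$break_even_cycle, 1L)

  # program cost with identical transitions is never recouped
  s2 <- flat_spec(q_annual = 0.05, p_sc = 0.03, p_int = 0.03, program_cost = 1000,
                  community_cost = 300)
  cmp2 <- compare_arms(s2)
  expect_true(is.na(cmp2$break_even_cycle))
  expect_equal(cmp2$incremental_total, 1000, tolerance = 1e-6)

  # lower admission probability plus a program cost: break-even exists, >= 1
  s3 <- flat_spec(q_annual = 0.02, p_sc = 0.05, p_int = 0.02, program_cost = 3755)
  cmp3 <- compare_arms(s3)
  expect_false(is.na(cmp3$break_even_cycle))
  expect_gte(cmp3$break_even_cycle, 1L)
  expect_lt(cmp3$incremental_total, 0)
  # before break-even the intervention is dearer, at break-even it is not
  b <- cmp3$break_even_cycle
  expect_true(all(cmp3$cumulative_intervention[2:b] >
                    cmp3$cumulative_standard_care[2:b]))
  expect_lte(cmp3$cumulative_intervention[b + 1],
             cmp3$cumulative_standard_care[b + 1])
})

test_that("engine occupancy, admissions and costs match the microsimulation oracle", {
  spec <- random_valid_spec(101)
  n <- 20000L
  sim <- microsimulate(spec, "standard_care", n, seed = 101, keep_paths = FALSE)
  run <- run_arm(spec, "standard_care")
  tt <- spec$time$horizon_cycles + 1L
  z_crit <- mc_z_crit(4)  # four simultaneous Monte-Carlo comparisons
  for (s in c("community", "prac")) {
    p_hat <- sim$occupancy[tt, s]
    se <- sqrt(max(p_hat * (1 - p_hat), 1e-12) / n)
    expect_lt(abs(run$trace[[s]][tt] - p_hat), z_crit * se + 1e-9)
  }
  expect_lt(abs(run$costs$total_discounted - sim$mean_cost),
            z_crit * sim$se_cost)
  adm <- cumsum(run$trace$new_admissions)[tt]
  se_adm <- sqrt(adm * (1 - min(adm, 0.999)) / n)
  expect_lt(abs(adm - sim$mean_cum_admissions[tt]), z_crit * se_adm + 1e-9)
})
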