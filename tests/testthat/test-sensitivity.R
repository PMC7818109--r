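test_that("apply_scenario is pure, validates, and hits the intended parameters", {
  spec <- make_default_spec("GTSAH")
  before <- spec
  zero_disc <- apply_scenario(spec, scenario_transform("Discount rate down to 0%",
    list(list(path = "discount.annual_rate", op = "set", value = 0))))
  expect_equal(zero_disc$discount$annual_rate, 0)
  expect_equal(spec, before)  # input untouched

  ident <- apply_scenario(spec, scenario_transform("identity",
    list(list(path = "prac_daily_cost", op = "multiply", value = 1))))
  expect_equal(ident, spec)

  expect_error(apply_scenario(spec, scenario_transform("bad path",
    list(list(path = "no.such.knob", op = "set", value = 1)))), "resolve")
  expect_error(apply_scenario(spec, scenario_transform("bad horizon",
    list(list(path = "time.horizon_cycles", op = "set", value = 0)))),
    "horizon_cycles")
})

test_that("the admission-probability-difference lever holds standard care fixed", {
  spec <- make_default_spec("GTSAH")  # p_sc 0.05, p_int 0.02
  halved <- apply_scenario(spec, scenario_transform("difference halved",
    list(list(path = "admission_prob_difference", op = "multiply", value = 0.5))))
  expect_equal(spec_arm(halved, "intervention")$transition$monthly_admission_prob,
               0.035, tolerance = 1e-12)
  expect_equal(spec_arm(halved, "standard_care")$transition$monthly_admission_prob,
               0.05)
  # doubling the 0.03 gap would give 0.05 - 0.06 < 0: clamped to 0
  doubled <- apply_scenario(spec, scenario_transform("difference doubled",
    list(list(path = "admission_prob_difference", op = "multiply", value = 2))))
  expect_equal(spec_arm(doubled, "intervention")$transition$monthly_admission_prob, 0)
  expect_equal(spec_arm(doubled, "standard_care")$transition$monthly_admission_prob,
               0.05)
})

test_that("scenario transforms compose sequentially (multivariate rows)", {
  spec <- make_default_spec("FIT")
  combo <- apply_scenario(spec, scenario_transform("1 y + difference halved",
    list(list(path = "time.horizon_cycles", op = "set", value = 12),
         list(path = "admission_prob_difference", op = "multiply", value = 0.5))))
  step1 <- apply_scenario(spec, scenario_transform("1 y",
    list(list(path = "time.horizon_cycles", op = "set", value = 12))))
  step2 <- apply_scenario(step1, scenario_transform("difference halved",
    list(list(path = "admission_prob_difference", op = "multiply", value = 0.5))))
  expect_equal(combo, step2)
})

test_that("the packaged scenario file loads 25 scenarios and the suite adds a base row", {
  transforms <- default_scenarios()
  expect_length(transforms, 25)
  spec <- make_default_spec("GTSAH")
  empty <- run_sensitivity_suite(spec, list())
  expect_equal(nrow(empty), 1L)
  expect_equal(empty$scenario, "Base case")
  expect_equal(empty$incremental, empty$intervention_total - empty$standard_care_total,
               tolerance = 1e-6)
})

test_that("the full scenario suite keeps every intervention cost-saving on both default specs", {
  for (program in c("GTSAH", "FIT")) {
    spec <- make_default_spec(program)
    tab <- run_sensitivity_suite(spec, default_scenarios())
    expect_equal(nrow(tab), 26L)
    expect_true(all(tab$incremental < 0))
    expect_equal(tab$incremental, tab$intervention_total - tab$standard_care_total,
                 tolerance = 1e-6)
    get_inc <- function(nm) tab$incremental[tab$scenario == nm]
    base <- tab$incremental[tab$scenario == "Base case"]
    # savings grow with P-RAC cost, horizon and the probability difference
    expect_lt(get_inc("P-RAC costs doubled"), base)
    expect_lt(get_inc("Time horizon up to 7 y"), base)
    expect_lt(get_inc(
      "Difference in prob of entry to P-RAC between int and SC arms doubled"), base)
    # and shrink with their halved counterparts and a higher discount rate
    expect_gt(get_inc("P-RAC costs halved"), base)
    expect_gt(get_inc("Time horizon down to 1 y"), base)
    expect_gt(get_inc(
      "Difference in prob of entry to P-RAC between int and SC arms halved"), base)
    expect_gt(get_inc("Discount rate up to 10%"), base)
    expect_lt(get_inc("Discount rate down to 0%"), base)
    # the 1-year horizon row has far smaller magnitude than the base case
    expect_lt(abs(get_inc("Time horizon down to 1 y")), abs(base))
  }
})

test_that("intervention-cost scenarios shift the intervention total by exactly half/full program cost", {
  for (program in c("GTSAH", "FIT")) {
    spec <- make_default_spec(program)
    pc <- spec_arm(spec, "intervention")$program_cost
    tab <- run_sensitivity_suite(spec, default_scenarios())
    base_int <- tab$intervention_total[tab$scenario == "Base case"]
    base_sc <- tab$standard_care_total[tab$scenario == "Base case"]
    halved <- tab[tab$scenario == "Intervention costs halved", ]
    doubled <- tab[tab$scenario == "Intervention costs doubled", ]
    expect_equal(halved$intervention_total, base_int - pc / 2, tolerance = 1e-9)
    expect_equal(doubled$intervention_total, base_int + pc, tolerance = 1e-9)
    expect_equal(halved$standard_care_total, base_sc, tolerance = 1e-12)
    expect_equal(doubled$standard_care_total, base_sc, tolerance = 1e-12)
  }
})

test_that("removing discounting never lowers either arm's total", {
  for (seed in 1:5) {
    spec <- random_valid_spec(seed)
    undisc <- apply_scenario(spec, scenario_transform("no discounting",
      list(list(path = "discount.annual_rate", op = "set", value = 0))))
    cmp <- compare_arms(spec)
    cmp0 <- compare_arms(undisc)
    expect_gte(cmp0$intervention_total, cmp$intervention_total - 1e-9)
    expect_gte(cmp0$standard_care_total, cmp$standard_care_total - 1e-9)
  }
})

test_that("doubling the P-RAC cost deepens negative incrementals on random saving specs", {
  for (seed in 1:5) {
    spec <- random_valid_spec(seed)
    cmp <- compare_arms(spec)
    if (cmp$incremental_total >= 0) next  # program cost too high to recoup
    doubled <- apply_scenario(spec, scenario_transform("P-RAC doubled",
      list(list(path = "prac_daily_cost", op = "multiply", value = 2))))
    expect_lt(compare_arms(doubled)$incremental_total, cmp$incremental_total)
  }
})
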