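ref <- reference_base_case()
intv_tal <- state_tallies(ref$intervention$life_days, 85 / 321)
ctrl_tal <- state_tallies(ref$control$life_days, 102 / 324)

test_that("cost accrual reproduces the reported base-case cells", {
  bi <- accrue_costs(intv_tal, cost_inputs(), "intervention")
  # inpatient nutrition: 5 SF on every in-hospital day
  expect_equal(bi$nutrition_inpatient, (123.84 + 10.09 + 1.88) * 5)
  expect_equal(round(bi$nutrition_inpatient), 679)
  expect_equal(bi$nutrition_outpatient, 0.2 * 18.77 * 5)
  expect_equal(bi$ward, 123.84 * 1650)
  # reported cells carry rounded life days; agreement within 0.2%
  for (k in c("ward", "icu", "complication")) {
    expect_lt(abs(bi[[k]] - ref$intervention$costs[[k]]) /
                ref$intervention$costs[[k]], 0.002)
  }

  bc <- accrue_costs(ctrl_tal, cost_inputs(), "control")
  expect_equal(bc$nutrition_inpatient, 0)
  expect_equal(bc$nutrition_outpatient, 0)
  for (k in c("ward", "icu", "complication")) {
    expect_lt(abs(bc[[k]] - ref$control$costs[[k]]) /
                ref$control$costs[[k]], 0.002)
  }

  z <- accrue_costs(state_tallies(c(0, 0, 0, 0), 0), cost_inputs(),
                    "intervention")
  expect_equal(z$total, 0)

  # breakdown totals are component sums
  expect_equal(bi$total,
               bi$nutrition_inpatient + bi$ward + bi$icu +
                 bi$complication + bi$nutrition_outpatient)
})

test_that("cost accrual is linear in the unit costs", {
  ci <- cost_inputs()
  ci2 <- cost_inputs(10, 10, 3300, 9308, 3026, 0.2)
  b1 <- accrue_costs(intv_tal, ci, "intervention")
  b2 <- accrue_costs(intv_tal, ci2, "intervention")
  for (k in c("nutrition_inpatient", "ward", "icu", "complication",
              "nutrition_outpatient", "total")) {
    expect_equal(b2[[k]], 2 * b1[[k]])
  }
})

test_that("utility accrual applies daily weights, death contributing nothing", {
  u <- accrue_utilities(intv_tal, utility_weights())
  expect_equal(round(u$per_state[["WARD"]], 2), 0.25)
  expect_equal(round(u$total, 2), 0.31)
  expect_equal(accrue_utilities(intv_tal, utility_weights(0, 0, 0, 0))$total, 0)
  w1 <- utility_weights(1, 1, 1, 1)
  expect_equal(accrue_utilities(intv_tal, w1)$total, sum(intv_tal$life_days))
  expect_error(utility_weights(WARD = 1.2), "\\[0, 1\\]")
})

test_that("icer classifies the cost-effectiveness plane and flags zero effects", {
  r <- icer(15159, 5.77)
  expect_equal(r$value, 15159 / 5.77)
  expect_equal(r$quadrant, "trade-off")

  r0 <- icer(0, 5)
  expect_equal(r0$value, 0)
  expect_equal(r0$quadrant, "trade-off")

  rd <- icer(-6214, 4.11)
  expect_equal(rd$quadrant, "dominant")
  expect_equal(abs(rd$value), 6214 / 4.11)

  expect_equal(icer(100, -2)$quadrant, "dominated")
  ru <- icer(100, 0)
  expect_false(ru$defined)
  expect_true(is.na(ru$value))
})

test_that("incremental table reproduces the reported deltas from reported cells", {
  mk_arm <- function(arm) {
    b <- structure(c(as.list(ref[[arm]]$costs),
                     list(total = sum(ref[[arm]]$costs), arm = arm)),
                   class = "cost_breakdown")
    list(tallies = state_tallies(ref[[arm]]$life_days), breakdown = b)
  }
  inc <- incremental_table(mk_arm("intervention"), mk_arm("control"))
  tot <- attr(inc, "total")
  expect_equal(tot$delta_cost, 679 + 20798 - 124 - 6214 + 19)
  expect_equal(round(tot$delta_effect, 2), 5.77)
  comp <- attr(inc, "complication_avoidance")
  expect_equal(comp$quadrant, "dominant")
  expect_equal(comp$delta_cost, -6214)
  expect_equal(comp$delta_effect, 4.11)

  # identical arms: all deltas zero, ICER flagged undefined
  inc0 <- incremental_table(mk_arm("intervention"), mk_arm("intervention"))
  expect_true(all(inc0$delta_cost == 0))
  expect_false(attr(inc0, "total")$defined)

  short <- mk_arm("control")
  short$tallies <- state_tallies(ref$control$life_days, horizon = 365)
  expect_error(incremental_table(mk_arm("intervention"), short),
               "different horizons")
})

test_that("component ICERs collapse to the daily rate when only state time moves", {
  # two synthetic arms differing only in ward days
  a <- state_tallies(c(WARD = 100, COMPLICATION = 5, ICU = 1, DISCHARGED = 10))
  b <- state_tallies(c(WARD = 90, COMPLICATION = 5, ICU = 1, DISCHARGED = 10))
  inc <- incremental_table(
    list(tallies = a, breakdown = accrue_costs(a, cost_inputs(), "control")),
    list(tallies = b, breakdown = accrue_costs(b, cost_inputs(), "control")))
  expect_equal(inc$icer[inc$component == "ward"], 1650)
})

test_that("deterministic sensitivity analysis spans both scenario grids", {
  sa <- deterministic_sa(intv_tal, ctrl_tal)
  expect_equal(nrow(sa), 9L)
  out5 <- function(f) {
    sa$nutrition_outpatient[sa$supplement_cost_per_day == 5 &
                              sa$outpatient_fraction == f]
  }
  expect_equal(round(out5(0.2)), 19)
  expect_equal(round(out5(0.5)), 47)
  expect_equal(round(out5(1.0)), 94)

  z <- deterministic_sa(intv_tal, ctrl_tal, fraction_grid = 0)
  expect_equal(z$nutrition_outpatient, rep(0, 3))

  expect_error(deterministic_sa(intv_tal, ctrl_tal,
                                supplement_cost_grid = numeric(0)),
               "non-empty")
  expect_error(deterministic_sa(intv_tal, ctrl_tal,
                                supplement_cost_grid = -5),
               "non-negative")
})

test_that("extrapolation keeps accrual rules and is monotone in the horizon", {
  # no-death toy pair: ward-day difference grows linearly with the horizon
  M_stay <- transition_matrix(local({
    p <- toy_probs(); p["WARD", "WARD"] <- 1; p
  }))
  M_leave <- transition_matrix(local({
    p <- toy_probs(); p["WARD", "DISCHARGED"] <- 1; p
  }))
  e180 <- extrapolate(M_stay, M_leave, horizon = 180)
  e365 <- extrapolate(M_stay, M_leave, horizon = 365)
  dw <- function(e) {
    df <- as.data.frame(e$incremental)
    df$delta_life_days[df$component == "ward"]
  }
  expect_equal(dw(e180), 179)
  expect_equal(dw(e365), 364)

  M1 <- seeded_random_matrix(31)
  M2 <- seeded_random_matrix(32)
  alive <- function(M, h) sum(tally_life_days(run_cohort(M, h))$life_days)
  expect_gte(alive(M1, 365), alive(M1, 180))
  expect_gte(alive(M2, 365), alive(M2, 180))
  ext <- extrapolate(M1, M2)
  expect_equal(ext$icer_per_life_year$delta_effect * 365,
               attr(ext$incremental, "total")$delta_effect)
})

test_that("threshold solver honours its contract and orders with the fraction", {
  expect_equal(threshold_nutrition_cost(1, wtp = 1e5)$max_cost, 1e5,
               tolerance = 1e-6)

  th <- threshold_nutrition_cost(0.05, wtp = 1e5,
                                 other_incremental_cost = 2000,
                                 mode = "full-incremental")
  expect_equal(th$max_cost, 3000, tolerance = 1e-3)
  expect_lt(abs(th$achieved_icer - 1e5), 1)

  # solver contract on an awkward toy
  th2 <- threshold_nutrition_cost(0.0137, wtp = 98765,
                                  outpatient_cost = 55.5)
  expect_lt(abs(th2$achieved_icer - 98765), 1)

  expect_false(threshold_nutrition_cost(0, wtp = 1e5)$feasible)
  expect_false(threshold_nutrition_cost(-0.2, wtp = 1e5)$feasible)
  # committed costs already above the budget
  expect_false(threshold_nutrition_cost(0.01, wtp = 1e5,
                                        outpatient_cost = 2000)$feasible)

  # admissible spend falls as the continuation fraction rises
  cs <- vapply(c(0.2, 0.5, 1.0), function(f) {
    threshold_nutrition_cost(0.03, wtp = 1e5,
                             outpatient_cost = f * 100)$max_cost
  }, numeric(1))
  expect_true(all(diff(cs) < 0))
})
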