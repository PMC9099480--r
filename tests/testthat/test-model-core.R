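test_that("validate_matrix reports each violated constraint", {
  expect_true(validate_matrix(identity_matrix())$valid)

  p <- toy_probs()
  p["WARD", "WARD"] <- 0.9  # row sums to 0.9
  v <- validate_matrix(transition_matrix(p))
  expect_false(v$valid)
  expect_match(v$violations, "row-sum", all = FALSE)

  p <- toy_probs()
  p["WARD", "WARD"] <- 1
  p["DISCHARGED", "DISCHARGED"] <- 0.9
  p["DISCHARGED", "ICU"] <- 0.1  # not an arrow of the state diagram
  v <- validate_matrix(transition_matrix(p))
  expect_false(v$valid)
  expect_match(v$violations, "mask.*DISCHARGED->ICU", all = FALSE)

  p <- toy_probs()
  p["WARD", "WARD"] <- 1
  p["DEAD", ] <- c(0.5, 0, 0, 0, 0.5)  # resurrection
  v <- validate_matrix(transition_matrix(p))
  expect_false(v$valid)
  expect_match(v$violations, "absorbing", all = FALSE)

  p <- toy_probs()
  p["WARD", "WARD"] <- 2
  p["WARD", "DEAD"] <- -1
  v <- validate_matrix(transition_matrix(p))
  expect_match(v$violations, "range", all = FALSE)
})

test_that("run_cohort matches hand enumeration and handles degenerate chains", {
  tr <- run_cohort(identity_matrix(), 3)
  expect_equal(unname(tr$occupancy[, "WARD"]), c(1, 1, 1))

  tr <- run_cohort(ward_to_dead(), 5)
  expect_equal(unname(tr$occupancy[, "WARD"]), c(1, 0, 0, 0, 0))
  expect_equal(unname(tr$occupancy[, "DEAD"]), c(0, 1, 1, 1, 1))

  M <- discharge_toy()
  tr <- run_cohort(M, 4)
  expect_equal(unname(tr$occupancy[, "WARD"]), c(1, 0.5, 0.25, 0.125))
  expect_equal(tr$occupancy, enumerate_occupancy(M$probs, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # a denser chain against the same oracle
  M <- seeded_random_matrix(42)
  expect_equal(run_cohort(M, 4)$occupancy,
               enumerate_occupancy(M$probs, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  bad <- transition_matrix(matrix(0.2, 5, 5))
  expect_error(run_cohort(bad, 10), "invalid transition matrix")
  expect_error(run_cohort(discharge_toy(), 0), "horizon")
})

test_that("life-day tallies equal occupancy column sums and account every day", {
  t180 <- tally_life_days(run_cohort(identity_matrix(), 180))
  expect_equal(t180$life_days[["WARD"]], 180)
  expect_equal(sum(t180$life_days[c("COMPLICATION", "ICU", "DISCHARGED")]), 0)

  tt <- tally_life_days(run_cohort(discharge_toy(), 4))
  expect_equal(tt$life_days[["WARD"]], 1.875)
  expect_equal(tt$life_days[["DISCHARGED"]], 2.125)
  oracle <- enumerate_life_days(discharge_toy()$probs, 4)
  expect_equal(unname(tt$life_days), unname(oracle[alive_states()]))

  for (seed in 1:8) {
    M <- seeded_random_matrix(seed)
    tl <- tally_life_days(run_cohort(M, 90))
    expect_equal(sum(tl$life_days) + tl$dead_days, 90, tolerance = 1e-10)
  }
})

test_that("cohort traces conserve mass and death is absorbing", {
  for (seed in 1:10) {
    M <- seeded_random_matrix(seed)
    tr <- run_cohort(M, 120)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-10))
    expect_true(all(diff(tr$occupancy[, "DEAD"]) >= -1e-12))
  }
  # with positive daily death risk everywhere, the cohort is fully absorbed
  M <- seeded_random_matrix(4)
  expect_gt(min(M$probs[1:4, "DEAD"]), 0)
  expect_equal(run_cohort(M, 3000)$occupancy[3000, "DEAD"], 1,
               tolerance = 1e-6)
})

test_that("microsimulation agrees with the cohort expectation", {
  sim <- simulate_individuals(ward_to_dead(), n = 50, horizon = 6, seed = 1)
  expect_equal(unname(sim$tallies$life_days[["WARD"]]), 1)
  expect_equal(sim$tallies$dead_fraction_at_end, 1)
  expect_true(all(sim$patient_days[, "WARD"] == 1))

  # same seed, same draw-for-draw output
  a <- simulate_individuals(discharge_toy(), 500, 10, seed = 7)
  b <- simulate_individuals(discharge_toy(), 500, 10, seed = 7)
  expect_identical(a$patient_days, b$patient_days)

  # closed form for the discharge toy: E[ward days] = 1.875 over 4 days
  sim <- simulate_individuals(discharge_toy(), 1e5, 4, seed = 11)
  se <- stats::sd(sim$patient_days[, "WARD"]) / sqrt(sim$n)
  expect_lt(abs(mean(sim$patient_days[, "WARD"]) - 1.875), 3 * se)

  # equivalence on a random matrix, all four states
  M <- seeded_random_matrix(5)
  coh <- tally_life_days(run_cohort(M, 60))
  sim <- simulate_individuals(M, 1e5, 60, seed = 13)
  for (s in alive_states()) {
    se <- stats::sd(sim$patient_days[, s]) / sqrt(sim$n)
    expect_lt(abs(sim$tallies$life_days[[s]] - coh$life_days[[s]]),
              3 * se + 1e-12)
  }
  se_dead <- sqrt(coh$dead_fraction_at_end * (1 - coh$dead_fraction_at_end) / sim$n)
  expect_lt(abs(sim$tallies$dead_fraction_at_end - coh$dead_fraction_at_end),
            3 * se_dead)

  expect_error(simulate_individuals(discharge_toy(), 0, 5, seed = 1), "`n`")
})

test_that("matrices round-trip through the delimited text format", {
  M <- seeded_random_matrix(21)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(M, f, meta = list(arm = "test"))
  M2 <- read_matrix(f)
  expect_equal(M2$probs, M$probs, tolerance = 1e-12)
  expect_identical(M2$mask, M$mask)
  expect_true(file.exists(paste0(f, ".json")))
})
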