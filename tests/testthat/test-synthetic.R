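test_that("trajectory tables respect the patient-day contract", {
  ward_stay <- identity_matrix()
  tr <- generate_trial(ward_stay, ward_stay, n_intv = 3, n_ctrl = 3,
                       horizon = 5, seed = 1)
  expect_equal(nrow(tr), 30L)
  expect_true(all(tr$state == "WARD"))
  expect_equal(as.vector(table(tr$patient_id)), rep(5L, 6))
  expect_equal(sort(unique(tr$day)), 0:4)

  # immediate death: one alive day plus a single terminal DEAD row
  trd <- generate_trial(ward_to_dead(), ward_to_dead(), n_intv = 4,
                        n_ctrl = 2, horizon = 10, seed = 2)
  per <- split(trd, trd$patient_id)
  for (p in per) {
    expect_equal(p$state, c("WARD", "DEAD"))
    expect_equal(p$day, c(0L, 1L))
  }

  # days are contiguous from 0 and DEAD is terminal for every patient
  M <- seeded_random_matrix(15)
  tr2 <- generate_trial(M, M, n_intv = 200, n_ctrl = 200, horizon = 30,
                        seed = 3)
  for (p in split(tr2, tr2$patient_id)) {
    expect_equal(p$day, seq_len(nrow(p)) - 1L)
    dead_at <- which(p$state == "DEAD")
    if (length(dead_at)) expect_equal(dead_at, nrow(p))
    expect_equal(p$state[1], "WARD")
  }
})

test_that("arms are independent RNG substreams under one master seed", {
  M1 <- seeded_random_matrix(41)
  M2 <- seeded_random_matrix(43)
  M3 <- seeded_random_matrix(47)
  a <- generate_trial(M1, M2, n_intv = 50, n_ctrl = 50, horizon = 20, seed = 9)
  b <- generate_trial(M1, M3, n_intv = 50, n_ctrl = 50, horizon = 20, seed = 9)
  expect_identical(a[a$arm == "intervention", ],
                   b[b$arm == "intervention", ])
  expect_false(identical(a[a$arm == "control", ], b[b$arm == "control", ]))
})

test_that("transition counts yield the maximum-likelihood matrix", {
  # deterministic chain: ward -> discharged -> discharged ...
  M_leave <- transition_matrix(local({
    p <- toy_probs(); p["WARD", "DISCHARGED"] <- 1; p
  }))
  tr <- generate_trial(M_leave, M_leave, n_intv = 10, n_ctrl = 1,
                       horizon = 6, seed = 5)
  est <- estimate_matrix(tr, "intervention")
  expect_equal(est$probs["WARD", "DISCHARGED"], 1)
  expect_equal(est$probs["DISCHARGED", "DISCHARGED"], 1)
  # states never visited are flagged
  expect_setequal(attr(est$probs, "unobserved_states"),
                  c("COMPLICATION", "ICU"))

  # masked-out cells are exactly zero even with an adversarial mask
  M <- seeded_random_matrix(16)
  tr2 <- generate_trial(M, M, n_intv = 500, n_ctrl = 1, horizon = 20, seed = 6)
  est2 <- estimate_matrix(tr2, "intervention")
  expect_true(all(est2$probs[!est2$mask] == 0))
  expect_error(estimate_matrix(tr2, "placebo"), "no rows")
})

test_that("round-trip: estimate from 50,000 patients recovers the generator", {
  M <- seeded_random_matrix(18)
  tr <- generate_trial(M, M, n_intv = 5e4, n_ctrl = 1, horizon = 60, seed = 7)
  est <- estimate_matrix(tr, "intervention")
  counts <- attr(est$probs, "transition_counts")
  departures <- rowSums(counts)
  for (i in 1:4) {
    for (j in 1:5) {
      if (!M$mask[i, j]) next
      p <- M$probs[i, j]
      se <- sqrt(p * (1 - p) / departures[i])
      expect_lt(abs(est$probs[i, j] - p), 3 * se + 1e-12)
    }
  }
  # cohort tallies computed from the estimate reproduce the generator's
  truth <- tally_life_days(run_cohort(M, 60))
  fitted <- tally_life_days(run_cohort(est, 60))
  expect_equal(unname(fitted$life_days), unname(truth$life_days),
               tolerance = 0.01)
})

test_that("trial summaries match the cohort expectation", {
  one <- generate_trial(identity_matrix(), identity_matrix(),
                        n_intv = 1, n_ctrl = 1, horizon = 180, seed = 11)
  s <- summarize_trial(one)
  expect_equal(s$intervention$tallies$life_days[["WARD"]], 180)
  expect_equal(s$intervention$mortality, 0)

  M <- seeded_random_matrix(19)
  tr <- generate_trial(M, M, n_intv = 2e4, n_ctrl = 100, horizon = 40,
                       seed = 12)
  s <- summarize_trial(tr)
  expect_equal(s$intervention$n, 2e4)
  coh <- tally_life_days(run_cohort(M, 40))
  sim <- simulate_individuals(M, 2e4, 40, seed = 13)  # for standard errors
  for (st in alive_states()) {
    se <- sd(sim$patient_days[, st]) / sqrt(2e4)
    expect_lt(abs(s$intervention$tallies$life_days[[st]] - coh$life_days[[st]]),
              3 * se + 1e-12)
  }

  # an arm with no patients is flagged rather than summarized
  sub <- tr[tr$arm == "intervention", ]
  attr(sub, "horizon") <- attr(tr, "horizon")
  class(sub) <- class(tr)
  s2 <- summarize_trial(sub)
  expect_null(s2$control$tallies)
})

test_that("trajectories round-trip through the delimited format", {
  M <- seeded_random_matrix(22)
  tr <- generate_trial(M, M, n_intv = 20, n_ctrl = 20, horizon = 15, seed = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(tr, f)
  back <- read_trajectories(f, horizon = 15)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  expect_equal(attr(back, "horizon"), 15L)
})
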