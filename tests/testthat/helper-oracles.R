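# Brute-force path-enumeration oracle for tiny chains: expected start-of-day
# occupancy and life days computed by summing over every state path, entirely
# independent of the package's cohort recursion.
enumerate_occupancy <- function(probs, horizon) {
  occ <- matrix(0, horizon, 5)
  paths <- list(list(states = 1L, p = 1))
  for (t in seq_len(horizon)) {
    for (pp in paths) {
      occ[t, pp$states[t]] <- occ[t, pp$states[t]] + pp$p
    }
    if (t == horizon) break
    nxt <- list()
    for (pp in paths) {
      cur <- pp$states[t]
      for (to in 1:5) {
        pr <- probs[cur, to]
        if (pr > 0) {
          nxt[[length(nxt) + 1L]] <- list(states = c(pp$states, to),
                                          p = pp$p * pr)
        }
      }
    }
    paths <- nxt
  }
  colnames(occ) <- health_states()
  occ
}

enumerate_life_days <- function(probs, horizon) {
  colSums(enumerate_occupancy(probs, horizon))
}

# Toy chains reused across files (all valid under the default mask).
toy_probs <- function() {
  s <- health_states()
  p <- matrix(0, 5, 5, dimnames = list(s, s))
  p["COMPLICATION", "COMPLICATION"] <- 1
  p["ICU", "ICU"] <- 1
  p["DISCHARGED", "DISCHARGED"] <- 1
  p["DEAD", "DEAD"] <- 1
  p
}

discharge_toy <- function() {
  p <- toy_probs()
  p["WARD", "WARD"] <- 0.5
  p["WARD", "DISCHARGED"] <- 0.5
  transition_matrix(p)
}

ward_to_dead <- function() {
  p <- toy_probs()
  p["WARD", "DEAD"] <- 1
  transition_matrix(p)
}

identity_matrix <- function() {
  transition_matrix(diag(5), mask = diag(5) > 0)
}

seeded_random_matrix <- function(seed, mask = default_mask()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  random_transition_matrix(mask)
}

# Trial-arm calibrations are expensive; fit each arm once per test run.
.calibration_cache <- new.env(parent = emptyenv())
cached_calibration <- function(arm) {
  if (is.null(.calibration_cache[[arm]])) {
    .calibration_cache[[arm]] <- calibrate_arm(
      trial_targets(arm),
      seed = 101 + match(arm, c("intervention", "control")))
  }
  .calibration_cache[[arm]]
}
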