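#' Individual-level microsimulation of the daily chain
#'
#' Monte-Carlo cross-check of the cohort expectation: `n` patients start in
#' the ward and step once per day by sampling their current state's row of
#' the transition matrix. Day counting matches [run_cohort()] /
#' [tally_life_days()]: the state occupied at the start of each of the
#' `horizon` days accrues one day, and the dead fraction is measured at the
#' start of the final modeled day.
#'
#' @param M A valid [transition_matrix()].
#' @param n Number of simulated patients (>= 1).
#' @param horizon Number of daily cycles (>= 1).
#' @param seed Integer seed; identical seeds give identical output. The
#'   caller's RNG state is left untouched.
#' @return List with `tallies` (a `state_tallies` of sample means),
#'   `patient_days` (`n` x 4 matrix of per-patient alive-state day counts),
#'   `dead` (logical vector, dead at end of horizon), and `n`.
#' @export
#' @examples
#' s <- health_states()
#' p <- matrix(0, 5, 5, dimnames = list(s, s))
#' p[, "DEAD"] <- 1  # everyone dies after day 0
#' sim <- simulate_individuals(transition_matrix(p, p > 0 | default_mask()),
#'                             n = 10, horizon = 5, seed = 1)
#' mean(sim$patient_days[, "WARD"])  # exactly 1
simulate_individuals <- function(M, n, horizon, seed) {
  stop_if_invalid(M)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L)
  with_seed(seed, {
    state <- rep(1L, n)  # WARD
    counts <- matrix(0L, n, 5L, dimnames = list(NULL, health_states()))
    idx <- seq_len(n)
    for (t in seq_len(horizon)) {
      counts[cbind(idx, state)] <- counts[cbind(idx, state)] + 1L
      if (t < horizon) state <- step_states(state, M$probs)
    }
    tallies <- structure(list(
      life_days = colMeans(counts[, alive_states(), drop = FALSE]),
      dead_days = mean(counts[, "DEAD"]),
      dead_fraction_at_end = mean(state == 5L),
      horizon = horizon
    ), class = "state_tallies")
    list(tallies = tallies,
         patient_days = counts[, alive_states(), drop = FALSE],
         dead = state == 5L,
         n = n)
  })
}

# One synchronous daily step for a vector of integer states (1..5).
step_states <- function(state, probs) {
  nxt <- state
  for (s in 1:4) {
    here <- which(state == s)
    if (length(here)) {
      nxt[here] <- sample.int(5L, length(here), replace = TRUE, prob = probs[s, ])
    }
  }
  nxt
}

# Evaluate `expr` under a deterministic RNG stream without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
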