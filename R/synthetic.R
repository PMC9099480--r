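#' Generate a synthetic two-arm trial of daily state trajectories
#'
#' Emulates the patient-level data the model assumes: each patient starts in
#' the ward on day 0 and steps once per day by sampling their arm's
#' transition matrix, for `horizon` days or until death. The result is a
#' long patient-day table; death is recorded as a single terminal row and no
#' rows are emitted after it. Each arm is simulated on its own RNG substream
#' derived from the master seed, so regenerating one arm never perturbs the
#' other.
#'
#' @param M_intv,M_ctrl Valid arm [transition_matrix()] objects.
#' @param n_intv,n_ctrl Arm sizes (defaults 321 and 324, the trial's
#'   allocation).
#' @param horizon Days (default 180).
#' @param seed Master integer seed.
#' @return A `trajectory_table`: data frame with columns `patient_id`
#'   (unique across arms), `arm`, `day` (0-based, contiguous from 0), and
#'   `state`; attribute `horizon`.
#' @export
generate_trial <- function(M_intv, M_ctrl, n_intv = 321, n_ctrl = 324,
                           horizon = 180, seed) {
  stop_if_invalid(M_intv)
  stop_if_invalid(M_ctrl)
  stopifnot(n_intv >= 1, n_ctrl >= 1, horizon >= 1)
  arm_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))
  intv <- simulate_arm_paths(M_intv, n_intv, horizon, arm_seeds[1L],
                             arm = "intervention", id_offset = 0L)
  ctrl <- simulate_arm_paths(M_ctrl, n_ctrl, horizon, arm_seeds[2L],
                             arm = "control", id_offset = as.integer(n_intv))
  out <- rbind(intv, ctrl)
  attr(out, "horizon") <- as.integer(horizon)
  class(out) <- c("trajectory_table", "data.frame")
  out
}

simulate_arm_paths <- function(M, n, horizon, seed, arm, id_offset) {
  n <- as.integer(n)
  horizon <- as.integer(horizon)
  states <- with_seed(seed, {
    mat <- matrix(0L, n, horizon)
    st <- rep(1L, n)
    for (t in seq_len(horizon)) {
      mat[, t] <- st
      if (t < horizon) st <- step_states(st, M$probs)
    }
    mat
  })
  # emit alive days plus a single terminal DEAD row (if death occurs in-horizon)
  first_dead <- apply(states == 5L, 1L, function(z) {
    w <- which(z)
    if (length(w)) w[1L] else NA_integer_
  })
  len <- ifelse(is.na(first_dead), horizon, first_dead)
  idx <- cbind(rep(seq_len(n), len), sequence(len))
  data.frame(
    patient_id = id_offset + idx[, 1L],
    arm = arm,
    day = idx[, 2L] - 1L,
    state = health_states()[states[idx]],
    stringsAsFactors = FALSE
  )
}

#' Maximum-likelihood transition-matrix estimate from trajectories
#'
#' Counts observed day-to-day transitions within patients of one arm and
#' divides each row by its total departures; cells the structural mask
#' forbids are forced to zero (and the row renormalized) and alive states
#' never observed get an absorbing self-loop row, flagged in the
#' `unobserved_states` attribute of the result's probability matrix.
#'
#' @param trajectories A `trajectory_table` from [generate_trial()].
#' @param arm Arm label to estimate from.
#' @param mask Structural mask (default [default_mask()]).
#' @return A [transition_matrix()]; its `probs` carries attributes
#'   `transition_counts` (the 5x5 count table) and `unobserved_states`.
#' @export
estimate_matrix <- function(trajectories, arm, mask = default_mask()) {
  stopifnot(inherits(trajectories, "trajectory_table"))
  tr <- trajectories[trajectories$arm == arm, , drop = FALSE]
  if (!nrow(tr)) stop("no rows for arm '", arm, "'", call. = FALSE)
  tr <- tr[order(tr$patient_id, tr$day), , drop = FALSE]
  st <- match(tr$state, health_states())
  same <- tr$patient_id[-1L] == tr$patient_id[-nrow(tr)] &
    tr$day[-1L] == tr$day[-nrow(tr)] + 1L
  from <- st[-nrow(tr)][same]
  to <- st[-1L][same]
  counts <- matrix(tabulate(from + 5L * (to - 1L), nbins = 25L), 5L, 5L,
                   dimnames = list(health_states(), health_states()))
  p <- counts
  p[!mask] <- 0
  unobserved <- character(0)
  for (i in 1:4) {
    tot <- sum(p[i, ])
    if (tot > 0) {
      p[i, ] <- p[i, ] / tot
    } else {
      p[i, ] <- 0
      p[i, i] <- 1  # never observed: flagged absorbing placeholder
      unobserved <- c(unobserved, health_states()[i])
    }
  }
  p[5L, ] <- c(0, 0, 0, 0, 1)
  attr(p, "transition_counts") <- counts
  attr(p, "unobserved_states") <- unobserved
  mask2 <- mask
  for (s in unobserved) mask2[s, s] <- TRUE  # keep placeholder self-loops valid
  M <- transition_matrix(p, mask2)
  M$probs <- p
  M
}

#' Per-arm summaries of a synthetic trial
#'
#' Mean per-patient days in each alive state (over days `0 .. horizon-1`)
#' and the dead fraction at the end of the horizon — the microsimulation
#' analogue of [tally_life_days()], so arm summaries are directly
#' comparable to cohort-model tallies.
#'
#' @param trajectories A `trajectory_table`.
#' @return Named list per arm: `n`, `tallies` (a `state_tallies`), and
#'   `mortality`. Arms with no patients are flagged (`n = 0`, no tallies).
#' @export
summarize_trial <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_table"))
  horizon <- attr(trajectories, "horizon")
  if (is.null(horizon)) horizon <- max(trajectories$day) + 1L
  arms <- unique(trajectories$arm)
  out <- lapply(arms, function(a) {
    tr <- trajectories[trajectories$arm == a, , drop = FALSE]
    n <- length(unique(tr$patient_id))
    if (!n) return(list(n = 0L, tallies = NULL, mortality = NA_real_))
    alive <- tr[tr$state != "DEAD", , drop = FALSE]
    days <- vapply(alive_states(), function(s) {
      sum(alive$state == s) / n
    }, numeric(1))
    dead_ids <- unique(tr$patient_id[tr$state == "DEAD" &
                                       tr$day <= horizon - 1L])
    mortality <- length(dead_ids) / n
    tallies <- structure(list(
      life_days = days,
      dead_days = horizon - sum(days),
      dead_fraction_at_end = mortality,
      horizon = horizon
    ), class = "state_tallies")
    list(n = n, tallies = tallies, mortality = mortality)
  })
  names(out) <- arms
  out
}

#' Read / write trajectory tables as delimited text
#'
#' @param trajectories A `trajectory_table`.
#' @param file Path of the tab-delimited table with header
#'   `patient_id, arm, day, state`.
#' @return `write_trajectories()` returns `file` invisibly;
#'   `read_trajectories()` returns a `trajectory_table`.
#' @export
write_trajectories <- function(trajectories, file) {
  stopifnot(inherits(trajectories, "trajectory_table"))
  utils::write.table(trajectories, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectories
#' @param horizon Horizon of the stored table; inferred from the data when
#'   omitted.
#' @export
read_trajectories <- function(file, horizon = NULL) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "arm", "day", "state") %in% names(df)))
  attr(df, "horizon") <- if (is.null(horizon)) max(df$day) + 1L else
    as.integer(horizon)
  class(df) <- c("trajectory_table", "data.frame")
  df
}
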