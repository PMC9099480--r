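#' Run the deterministic cohort model
#'
#' Propagates a cohort that starts entirely in the ward through `horizon`
#' daily cycles. Row `t` of the returned occupancy grid (0-based) is the
#' cohort distribution at the start of day `t`; row `t + 1` is row `t`
#' post-multiplied by the transition matrix. One full day of time (and, in
#' the accrual step, cost) is attributed to the state occupied at the start
#' of each day; no half-cycle correction is applied.
#'
#' @param M A valid [transition_matrix()].
#' @param horizon Number of daily cycles (>= 1); 180 in the base case.
#' @return A `cohort_trace`: list with `occupancy` (`horizon` x 5 matrix,
#'   rows named `t0, t1, ...`) and `horizon`.
#' @seealso [tally_life_days()], [simulate_individuals()]
#' @export
#' @examples
#' M <- transition_matrix(diag(5), mask = diag(5) > 0)
#' run_cohort(M, 3)$occupancy[, "WARD"]
run_cohort <- function(M, horizon) {
  stop_if_invalid(M)
  horizon <- as.integer(horizon)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 1L) {
    stop("`horizon` must be a positive integer number of days", call. = FALSE)
  }
  s <- health_states()
  occ <- matrix(0, horizon, 5, dimnames = list(paste0("t", seq_len(horizon) - 1L), s))
  row <- c(1, 0, 0, 0, 0)  # all patients begin hospitalized in the ward
  occ[1L, ] <- row
  if (horizon > 1L) {
    for (t in 2:horizon) {
      row <- as.vector(row %*% M$probs)
      occ[t, ] <- row
    }
  }
  structure(list(occupancy = occ, horizon = horizon), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$horizon, "daily cycles\n")
  cat("Final-day occupancy:\n")
  print(round(x$occupancy[x$horizon, ], 4))
  invisible(x)
}

#' Tally expected life days per state
#'
#' Sums start-of-day occupancy over the horizon: the expected number of days
#' the cohort spends in each alive state, plus the dead fraction at the
#' start of the final modeled day. Alive-state life days plus expected days
#' spent dead always total the horizon exactly.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @return A `state_tallies`: list with `life_days` (named numeric over the
#'   four alive states), `dead_days` (expected days spent dead),
#'   `dead_fraction_at_end`, and `horizon`.
#' @export
#' @examples
#' M <- transition_matrix(diag(5), mask = diag(5) > 0)
#' tally_life_days(run_cohort(M, 180))$life_days["WARD"]
tally_life_days <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  sums <- colSums(trace$occupancy)
  structure(list(
    life_days = sums[alive_states()],
    dead_days = unname(sums["DEAD"]),
    dead_fraction_at_end = unname(trace$occupancy[trace$horizon, "DEAD"]),
    horizon = trace$horizon
  ), class = "state_tallies")
}

#' Construct state tallies directly
#'
#' Builds a `state_tallies` object from known per-state expected life days —
#' e.g. a published base-case table — so the accrual and reporting layers can
#' run without a transition matrix.
#'
#' @param life_days Named (or canonically ordered) numeric of expected days
#'   in WARD, COMPLICATION, ICU, DISCHARGED.
#' @param dead_fraction_at_end Probability of being dead at the end of the
#'   horizon (default `NA`).
#' @param horizon Horizon in days (default 180).
#' @return A `state_tallies` object.
#' @export
state_tallies <- function(life_days, dead_fraction_at_end = NA_real_,
                          horizon = 180) {
  a <- alive_states()
  if (is.null(names(life_days))) names(life_days) <- a
  stopifnot(setequal(names(life_days), a))
  life_days <- life_days[a]
  if (any(life_days < 0) || sum(life_days) > horizon + 1e-9) {
    stop("life days must be non-negative and sum to at most the horizon",
         call. = FALSE)
  }
  structure(list(
    life_days = life_days,
    dead_days = horizon - sum(life_days),
    dead_fraction_at_end = dead_fraction_at_end,
    horizon = horizon
  ), class = "state_tallies")
}

#' @export
print.state_tallies <- function(x, ...) {
  cat("Expected life days over", x$horizon, "days:\n")
  print(round(x$life_days, 2))
  cat(sprintf("Total alive: %.2f days; dead fraction at end: %s\n",
              sum(x$life_days),
              ifelse(is.na(x$dead_fraction_at_end), "NA",
                     sprintf("%.3f", x$dead_fraction_at_end))))
  invisible(x)
}

#' Write a cohort trace as a delimited table with a JSON sidecar
#'
#' @param trace A `cohort_trace`.
#' @param file Output path for the tab-delimited occupancy table
#'   (one row per cycle). A `<file>.json` sidecar records the horizon and
#'   any extra metadata.
#' @param meta Optional named list merged into the sidecar.
#' @return `file`, invisibly.
#' @export
write_trace <- function(trace, file, meta = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- data.frame(day = seq_len(trace$horizon) - 1L, trace$occupancy,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(horizon = trace$horizon), meta),
                       paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
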