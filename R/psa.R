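#' Moment-matched Gamma specification for a cost input
#'
#' Parameterizes a Gamma distribution by its mean and standard deviation:
#' shape = (mean/sd)^2, scale = sd^2/mean, so the reconstructed moments
#' match the inputs exactly. Used for the probabilistic sensitivity
#' analysis, where each unit cost is Gamma-distributed around its base-case
#' value.
#'
#' @param mean,sd Positive mean and standard deviation (SF).
#' @return Object of class `gamma_spec`: `mean`, `sd`, `shape`, `scale`.
#' @export
#' @examples
#' gamma_from_mean_sd(1650, 1485)  # ward cost: shape ~1.23, scale ~1336.5
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("`mean` must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  structure(list(mean = mean, sd = sd,
                 shape = (mean / sd)^2, scale = sd^2 / mean),
            class = "gamma_spec")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf("Gamma(shape = %.6g, scale = %.6g): mean %.6g, sd %.6g\n",
              x$shape, x$scale, x$mean, x$sd))
  invisible(x)
}

#' Default Gamma specifications for the five cost inputs
#'
#' Base-case means with their probabilistic-analysis standard deviations:
#' nutrition in/outpatient 5 (SD 1), ward day 1650 (SD 1485), ICU day 4654
#' (SD 3900), complication day 1513 (SD 1477).
#'
#' @param costs Base [cost_inputs()] supplying the means.
#' @param sds Named numeric of standard deviations for
#'   `nutrition_inpatient_per_day`, `nutrition_outpatient_per_day`,
#'   `ward_per_day`, `icu_per_day`, `complication_per_day`.
#' @return Named list of [gamma_from_mean_sd()] specs.
#' @export
default_gamma_specs <- function(costs = cost_inputs(),
                                sds = c(nutrition_inpatient_per_day = 1,
                                        nutrition_outpatient_per_day = 1,
                                        ward_per_day = 1485,
                                        icu_per_day = 3900,
                                        complication_per_day = 1477)) {
  nm <- names(sds)
  stats::setNames(lapply(nm, function(k) {
    gamma_from_mean_sd(costs[[k]], sds[[k]])
  }), nm)
}

#' Probabilistic sensitivity analysis over Gamma-distributed cost inputs
#'
#' Each draw samples the five unit costs independently from their Gamma
#' specifications (the same draw applies to both arms — unit costs are
#' common parameters), holds the arm life-day tallies fixed, and recomputes
#' the incremental total cost and the ICER per life day. Uncertainty is
#' summarized by the mean and the 2.5/97.5 percentile interval; percentile
#' (not normal-approximation) intervals are used because Gamma draws are
#' right-skewed. Transition probabilities and life days are not varied:
#' only costs carry probabilistic specifications here.
#'
#' @param intv_tallies,ctrl_tallies Per-arm `state_tallies`.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed; identical seeds give identical summaries.
#' @param specs Named list of `gamma_spec`s (default
#'   [default_gamma_specs()]).
#' @param costs Base [cost_inputs()] supplying the outpatient continuation
#'   fraction (held fixed across draws).
#' @return Object of class `psa_summary`: `draws` (data frame with one row
#'   per draw: sampled unit costs, `delta_cost`, `icer_per_life_day`),
#'   `mean_delta_cost`, `ci_delta_cost` (2.5/97.5 percentiles),
#'   `mean_icer`, `ci_icer`, `n_draws`, `seed`.
#' @export
run_psa <- function(intv_tallies, ctrl_tallies, n_draws, seed,
                    specs = default_gamma_specs(), costs = cost_inputs()) {
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) {
    stop("`n_draws` must be a positive integer", call. = FALSE)
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "gamma_spec")))
  keys <- names(specs)
  with_seed(seed, {
    draws_mat <- vapply(keys, function(k) {
      stats::rgamma(n_draws, shape = specs[[k]]$shape,
                    scale = specs[[k]]$scale)
    }, numeric(n_draws))
    if (n_draws == 1L) draws_mat <- matrix(draws_mat, 1L,
                                           dimnames = list(NULL, keys))
    res <- apply(draws_mat, 1L, function(u) {
      ci <- costs
      for (k in keys) ci[[k]] <- u[[k]]
      inc <- incremental_table(
        arm_result(intv_tallies, ci, "intervention"),
        arm_result(ctrl_tallies, ci, "control"))
      tot <- attr(inc, "total")
      c(delta_cost = tot$delta_cost, icer_per_life_day = tot$value)
    })
    draws <- data.frame(draws_mat, t(res))
    structure(list(
      draws = draws,
      mean_delta_cost = mean(draws$delta_cost),
      ci_delta_cost = stats::quantile(draws$delta_cost, c(0.025, 0.975)),
      mean_icer = mean(draws$icer_per_life_day),
      ci_icer = stats::quantile(draws$icer_per_life_day, c(0.025, 0.975)),
      n_draws = n_draws, seed = seed
    ), class = "psa_summary")
  })
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("PSA over %d draws (seed %d):\n", x$n_draws, x$seed))
  cat(sprintf("  incremental cost: mean %.0f SF, 95%% CI [%.0f, %.0f]\n",
              x$mean_delta_cost, x$ci_delta_cost[1], x$ci_delta_cost[2]))
  cat(sprintf("  ICER per life day: mean %.0f SF, 95%% CI [%.0f, %.0f]\n",
              x$mean_icer, x$ci_icer[1], x$ci_icer[2]))
  invisible(x)
}

#' Write PSA draws as a delimited table
#'
#' @param psa A `psa_summary`.
#' @param file Output path (tab-delimited, one row per draw).
#' @return `file`, invisibly.
#' @export
write_psa_draws <- function(psa, file) {
  stopifnot(inherits(psa, "psa_summary"))
  utils::write.table(psa$draws, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
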