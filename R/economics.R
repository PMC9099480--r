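#' Cost inputs of the model
#'
#' Per-day unit costs in Swiss francs (SF) and the fraction of discharged
#' patients who continue oral nutritional supplements as outpatients.
#' Defaults are the base-case unit costs: 5 SF/day for in- and outpatient
#' nutritional supplements (one oral supplement per day), 1650 SF per ward
#' day, 4654 SF per ICU day (intensive-care complex-treatment DRG), 1513 SF
#' per complication day (severe arrhythmia / cardiac arrest DRG), and 20%
#' post-discharge continuation. No cost is ever assigned to death.
#'
#' @param nutrition_inpatient_per_day,nutrition_outpatient_per_day,ward_per_day,icu_per_day,complication_per_day
#'   Non-negative daily unit costs (SF/day).
#' @param outpatient_fraction Fraction of discharged patients continuing
#'   supplements, in `[0, 1]`.
#' @return Object of class `cost_inputs`.
#' @export
cost_inputs <- function(nutrition_inpatient_per_day = 5,
                        nutrition_outpatient_per_day = 5,
                        ward_per_day = 1650,
                        icu_per_day = 4654,
                        complication_per_day = 1513,
                        outpatient_fraction = 0.2) {
  vals <- c(nutrition_inpatient_per_day, nutrition_outpatient_per_day,
            ward_per_day, icu_per_day, complication_per_day)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all unit costs must be finite and non-negative", call. = FALSE)
  }
  if (outpatient_fraction < 0 || outpatient_fraction > 1) {
    stop("`outpatient_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    nutrition_inpatient_per_day = nutrition_inpatient_per_day,
    nutrition_outpatient_per_day = nutrition_outpatient_per_day,
    ward_per_day = ward_per_day,
    icu_per_day = icu_per_day,
    complication_per_day = complication_per_day,
    outpatient_fraction = outpatient_fraction
  ), class = "cost_inputs")
}

#' Daily utility weights per alive state
#'
#' Quality weights (unitless, per day, in `[0, 1]`) applied to life days to
#' form quality-adjusted life days (QALDs); death is fixed at 0. The default
#' is a single daily weight of 0.002 for every alive state, back-solved from
#' the published base-case utility column; utilities are reported but never
#' enter ICERs (all ICERs here are per unweighted life day).
#'
#' @param WARD,COMPLICATION,ICU,DISCHARGED Daily weights in `[0, 1]`.
#' @return Named numeric of class `utility_weights`.
#' @export
utility_weights <- function(WARD = 0.002, COMPLICATION = 0.002,
                            ICU = 0.002, DISCHARGED = 0.002) {
  w <- c(WARD = WARD, COMPLICATION = COMPLICATION,
         ICU = ICU, DISCHARGED = DISCHARGED)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("utility weights must lie in [0, 1]", call. = FALSE)
  }
  structure(w, class = "utility_weights")
}

#' Accrue per-state costs from life-day tallies
#'
#' Whole-day accrual at constant daily rates, undiscounted: ward, ICU and
#' complication costs are the respective life days times the daily unit
#' cost. Inpatient nutritional support costs accrue on every in-hospital day
#' (ward + complication + ICU) in the intervention arm only; outpatient
#' nutritional support accrues on discharged days for the continuing
#' fraction of intervention patients. The control arm receives usual
#' hospital food, so both nutrition components are zero there. Death accrues
#' nothing.
#'
#' @param tallies A `state_tallies` (see [tally_life_days()], [state_tallies()]).
#' @param costs A [cost_inputs()].
#' @param arm `"intervention"` or `"control"`.
#' @return A `cost_breakdown`: named list of the five components
#'   (`nutrition_inpatient`, `ward`, `icu`, `complication`,
#'   `nutrition_outpatient`), their `total`, and the `arm`. All in SF,
#'   unrounded.
#' @export
#' @examples
#' td <- state_tallies(c(WARD = 123.84, COMPLICATION = 10.09,
#'                       ICU = 1.88, DISCHARGED = 18.77), 0.265)
#' accrue_costs(td, cost_inputs(), "intervention")$nutrition_inpatient
accrue_costs <- function(tallies, costs, arm = c("intervention", "control")) {
  stopifnot(inherits(tallies, "state_tallies"), inherits(costs, "cost_inputs"))
  arm <- match.arg(arm)
  d <- tallies$life_days
  if (any(d < 0)) stop("life-day tallies must be non-negative", call. = FALSE)
  inhosp_days <- d[["WARD"]] + d[["COMPLICATION"]] + d[["ICU"]]
  treated <- arm == "intervention"
  comp <- list(
    nutrition_inpatient = if (treated) inhosp_days * costs$nutrition_inpatient_per_day else 0,
    ward = d[["WARD"]] * costs$ward_per_day,
    icu = d[["ICU"]] * costs$icu_per_day,
    complication = d[["COMPLICATION"]] * costs$complication_per_day,
    nutrition_outpatient = if (treated) {
      costs$outpatient_fraction * d[["DISCHARGED"]] * costs$nutrition_outpatient_per_day
    } else 0
  )
  structure(c(comp, list(total = sum(unlist(comp)), arm = arm)),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Cost breakdown (%s arm), SF:\n", x$arm))
  for (k in cost_components()) cat(sprintf("  %-22s %12.0f\n", k, x[[k]]))
  cat(sprintf("  %-22s %12.0f\n", "total", x$total))
  invisible(x)
}

cost_components <- function() {
  c("nutrition_inpatient", "ward", "icu", "complication", "nutrition_outpatient")
}

#' Quality-adjusted life days
#'
#' Weighted sum of per-state life days with the per-state daily utility
#' weights; death contributes zero.
#'
#' @param tallies A `state_tallies`.
#' @param weights A [utility_weights()].
#' @return List with `per_state` QALDs (named) and `total`.
#' @export
accrue_utilities <- function(tallies, weights = utility_weights()) {
  stopifnot(inherits(tallies, "state_tallies"), inherits(weights, "utility_weights"))
  per_state <- tallies$life_days * unclass(weights)[alive_states()]
  list(per_state = per_state, total = sum(per_state))
}

#' Incremental cost-effectiveness ratio
#'
#' Ratio of an incremental cost to an incremental effect, with the usual
#' cost-effectiveness-plane classification: `dominant` when the strategy
#' saves cost and gains effect, `dominated` when it adds cost and loses
#' effect, `trade-off` otherwise. A zero effect difference makes the ratio
#' undefined, which is flagged rather than thrown.
#'
#' @param delta_cost Incremental cost (SF).
#' @param delta_effect Incremental effect (life days or life years).
#' @return Object of class `icer`: list with `value` (SF per effect unit;
#'   `NA` when undefined), `quadrant`, `defined`, and the inputs.
#' @export
#' @examples
#' icer(15159, 5.77)   # trade-off, about 2627 SF per life day
#' icer(-6214, 4.11)   # dominant: cost saving and life days gained
icer <- function(delta_cost, delta_effect) {
  defined <- is.finite(delta_effect) && delta_effect != 0
  quadrant <- if (!defined) {
    "undefined"
  } else if (delta_cost < 0 && delta_effect > 0) {
    "dominant"
  } else if (delta_cost > 0 && delta_effect < 0) {
    "dominated"
  } else {
    "trade-off"
  }
  structure(list(
    value = if (defined) delta_cost / delta_effect else NA_real_,
    quadrant = quadrant,
    defined = defined,
    delta_cost = delta_cost,
    delta_effect = delta_effect
  ), class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("ICER: %.2f SF per effect unit (%s)\n", x$value, x$quadrant))
  } else {
    cat("ICER: undefined (zero effect difference)\n")
  }
  invisible(x)
}

#' Incremental table of the two arms
#'
#' Per-component incremental costs and life days (intervention minus
#' control) with component ICERs, mirroring the base-case incremental
#' report: ward, ICU and complication rows carry their state costs and life
#' days; the post-discharge row carries discharged life days together with
#' the outpatient nutrition cost; inpatient nutritional support is its own
#' cost row with no life-day denominator.
#'
#' @param intv,ctrl Per-arm lists with elements `tallies` (a
#'   `state_tallies`) and `breakdown` (a `cost_breakdown`), as returned by
#'   [arm_result()].
#' @return Object of class `incremental_result`: a data frame with columns
#'   `component`, `delta_cost`, `delta_life_days`, `icer`, plus attributes
#'   `total` (an [icer()] for the totals row) and
#'   `complication_avoidance` (an [icer()] framing avoided complication
#'   days as the effect gained).
#' @export
incremental_table <- function(intv, ctrl) {
  stopifnot(inherits(intv$tallies, "state_tallies"),
            inherits(ctrl$tallies, "state_tallies"))
  if (intv$tallies$horizon != ctrl$tallies$horizon) {
    stop("arms were run over different horizons", call. = FALSE)
  }
  dd <- intv$tallies$life_days - ctrl$tallies$life_days
  dc <- function(k) intv$breakdown[[k]] - ctrl$breakdown[[k]]
  rows <- data.frame(
    component = c("nutrition_inpatient", "ward", "icu", "complication",
                  "post_discharge"),
    delta_cost = c(dc("nutrition_inpatient"), dc("ward"), dc("icu"),
                   dc("complication"), dc("nutrition_outpatient")),
    delta_life_days = c(NA, dd[["WARD"]], dd[["ICU"]], dd[["COMPLICATION"]],
                        dd[["DISCHARGED"]]),
    stringsAsFactors = FALSE
  )
  rows$icer <- ifelse(!is.na(rows$delta_life_days) & rows$delta_life_days != 0,
                      rows$delta_cost / rows$delta_life_days, NA_real_)
  total_cost <- sum(rows$delta_cost)
  total_days <- sum(rows$delta_life_days, na.rm = TRUE)
  structure(rows,
            class = c("incremental_result", "data.frame"),
            total = icer(total_cost, total_days),
            complication_avoidance = icer(dc("complication"),
                                          -dd[["COMPLICATION"]]))
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("Incremental results (intervention - control):\n")
  print.data.frame(transform(as.data.frame(x),
                             delta_cost = round(delta_cost),
                             delta_life_days = round(delta_life_days, 2),
                             icer = round(icer)), row.names = FALSE)
  tot <- attr(x, "total")
  cat(sprintf("Total: %+.0f SF, %+.2f life days, ICER %.0f SF/life day (%s)\n",
              tot$delta_cost, tot$delta_effect, tot$value, tot$quadrant))
  invisible(x)
}

#' Compute one arm end-to-end from tallies
#'
#' Convenience bundling of cost accrual and utility accrual for one arm.
#'
#' @param tallies A `state_tallies`.
#' @param costs A [cost_inputs()].
#' @param arm Arm label.
#' @param weights A [utility_weights()].
#' @return List with `tallies`, `breakdown`, `utilities`, and `arm`.
#' @export
arm_result <- function(tallies, costs, arm, weights = utility_weights()) {
  list(tallies = tallies,
       breakdown = accrue_costs(tallies, costs, arm),
       utilities = accrue_utilities(tallies, weights),
       arm = arm)
}

#' Deterministic sensitivity analysis over nutrition price and continuation
#'
#' Re-runs cost accrual and the incremental table over the cross of a
#' supplement-price grid (applied to both in- and outpatient nutritional
#' support, SF/day) and an outpatient continuation-fraction grid, holding
#' the life-day tallies fixed. The default grids are the published scenario
#' bounds: 5 / 100 / 1000 SF per day and 20 / 50 / 100% continuation.
#'
#' @param intv_tallies,ctrl_tallies Per-arm `state_tallies`.
#' @param costs Base [cost_inputs()]; non-nutrition unit costs are held at
#'   these values.
#' @param supplement_cost_grid Positive prices (SF/day).
#' @param fraction_grid Continuation fractions in `[0, 1]`.
#' @return Data frame, one row per scenario: `supplement_cost_per_day`,
#'   `outpatient_fraction`, `nutrition_inpatient`, `nutrition_outpatient`
#'   (intervention-arm SF over the horizon), `delta_cost`,
#'   `delta_life_days`, `icer_per_life_day`. The full
#'   [incremental_table()] objects are attached as attribute `details`.
#' @export
deterministic_sa <- function(intv_tallies, ctrl_tallies,
                             costs = cost_inputs(),
                             supplement_cost_grid = c(5, 100, 1000),
                             fraction_grid = c(0.2, 0.5, 1.0)) {
  if (!length(supplement_cost_grid) || !length(fraction_grid)) {
    stop("scenario grids must be non-empty", call. = FALSE)
  }
  if (any(supplement_cost_grid < 0)) {
    stop("supplement costs must be non-negative", call. = FALSE)
  }
  grid <- expand.grid(supplement_cost_per_day = supplement_cost_grid,
                      outpatient_fraction = fraction_grid,
                      KEEP.OUT.ATTRS = FALSE)
  details <- vector("list", nrow(grid))
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- costs
    ci$nutrition_inpatient_per_day <- grid$supplement_cost_per_day[i]
    ci$nutrition_outpatient_per_day <- grid$supplement_cost_per_day[i]
    ci$outpatient_fraction <- grid$outpatient_fraction[i]
    intv <- arm_result(intv_tallies, ci, "intervention")
    ctrl <- arm_result(ctrl_tallies, ci, "control")
    inc <- incremental_table(intv, ctrl)
    details[[i]] <<- inc
    tot <- attr(inc, "total")
    data.frame(grid[i, , drop = FALSE],
               nutrition_inpatient = intv$breakdown$nutrition_inpatient,
               nutrition_outpatient = intv$breakdown$nutrition_outpatient,
               delta_cost = tot$delta_cost,
               delta_life_days = tot$delta_effect,
               icer_per_life_day = tot$value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "details") <- details
  res
}

#' Extrapolate the model to a longer horizon
#'
#' Runs both arms' cohorts to `horizon` daily cycles with unchanged
#' (time-homogeneous) transition matrices, accrues as in the base case, and
#' reports the incremental result with the total ICER re-expressed per life
#' year (`delta_life_days / 365` as the effect denominator).
#'
#' @param M_intv,M_ctrl Valid arm [transition_matrix()] objects.
#' @param costs A [cost_inputs()].
#' @param weights A [utility_weights()].
#' @param horizon Days (default 365, the one-year extrapolation).
#' @return List with per-arm `arm_result()`s (`intervention`, `control`),
#'   the `incremental` table, `icer_per_life_year` (an [icer()] with effect
#'   in life years), and `horizon`.
#' @export
extrapolate <- function(M_intv, M_ctrl, costs = cost_inputs(),
                        weights = utility_weights(), horizon = 365) {
  intv_t <- tally_life_days(run_cohort(M_intv, horizon))
  ctrl_t <- tally_life_days(run_cohort(M_ctrl, horizon))
  intv <- arm_result(intv_t, costs, "intervention", weights)
  ctrl <- arm_result(ctrl_t, costs, "control", weights)
  inc <- incremental_table(intv, ctrl)
  tot <- attr(inc, "total")
  list(intervention = intv, control = ctrl, incremental = inc,
       icer_per_life_year = icer(tot$delta_cost, tot$delta_effect / 365),
       horizon = horizon)
}

#' Maximum nutrition cost admissible at a willingness-to-pay threshold
#'
#' Solves for the largest inpatient nutritional-support spend `c` (SF, total
#' over the horizon, per patient) at which the strategy stays under a
#' willingness-to-pay threshold expressed per life year. The numerator of
#' the ratio being thresholded is `c` plus the committed outpatient
#' nutrition cost and, in `"full-incremental"` mode, all other incremental
#' (non-nutrition) costs; the denominator is the incremental effect in life
#' years. The ratio is strictly increasing in `c`, so the root is found by
#' bisection to within 1 SF per life year on the ratio.
#'
#' @param delta_life_years Incremental effect (life years, > 0 for a
#'   solution to exist).
#' @param wtp Willingness-to-pay threshold (SF per life year, > 0).
#' @param outpatient_cost Committed outpatient nutrition cost (SF) at the
#'   scenario's continuation fraction; rises with the fraction, so the
#'   admissible maximum falls.
#' @param other_incremental_cost Non-nutrition incremental costs (SF);
#'   enters only in `"full-incremental"` mode.
#' @param mode `"nutrition-only"` (default) or `"full-incremental"`.
#' @return List with `max_cost` (SF; `NA` when infeasible),
#'   `achieved_icer`, `feasible`, `mode`, and `wtp`.
#' @export
#' @examples
#' threshold_nutrition_cost(1, wtp = 100000)$max_cost  # == wtp
threshold_nutrition_cost <- function(delta_life_years, wtp,
                                     outpatient_cost = 0,
                                     other_incremental_cost = 0,
                                     mode = c("nutrition-only",
                                              "full-incremental")) {
  mode <- match.arg(mode)
  stopifnot(wtp > 0)
  base <- outpatient_cost +
    if (mode == "full-incremental") other_incremental_cost else 0
  if (!is.finite(delta_life_years) || delta_life_years <= 0) {
    return(list(max_cost = NA_real_, achieved_icer = NA_real_,
                feasible = FALSE, mode = mode, wtp = wtp))
  }
  ratio <- function(c) (c + base) / delta_life_years
  if (ratio(0) > wtp) {  # committed costs alone already exceed the threshold
    return(list(max_cost = NA_real_, achieved_icer = ratio(0),
                feasible = FALSE, mode = mode, wtp = wtp))
  }
  lo <- 0
  hi <- wtp * delta_life_years + abs(base) + 1
  while (ratio(hi) < wtp) hi <- hi * 2
  tol <- 0.5 * delta_life_years  # 1 SF/life-year on the ratio
  while (hi - lo > min(tol, 1e-6 * hi)) {
    mid <- (lo + hi) / 2
    if (ratio(mid) <= wtp) lo <- mid else hi <- mid
  }
  cstar <- (lo + hi) / 2
  list(max_cost = cstar, achieved_icer = ratio(cstar), feasible = TRUE,
       mode = mode, wtp = wtp)
}
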