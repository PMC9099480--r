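#' Run the base-case analysis from a configuration
#'
#' Resolves both arms (calibrating transition matrices where the
#' configuration asks for it), accrues costs and utilities, forms the
#' incremental table, and — when `outdir` is given — writes the per-arm
#' base-case report, the incremental report and a machine-readable JSON
#' bundle. All arithmetic is unrounded; rounding (costs to whole SF, days
#' and utilities to 2 decimals) happens only when reports are rendered, so
#' reports are regenerable byte-identically from the bundle.
#'
#' @param config A [read_config()] object.
#' @param outdir Optional output directory (created if missing).
#' @return List with `intervention`, `control` (per-arm [arm_result()]s plus
#'   resolution metadata), `incremental`, and `bundle` (the JSON-ready
#'   list).
#' @export
run_base_case <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  costs <- config_costs(config)
  weights <- config_weights(config)
  arms <- lapply(c(intervention = "intervention", control = "control"),
                 function(a) {
    r <- stage(paste0("resolve-", a), resolve_arm(config, a))
    c(arm_result(r$tallies, costs, a, weights), r[c("matrix", "source")])
  })
  inc <- incremental_table(arms$intervention, arms$control)
  bundle <- base_case_bundle(config, arms, inc)
  log_run(config, "base case")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(bundle, file.path(outdir, "bundle.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_reports_from_bundle(bundle, outdir)
  }
  list(intervention = arms$intervention, control = arms$control,
       incremental = inc, bundle = bundle)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

log_run <- function(config, what) {
  message(sprintf("[nutricea %s] %s | config md5 %s | seeds cal=%s psa=%s trial=%s",
                  as.character(utils::packageVersion("nutricea")), what,
                  config$config_md5 %||% "<none>",
                  config$seeds$calibration, config$seeds$psa,
                  config$seeds$trial))
}

base_case_bundle <- function(config, arms, inc) {
  per_arm <- lapply(arms, function(x) {
    list(source = x$source,
         life_days = as.list(x$tallies$life_days),
         dead_fraction = x$tallies$dead_fraction_at_end,
         utilities = as.list(x$utilities$per_state),
         total_utility = x$utilities$total,
         costs = x$breakdown[cost_components()],
         total_cost = x$breakdown$total)
  })
  tot <- attr(inc, "total")
  list(package_version = as.character(utils::packageVersion("nutricea")),
       config_md5 = config$config_md5 %||% NA,
       horizon = config$horizon,
       seeds = config$seeds,
       arms = per_arm,
       incremental = list(
         components = as.data.frame(inc),
         total = list(delta_cost = tot$delta_cost,
                      delta_life_days = tot$delta_effect,
                      icer_per_life_day = tot$value,
                      quadrant = tot$quadrant)))
}

#' Render the base-case reports from a JSON bundle
#'
#' The two delimited reports (per-arm base case, incremental) are pure
#' functions of the bundle, with rounding applied only here: costs to the
#' nearest whole SF, life days and utilities to two decimals. Re-rendering
#' a stored `bundle.json` therefore reproduces the reports byte for byte.
#'
#' @param bundle A bundle list (from [run_base_case()]) or the path of a
#'   `bundle.json`.
#' @param outdir Output directory.
#' @return Paths of the written reports, invisibly.
#' @export
write_reports_from_bundle <- function(bundle, outdir) {
  if (is.character(bundle)) {
    bundle <- jsonlite::read_json(bundle, simplifyVector = TRUE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t2 <- render_base_case_table(bundle)
  t3 <- render_incremental_table(bundle)
  f2 <- file.path(outdir, "base_case_by_state.tsv")
  f3 <- file.path(outdir, "incremental.tsv")
  utils::write.table(t2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(t3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f2, f3))
}

round2 <- function(x) sprintf("%.2f", x)
round0 <- function(x) sprintf("%.0f", x)

#' @rdname write_reports_from_bundle
#' @export
render_base_case_table <- function(bundle) {
  iv <- bundle$arms$intervention
  cn <- bundle$arms$control
  item <- c("nutrition_support", "days_in_normal_ward", "days_in_icu",
            "complications", "post_discharge_life_days", "total")
  ld <- function(a) c(NA, a$life_days$WARD, a$life_days$ICU,
                      a$life_days$COMPLICATION, a$life_days$DISCHARGED,
                      sum(unlist(a$life_days)))
  ut <- function(a) c(NA, a$utilities$WARD, a$utilities$ICU,
                      a$utilities$COMPLICATION, a$utilities$DISCHARGED,
                      a$total_utility)
  co <- function(a) c(a$costs$nutrition_inpatient, a$costs$ward, a$costs$icu,
                      a$costs$complication, a$costs$nutrition_outpatient,
                      a$total_cost)
  data.frame(
    cost_item = item,
    life_days_intervention = round2(ld(iv)),
    life_days_control = round2(ld(cn)),
    utilities_intervention = round2(ut(iv)),
    utilities_control = round2(ut(cn)),
    cost_sf_intervention = round0(co(iv)),
    cost_sf_control = round0(co(cn)),
    stringsAsFactors = FALSE
  )
}

#' @rdname write_reports_from_bundle
#' @export
render_incremental_table <- function(bundle) {
  comp <- bundle$incremental$components
  tot <- bundle$incremental$total
  data.frame(
    cost_item = c(comp$component, "total"),
    delta_cost_sf = round0(c(comp$delta_cost, tot$delta_cost)),
    delta_life_days = ifelse(
      is.na(c(comp$delta_life_days, tot$delta_life_days)), "",
      round2(c(comp$delta_life_days, tot$delta_life_days))),
    icer_sf_per_life_day = ifelse(
      is.na(c(comp$icer, tot$icer_per_life_day)), "",
      round0(c(comp$icer, tot$icer_per_life_day))),
    stringsAsFactors = FALSE
  )
}

#' Run every analysis of the evaluation from one configuration
#'
#' One call produces the complete result set: the base case, the
#' deterministic sensitivity analysis over the supplement-price and
#' continuation-fraction grids, the probabilistic sensitivity analysis, the
#' one-year extrapolation, and the willingness-to-pay threshold analysis.
#' Stages that need arm transition matrices (extrapolation, threshold) fail
#' with a stage-tagged error if both arms were configured as fixed tallies.
#'
#' @param config A [read_config()] object.
#' @param outdir Output directory for the report files (default: no files).
#' @return Named list: `base_case`, `deterministic_sa`, `psa`,
#'   `extrapolation`, `threshold`.
#' @export
run_full_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  costs <- config_costs(config)
  weights <- config_weights(config)
  base <- stage("base-case", run_base_case(config, outdir))
  iv <- base$intervention
  cn <- base$control

  sa <- stage("deterministic-sa", deterministic_sa(
    iv$tallies, cn$tallies, costs,
    supplement_cost_grid = unlist(config$grids$supplement_cost),
    fraction_grid = unlist(config$grids$outpatient_fraction)))

  psa <- stage("psa", run_psa(iv$tallies, cn$tallies,
                              n_draws = config$psa$n_draws,
                              seed = config$seeds$psa,
                              costs = costs))

  if (is.null(iv$matrix) || is.null(cn$matrix)) {
    stop("stage extrapolation: arm transition matrices are required ",
         "(configure arms via targets or matrix_file)", call. = FALSE)
  }
  ext <- stage("extrapolation", extrapolate(
    iv$matrix, cn$matrix, costs, weights,
    horizon = config$extrapolation_horizon))

  thr <- stage("threshold", threshold_analysis(
    ext, costs, wtp = config$wtp_per_life_year,
    fraction_grid = unlist(config$grids$outpatient_fraction),
    mode = config$threshold_mode))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sa, file.path(outdir, "deterministic_sa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_psa_draws(psa, file.path(outdir, "psa_draws.tsv"))
    jsonlite::write_json(
      list(n_draws = psa$n_draws, seed = psa$seed,
           mean_delta_cost = psa$mean_delta_cost,
           ci_delta_cost = as.list(psa$ci_delta_cost),
           mean_icer = psa$mean_icer, ci_icer = as.list(psa$ci_icer)),
      file.path(outdir, "psa_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(as.data.frame(ext$incremental),
                       file.path(outdir, "extrapolation_incremental.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(thr, file.path(outdir, "threshold.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(base_case = base, deterministic_sa = sa, psa = psa,
       extrapolation = ext, threshold = thr)
}

#' Willingness-to-pay threshold analysis over continuation fractions
#'
#' For each outpatient continuation fraction, computes the committed
#' outpatient nutrition cost over the extrapolated horizon and solves for
#' the maximum admissible inpatient nutritional-support spend under the
#' willingness-to-pay threshold (see [threshold_nutrition_cost()]). The
#' admissible maximum is non-increasing in the continuation fraction.
#'
#' @param ext An [extrapolate()] result for the two arms.
#' @param costs A [cost_inputs()] (supplies the outpatient price per day).
#' @param wtp Threshold in SF per life year.
#' @param fraction_grid Continuation fractions.
#' @param mode Passed to [threshold_nutrition_cost()].
#' @return Data frame: `outpatient_fraction`, `outpatient_cost_sf`,
#'   `delta_life_years`, `max_nutrition_cost_sf`, `mode`.
#' @export
threshold_analysis <- function(ext, costs = cost_inputs(), wtp = 1e5,
                               fraction_grid = c(0.2, 0.5, 1.0),
                               mode = "nutrition-only") {
  tot <- attr(ext$incremental, "total")
  dly <- tot$delta_effect / 365
  discharged <- ext$intervention$tallies$life_days[["DISCHARGED"]]
  # non-nutrition incremental cost (ward + icu + complication rows)
  comp <- as.data.frame(ext$incremental)
  other <- sum(comp$delta_cost[comp$component %in%
                                 c("ward", "icu", "complication")])
  rows <- lapply(fraction_grid, function(f) {
    outp <- f * discharged * costs$nutrition_outpatient_per_day
    th <- threshold_nutrition_cost(dly, wtp = wtp, outpatient_cost = outp,
                                   other_incremental_cost = other,
                                   mode = mode)
    data.frame(outpatient_fraction = f, outpatient_cost_sf = outp,
               delta_life_years = dly,
               max_nutrition_cost_sf = th$max_cost, mode = mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
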