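#' Load and validate a run configuration
#'
#' The whole analysis is driven by one structured YAML file: horizon,
#' willingness-to-pay threshold, seeds, cost inputs, utility weights,
#' scenario grids, PSA size, and per-arm definitions. Each arm is defined by
#' exactly one of: `targets` (calibration targets — the default route),
#' `matrix_file` (a stored transition matrix), or `tallies` (fixed per-state
#' life days, for report-parity runs without a matrix). Validation fails
#' fast and names the offending key path. An example with all defaults ships
#' as `system.file("extdata", "default_config.yaml", package = "nutricea")`.
#'
#' @param file Path to the YAML configuration.
#' @param overrides Named list of top-level overrides (applied after
#'   loading; intended for grids and seeds).
#' @return Object of class `run_config`.
#' @export
read_config <- function(file, overrides = NULL) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  cfg <- yaml::read_yaml(file)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg$config_file <- normalizePath(file)
  cfg$config_md5 <- unname(tools::md5sum(file))
  validate_config(cfg)
}

need_key <- function(cfg, path) {
  node <- cfg
  for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (is.null(node[[k]])) {
      stop("missing config key: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

validate_config <- function(cfg) {
  horizon <- need_key(cfg, "horizon")
  if (horizon < 1) stop("config key horizon: must be >= 1", call. = FALSE)
  for (k in c("wtp_per_life_year", "threshold_mode", "extrapolation_horizon",
              "seeds.calibration", "seeds.psa", "seeds.trial",
              "psa.n_draws", "grids.supplement_cost",
              "grids.outpatient_fraction", "utility_weights")) {
    need_key(cfg, k)
  }
  for (k in c("nutrition_inpatient_per_day", "nutrition_outpatient_per_day",
              "ward_per_day", "icu_per_day", "complication_per_day",
              "outpatient_fraction")) {
    need_key(cfg, paste0("costs.", k))
  }
  arms <- need_key(cfg, "arms")
  if (!setequal(names(arms), c("intervention", "control"))) {
    stop("config key arms: exactly two arms named ",
         "'intervention' and 'control' are required", call. = FALSE)
  }
  for (a in names(arms)) {
    spec <- arms[[a]]
    kinds <- intersect(names(spec), c("targets", "matrix_file", "tallies"))
    if (length(kinds) != 1L) {
      stop("config key arms.", a, ": exactly one of targets/matrix_file/",
           "tallies is required", call. = FALSE)
    }
    if (kinds == "matrix_file" && !file.exists(spec$matrix_file)) {
      stop("config key arms.", a, ".matrix_file: file not found: ",
           spec$matrix_file, call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

config_costs <- function(cfg) {
  do.call(cost_inputs, cfg$costs)
}

config_weights <- function(cfg) {
  do.call(utility_weights, cfg$utility_weights)
}

# Resolve one arm to (tallies, matrix-or-NULL, provenance), calibrating
# where the config asks for it.
resolve_arm <- function(cfg, arm) {
  spec <- cfg$arms[[arm]]
  if (!is.null(spec$matrix_file)) {
    M <- read_matrix(spec$matrix_file)
    stop_if_invalid(M)
    tal <- tally_life_days(run_cohort(M, cfg$horizon))
    list(tallies = tal, matrix = M, source = "matrix_file")
  } else if (!is.null(spec$targets)) {
    tg <- calibration_targets(
      life_days = unlist(spec$targets$life_days),
      dead_fraction = need_key(spec, "targets.dead_fraction"),
      horizon = cfg$horizon)
    cal <- calibrate_arm(tg, seed = cfg$seeds$calibration +
                           match(arm, c("intervention", "control")))
    if (!cal$feasible) {
      stop("calibration for arm '", arm, "' is infeasible", call. = FALSE)
    }
    list(tallies = cal$tallies, matrix = cal$matrix, source = "calibration",
         calibration = cal)
  } else {
    tal <- state_tallies(unlist(spec$tallies$life_days),
                         dead_fraction_at_end =
                           spec$tallies$dead_fraction %||% NA_real_,
                         horizon = cfg$horizon)
    list(tallies = tal, matrix = NULL, source = "fixed_tallies")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration file
#'
#' Path of the YAML configuration encoding the base case: 180-day horizon,
#' published cost inputs, calibration targets for both arms, the scenario
#' grids, the 100,000 SF/life-year threshold, and the default seeds.
#'
#' @return File path.
#' @export
default_config_file <- function() {
  system.file("extdata", "default_config.yaml", package = "nutricea")
}
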