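#' @import methods
NULL

#' ParameterSet: every rate, probability, cost and strategy magnitude
#'
#' A `ParameterSet` holds the complete numeric input of the model as a nested
#' list of named blocks (`demography`, `natural_history`, `strategies`,
#' `economics`, `meta`), an uncertainty table (one row per parameter path that
#' carries a sampling distribution for probabilistic sensitivity analysis),
#' and metadata (schema version, simulation window, step size).
#'
#' Individual entries are addressed by dot-separated paths such as
#' `"natural_history.cfr_prehospital.acs_initial"`; see [getParam()] and
#' [setParam()].
#'
#' @slot values nested named list of parameter blocks.
#' @slot uncertainty data.frame with columns `path`, `dist`, `lo`, `hi`.
#' @slot meta list with at least `schema_version`, `start_year`, `end_year`,
#'   `dt`, `rollout_start`, `checkpoints`.
#' @exportClass ParameterSet
setClass("ParameterSet",
  representation(values = "list", uncertainty = "data.frame", meta = "list"))

setValidity("ParameterSet", function(object) {
  msg <- character()
  need <- c("schema_version", "start_year", "end_year", "dt",
            "rollout_start", "checkpoints")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste("meta missing:", paste(miss, collapse = ", ")))
  if (!is.null(object@meta$dt) && object@meta$dt <= 0)
    msg <- c(msg, "dt must be > 0")
  if (!is.null(object@meta$start_year) && !is.null(object@meta$end_year) &&
      object@meta$start_year >= object@meta$end_year)
    msg <- c(msg, "start_year must precede end_year")
  if (nrow(object@uncertainty) &&
      !all(c("path", "dist", "lo", "hi") %in% names(object@uncertainty)))
    msg <- c(msg, "uncertainty table needs columns path, dist, lo, hi")
  if (length(msg)) msg else TRUE
})

#' FlowSpec: one directed flow between compartments
#'
#' A flow drains a source (a stock or the external world) into a target
#' (a stock or an accumulator) at a non-negative rate in persons/year,
#' evaluated from the current state, the effective parameter values and time.
#' `bandShift = TRUE` marks cohort-ageing flows whose inflow is credited to
#' the next age band of the same stock. `countAcc` optionally names an
#' accumulator that records the same flow as an event count (for example an
#' admission flow that also increments a hospitalisation counter).
#'
#' @slot name flow identifier.
#' @slot source stock id or `"external"`.
#' @slot target stock id, accumulator id, or `"external"`.
#' @slot rateFn `function(S, prm, t)` returning persons/year per age band.
#' @slot countAcc accumulator id or `NA_character_`.
#' @slot bandShift logical; inflow goes to the next age band.
#' @exportClass FlowSpec
setClass("FlowSpec",
  representation(name = "character", source = "character",
                 target = "character", rateFn = "function",
                 countAcc = "character", bandShift = "logical"),
  prototype(countAcc = NA_character_, bandShift = FALSE))

#' ModelSpec: declarative wiring of a stock-and-flow model
#'
#' Stocks hold person counts per age band; accumulators are sink counters
#' (deaths by place of death, hospitalisations by type, demographic entries
#' and exits). All stocks carry the unit tag `"persons"`; accumulators carry
#' `"persons"` or `"currency"`. Flows are [FlowSpec-class] objects.
#'
#' @slot stocks character vector of stock identifiers.
#' @slot stockUnits named character, unit tag per stock.
#' @slot accumulators character vector of accumulator identifiers.
#' @slot accUnits named character, unit tag per accumulator.
#' @slot flows list of [FlowSpec-class].
#' @slot bands character vector of age-band labels.
#' @slot timeGrid named numeric: `start`, `end`, `dt` (years).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(stocks = "character", stockUnits = "character",
                 accumulators = "character", accUnits = "character",
                 flows = "list", bands = "character", timeGrid = "numeric"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  tg <- object@timeGrid
  if (!all(c("start", "end", "dt") %in% names(tg)))
    msg <- c(msg, "timeGrid needs start, end, dt")
  else {
    if (tg[["dt"]] <= 0) msg <- c(msg, "step size must be > 0")
    if (tg[["start"]] >= tg[["end"]]) msg <- c(msg, "start must precede end")
  }
  if (anyDuplicated(c(object@stocks, object@accumulators)))
    msg <- c(msg, "stock/accumulator identifiers must be unique")
  if (!all(object@stockUnits == "persons"))
    msg <- c(msg, "all stocks must carry unit 'persons'")
  if (!all(object@accUnits %in% c("persons", "currency")))
    msg <- c(msg, "accumulator units must be 'persons' or 'currency'")
  if (length(msg)) msg else TRUE
})

#' CompartmentState: person counts per compartment and age band
#'
#' @slot stocks numeric matrix, rows = stocks, columns = age bands; counts >= 0.
#' @slot acc numeric matrix of accumulator totals (same band layout).
#' @slot time calendar year (continuous).
#' @exportClass CompartmentState
setClass("CompartmentState",
  representation(stocks = "matrix", acc = "matrix", time = "numeric"))

setValidity("CompartmentState", function(object) {
  msg <- character()
  if (any(object@stocks < -1e-9)) msg <- c(msg, "negative stock count")
  if (length(object@time) != 1L) msg <- c(msg, "time must be scalar")
  if (length(msg)) msg else TRUE
})

#' StrategySpec: one policy strategy as a ramped parameter overlay
#'
#' A strategy multiplies targeted parameters by an eligibility-weighted,
#' ramp-scaled relative effect: at time `t` the factor applied to a targeted
#' parameter is `1 - e * f(t) * (1 - m)` where `m` is the full-effect
#' multiplier, `e` the eligible fraction, and `f(t)` the rollout fraction
#' (linear ramp over `rampDuration`, optionally smoothed by a first-order
#' risk lag with time constant `riskLag`, or an exponential glide for
#' prescribed-trajectory strategies).
#'
#' @slot name strategy identifier.
#' @slot group one of `"supportive_environment"`, `"acute_response"`,
#'   `"medication_treatment"`.
#' @slot targets list of `list(path, multiplier, eligible)`.
#' @slot rolloutStart calendar year rollout begins.
#' @slot rampDuration years to full effect (2-10 unless `rampOverride`).
#' @slot riskLag first-order delay time constant in years (0 = immediate).
#' @slot rampShape `"linear"` or `"exponential"`.
#' @slot rampOverride logical; permits rampDuration outside [2, 10].
#' @exportClass StrategySpec
setClass("StrategySpec",
  representation(name = "character", group = "character", targets = "list",
                 rolloutStart = "numeric", rampDuration = "numeric",
                 riskLag = "numeric", rampShape = "character",
                 rampOverride = "logical"),
  prototype(riskLag = 0, rampShape = "linear", rampOverride = FALSE))

setValidity("StrategySpec", function(object) {
  msg <- character()
  if (!object@group %in% c("supportive_environment", "acute_response",
                           "medication_treatment"))
    msg <- c(msg, "unknown strategy group")
  for (tg in object@targets) {
    if (!all(c("path", "multiplier", "eligible") %in% names(tg)))
      msg <- c(msg, "each target needs path, multiplier, eligible")
    else {
      if (tg$multiplier <= 0) msg <- c(msg, "multipliers must be > 0")
      if (tg$eligible < 0 || tg$eligible > 1)
        msg <- c(msg, "eligible fraction must lie in [0,1]")
    }
  }
  if (!object@rampOverride &&
      (object@rampDuration < 2 || object@rampDuration > 10))
    msg <- c(msg, "rampDuration must lie in [2,10] years unless overridden")
  if (object@riskLag < 0) msg <- c(msg, "riskLag must be >= 0")
  if (object@rampShape == "exponential" && object@riskLag > 0)
    msg <- c(msg, "exponential ramp already embeds its delay; riskLag must be 0")
  if (length(msg)) msg else TRUE
})

#' Scenario: a named set of active strategies
#'
#' `active` is a list whose elements are either strategy names (resolved
#' against [buildStrategyLibrary()] at simulation time, so sampled strategy
#' magnitudes propagate in the PSA) or explicit [StrategySpec-class] objects.
#' `overrides` is a named list of per-strategy overrides
#' (`rolloutStart`, `rampDuration`).
#'
#' @slot label scenario label (e.g. `"base_case"`, `"supportive_environment"`).
#' @slot active list of strategy names or StrategySpec objects.
#' @slot overrides named list of per-strategy overrides.
#' @exportClass Scenario
setClass("Scenario",
  representation(label = "character", active = "list", overrides = "list"),
  prototype(label = "base_case", active = list(), overrides = list()))

setValidity("Scenario", function(object) {
  nm <- vapply(object@active, function(a)
    if (is(a, "StrategySpec")) a@name else as.character(a), character(1))
  if (anyDuplicated(nm)) "strategy names must be unique within a scenario" else TRUE
})

#' Trajectory: recorded states, flows and accumulators of one simulation
#'
#' @slot times numeric vector of calendar years at every recorded step.
#' @slot stocks 3-d array stocks x bands x time.
#' @slot acc 3-d array accumulators x bands x time (cumulative, start 0).
#' @slot bands age-band labels.
#' @slot label scenario label of the run.
#' @slot dt integration step (years).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", stocks = "array", acc = "array",
                 bands = "character", label = "character", dt = "numeric"))

#' CalibrationTargets: annual administrative series to fit against
#'
#' @slot years contiguous calendar years (2011-2017 style).
#' @slot deaths annual CVD deaths, persons/year.
#' @slot hospitalisations annual CVD hospitalisations, persons/year.
#' @slot source free-text source tag.
#' @exportClass CalibrationTargets
setClass("CalibrationTargets",
  representation(years = "numeric", deaths = "numeric",
                 hospitalisations = "numeric", source = "character"))

setValidity("CalibrationTargets", function(object) {
  msg <- character()
  n <- length(object@years)
  if (length(object@deaths) != n || length(object@hospitalisations) != n)
    msg <- c(msg, "series lengths must match years")
  if (any(object@deaths <= 0) || any(object@hospitalisations <= 0))
    msg <- c(msg, "target series must be strictly positive")
  if (n > 1 && any(diff(object@years) != 1))
    msg <- c(msg, "years must be contiguous")
  if (length(msg)) msg else TRUE
})

#' PsaResult: probabilistic sensitivity analysis output
#'
#' @slot draws data.frame, one row per draw x outcome x checkpoint with `value`.
#' @slot point data.frame of the all-defaults run, same layout minus `draw`.
#' @slot summary data.frame: outcome, checkpoint, point, q25, median, q75.
#' @slot n number of draws.
#' @slot seed RNG seed used.
#' @exportClass PsaResult
setClass("PsaResult",
  representation(draws = "data.frame", point = "data.frame",
                 summary = "data.frame", n = "numeric", seed = "numeric"))

setValidity("PsaResult", function(object) {
  s <- object@summary
  if (nrow(s) && any(s$q25 > s$median | s$median > s$q75))
    "quartiles must be ordered q25 <= median <= q75" else TRUE
})
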