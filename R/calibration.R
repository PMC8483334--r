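#' @include uncertainty.R
NULL

#' Construct calibration targets
#'
#' @param years contiguous calendar years.
#' @param deaths annual CVD deaths (persons/year).
#' @param hospitalisations annual CVD hospitalisations (persons/year).
#' @param source free-text source tag.
#' @return A [CalibrationTargets-class].
#' @export
calibrationTargets <- function(years, deaths, hospitalisations,
                               source = "synthetic") {
  new("CalibrationTargets", years = as.numeric(years),
      deaths = unname(as.numeric(deaths)),
      hospitalisations = unname(as.numeric(hospitalisations)),
      source = source)
}

#' Read / write calibration targets as CSV
#'
#' Two-column-per-series layout: `year`, `deaths`, `hospitalisations`.
#'
#' @param targets a [CalibrationTargets-class].
#' @param file path.
#' @return `file` (write) or a [CalibrationTargets-class] (read).
#' @export
writeTargetsCSV <- function(targets, file) {
  utils::write.csv(data.frame(year = targets@years, deaths = targets@deaths,
                              hospitalisations = targets@hospitalisations),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTargetsCSV
#' @param source source tag for the read object.
#' @export
readTargetsCSV <- function(file, source = "file") {
  df <- utils::read.csv(file)
  calibrationTargets(df$year, df$deaths, df$hospitalisations, source)
}

#' Calibration loss
#'
#' Sum over target years and both series (deaths, hospitalisations) of
#' squared relative errors `((sim - obs) / obs)^2`. Relative errors put the
#' two differently scaled series on an equal footing and make the loss
#' unit-invariant; the loss is 0 iff the simulation matches exactly.
#'
#' @param traj a [Trajectory-class] covering the target years.
#' @param targets a [CalibrationTargets-class].
#' @return scalar loss >= 0.
#' @export
calibrationLoss <- function(traj, targets) {
  simD <- annualSeries(traj, "deaths_cvd")
  simH <- annualSeries(traj, "hospitalisations")
  yrs <- as.character(targets@years)
  if (!all(yrs %in% names(simD)))
    stop("trajectory does not cover target years ",
         paste(setdiff(yrs, names(simD)), collapse = ", "))
  sum(((simD[yrs] - targets@deaths) / targets@deaths)^2) +
    sum(((simH[yrs] - targets@hospitalisations) /
           targets@hospitalisations)^2)
}

#' Fit free scaling parameters to calibration targets
#'
#' Bounded minimisation of [calibrationLoss()] over a small set of free
#' multipliers applied to named parameter paths (typically global incidence,
#' recurrence and chronic-hospitalisation scales). Uses `stats::optim`
#' L-BFGS-B (no analytic gradients; finite differences), which is
#' deterministic given the start point. Only deterministic point-estimate
#' parameters are fitted; PSA distributions are not refit.
#'
#' @param params a [ParameterSet-class].
#' @param free named list: parameter path -> `c(lo, hi)` bounds for its
#'   multiplier (start value 1 clamped into bounds).
#' @param targets a [CalibrationTargets-class].
#' @param dt integration step used during fitting (default `params@meta$dt`).
#' @return list: `params` (fitted), `multipliers`, `start_loss`, `end_loss`,
#'   `residuals` (per-year relative errors), `convergence`.
#' @export
fitFreeParameters <- function(params, free, targets, dt = NULL) {
  stopifnot(length(free) >= 1, length(free) <= 8)
  if (is.null(dt)) dt <- params@meta$dt
  horizon <- max(targets@years) + 1 - params@meta$start_year
  paths <- names(free)
  lo <- vapply(free, `[`, numeric(1), 1)
  hi <- vapply(free, `[`, numeric(1), 2)
  base_vals <- lapply(paths, function(p) getParam(params, p))
  apply_mult <- function(m) {
    ps <- params
    for (i in seq_along(paths))
      ps <- setParam(ps, paths[i], base_vals[[i]] * m[i])
    ps
  }
  lossFn <- function(m) {
    traj <- simulateModel(apply_mult(m), horizon = horizon, dt = dt)
    l <- calibrationLoss(traj, targets)
    if (!is.finite(l)) stop("non-finite calibration loss at multipliers ",
                            paste(signif(m, 4), collapse = ", "))
    l
  }
  start <- pmin(pmax(rep(1, length(paths)), lo), hi)
  start_loss <- lossFn(start)
  fit <- stats::optim(start, lossFn, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(factr = 1e9, maxit = 60))
  end_loss <- min(fit$value, start_loss)
  best <- if (fit$value <= start_loss) fit$par else start
  fitted <- apply_mult(best)
  traj <- simulateModel(fitted, horizon = horizon, dt = dt)
  simD <- annualSeries(traj, "deaths_cvd")[as.character(targets@years)]
  simH <- annualSeries(traj,
                       "hospitalisations")[as.character(targets@years)]
  list(params = fitted,
       multipliers = stats::setNames(best, paths),
       start_loss = start_loss, end_loss = end_loss,
       residuals = data.frame(
         year = targets@years,
         deaths_rel_err = (simD - targets@deaths) / targets@deaths,
         hosp_rel_err = (simH - targets@hospitalisations) /
           targets@hospitalisations),
       convergence = fit$convergence)
}

#' Extreme-condition structural validation suite
#'
#' Drives the model to analytic limits and checks the forced outcome of
#' each: zero incidence leaves the CVD accumulators flat; 100% pre-hospital
#' case fatality produces no acute admissions; zero entry inflow (and
#' migration) decays the population towards zero; a zero discount rate
#' makes present value equal nominal value.
#'
#' @param params a [ParameterSet-class].
#' @param dt integration step (default `params@meta$dt`).
#' @return data.frame: `case`, `pass`, `detail`.
#' @export
extremeConditionSuite <- function(params, dt = NULL) {
  if (is.null(dt)) dt <- params@meta$dt
  nb <- length(AGE_BANDS)
  rows <- list()
  note <- function(case, pass, detail)
    rows[[length(rows) + 1L]] <<- data.frame(case = case, pass = pass,
                                             detail = detail)

  p0 <- params
  for (path in c("natural_history.incidence_initial.acs",
                 "natural_history.incidence_initial.stroke",
                 "natural_history.incidence_recurrent.acs",
                 "natural_history.incidence_recurrent.stroke",
                 "natural_history.chronic_hosp_rate",
                 "natural_history.community_death_rate"))
    p0 <- setParam(p0, path, rep(0, nb))
  p0 <- setParam(p0, "natural_history.initial_prevalence", rep(0, nb))
  traj <- simulateModel(p0, horizon = 10, dt = dt)
  cvd <- accSeries(traj, c("deaths_prehospital", "deaths_inhospital",
                           "deaths_community", "hosp_chronic"))
  note("zero_incidence", max(cvd) < 1e-6,
       paste("max CVD accumulator:", signif(max(cvd), 3)))

  p1 <- params
  for (k in c("acs_initial", "acs_recurrent", "stroke_initial",
              "stroke_recurrent"))
    p1 <- setParam(p1, paste0("natural_history.cfr_prehospital.", k), 1)
  traj <- simulateModel(p1, horizon = 10, dt = dt)
  adm <- sum(window_totals(traj, c("hosp_acs_initial", "hosp_acs_recurrent",
                                   "hosp_stroke_initial",
                                   "hosp_stroke_recurrent")))
  note("total_prehospital_fatality", adm < 1e-6,
       paste("acute admissions:", signif(adm, 3)))

  p2 <- setParam(params, "demography.entry_inflow_base", 0)
  p2 <- setParam(p2, "demography.net_migration_rate", rep(0, nb))
  traj <- simulateModel(p2, horizon = 150, dt = max(dt, 0.1))
  tot0 <- sum(traj@stocks[, , 1])
  totT <- sum(traj@stocks[, , dim(traj@stocks)[3]])
  note("zero_entry_decay", totT < 0.02 * tot0,
       paste0("population fraction remaining after 150 y: ",
              signif(totT / tot0, 3)))

  p3 <- setParam(params, "economics.discount_rate", 0)
  traj <- simulateModel(p3, horizon = 5, dt = dt)
  q <- qalyStream(traj, p3)
  w <- stock_utility(p3@values$economics)
  py <- person_year_steps(traj)
  nominal <- sum(colSums(py[names(w), , drop = FALSE] * w))
  note("zero_discount_identity", abs(q$total - nominal) < 1e-6 * nominal,
       paste("PV/nominal:", signif(q$total / nominal, 10)))

  do.call(rbind, rows)
}
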