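#' @include AllClasses.R AllGenerics.R params.R
NULL

#' Build a FlowSpec
#'
#' @param name flow identifier.
#' @param source stock id or `"external"`.
#' @param target stock id, accumulator id, or `"external"`.
#' @param rateFn `function(S, prm, t)` returning a non-negative persons/year
#'   rate per age band (`S` is the stock matrix, `prm` the effective
#'   parameter values, `t` the calendar year).
#' @param countAcc optional accumulator id that additionally counts this flow.
#' @param bandShift if `TRUE`, inflow is credited to the next age band
#'   (cohort ageing).
#' @return A [FlowSpec-class].
#' @export
flowSpec <- function(name, source, target, rateFn,
                     countAcc = NA_character_, bandShift = FALSE) {
  new("FlowSpec", name = name, source = source, target = target,
      rateFn = rateFn, countAcc = countAcc, bandShift = bandShift)
}

#' Build a ModelSpec
#'
#' @param stocks character vector of stock ids.
#' @param accumulators character vector of accumulator ids.
#' @param flows list of [FlowSpec-class] objects.
#' @param bands age-band labels.
#' @param timeGrid named numeric `c(start=, end=, dt=)` in calendar years.
#' @param accUnits named character of unit tags per accumulator; defaults to
#'   `"persons"` for all.
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(stocks, accumulators, flows, bands, timeGrid,
                      accUnits = NULL) {
  if (is.null(accUnits))
    accUnits <- stats::setNames(rep("persons", length(accumulators)),
                                accumulators)
  stockUnits <- stats::setNames(rep("persons", length(stocks)), stocks)
  new("ModelSpec", stocks = stocks, stockUnits = stockUnits,
      accumulators = accumulators, accUnits = accUnits, flows = flows,
      bands = bands, timeGrid = timeGrid)
}

#' Structural validation of a ModelSpec
#'
#' Checks, without running the model, that every flow endpoint resolves to a
#' declared stock, an accumulator, or the external world; that no flow drains
#' an accumulator (a currency or sink counter cannot feed a persons flow);
#' that units are consistent; and that every stock is reachable (touched by
#' at least one flow). Always returns a report; an empty `findings` table
#' means the spec is well-formed.
#'
#' @param spec a [ModelSpec-class].
#' @return list with `ok` (logical) and `findings`
#'   (data.frame: `kind`, `flow`, `detail`).
#' @export
setMethod("validateSpec", "ModelSpec", function(spec) {
  findings <- list()
  add <- function(kind, flow, detail)
    findings[[length(findings) + 1L]] <<-
      data.frame(kind = kind, flow = flow, detail = detail)
  ids_stock <- spec@stocks
  ids_acc <- spec@accumulators
  touched <- character()
  for (f in spec@flows) {
    if (f@source %in% ids_acc)
      add("unit_mismatch", f@name,
          paste0("accumulator '", f@source,
                 "' used as a flow source; sinks cannot drain"))
    else if (!(f@source %in% c(ids_stock, "external")))
      add("dangling_endpoint", f@name,
          paste0("source '", f@source, "' is not a declared stock"))
    if (!(f@target %in% c(ids_stock, ids_acc, "external")))
      add("dangling_endpoint", f@name,
          paste0("target '", f@target,
                 "' is not a declared stock or accumulator"))
    if (f@target %in% ids_acc && spec@accUnits[[f@target]] != "persons")
      add("unit_mismatch", f@name,
          paste0("persons flow cannot feed '", spec@accUnits[[f@target]],
                 "' accumulator '", f@target, "'"))
    if (!is.na(f@countAcc) && !(f@countAcc %in% ids_acc))
      add("dangling_endpoint", f@name,
          paste0("count accumulator '", f@countAcc, "' not declared"))
    touched <- c(touched, f@source, f@target)
  }
  unreachable <- setdiff(ids_stock, touched)
  for (s in unreachable)
    add("unreachable_stock", NA_character_,
        paste0("stock '", s, "' is touched by no flow"))
  findings <- if (length(findings)) do.call(rbind, findings)
    else data.frame(kind = character(), flow = character(),
                    detail = character())
  list(ok = nrow(findings) == 0L, findings = findings)
})

#' Construct a CompartmentState
#'
#' @param stocks matrix stocks x bands of person counts.
#' @param acc matrix accumulators x bands (defaults to zero).
#' @param time calendar year.
#' @param spec the [ModelSpec-class] (used for accumulator layout when
#'   `acc` is missing).
#' @return A [CompartmentState-class].
#' @export
compartmentState <- function(stocks, acc = NULL, time = 0, spec = NULL) {
  if (is.null(acc)) {
    stopifnot(!is.null(spec))
    acc <- matrix(0, length(spec@accumulators), ncol(stocks),
                  dimnames = list(spec@accumulators, colnames(stocks)))
  }
  new("CompartmentState", stocks = stocks, acc = acc, time = time)
}

# Pre-index flows against the spec so the integration loop does integer
# bookkeeping only. Returns parallel vectors over flows.
index_flows <- function(spec) {
  n <- length(spec@flows)
  src <- integer(n); tgt <- integer(n); tgt_acc <- integer(n)
  cnt <- integer(n); shift <- logical(n)
  fns <- vector("list", n)
  for (i in seq_len(n)) {
    f <- spec@flows[[i]]
    src[i] <- match(f@source, spec@stocks, nomatch = 0L)
    tgt[i] <- match(f@target, spec@stocks, nomatch = 0L)
    tgt_acc[i] <- match(f@target, spec@accumulators, nomatch = 0L)
    cnt[i] <- if (is.na(f@countAcc)) 0L
      else match(f@countAcc, spec@accumulators)
    shift[i] <- f@bandShift
    fns[[i]] <- f@rateFn
  }
  list(n = n, src = src, tgt = tgt, tgt_acc = tgt_acc, cnt = cnt,
       shift = shift, fns = fns,
       names = vapply(spec@flows, function(f) f@name, character(1)))
}

# One explicit-Euler step on raw matrices. Outflows from a (stock, band) cell
# are jointly capped at its content and scaled proportionally on breach, which
# preserves branching fractions and non-negativity. Returns list(S, A).
step_raw <- function(S, A, idx, prm, t, dt, check = TRUE) {
  nb <- ncol(S)
  rates <- matrix(0, idx$n, nb)
  for (i in seq_len(idx$n)) {
    r <- idx$fns[[i]](S, prm, t)
    if (check && any(r < 0))
      stop("rate rule '", idx$names[i], "' returned a negative rate at t = ", t)
    rates[i, ] <- r
  }
  # joint outflow cap per source cell
  out <- matrix(0, nrow(S), nb)
  for (i in seq_len(idx$n)) if (idx$src[i] > 0L)
    out[idx$src[i], ] <- out[idx$src[i], ] + rates[i, ]
  scale <- matrix(1, nrow(S), nb)
  breach <- out * dt > S
  if (any(breach))
    scale[breach] <- S[breach] / (out[breach] * dt)
  for (i in seq_len(idx$n)) if (idx$src[i] > 0L)
    rates[i, ] <- rates[i, ] * scale[idx$src[i], ]
  newS <- S
  for (i in seq_len(idx$n)) {
    flux <- rates[i, ] * dt
    if (idx$src[i] > 0L)
      newS[idx$src[i], ] <- newS[idx$src[i], ] - flux
    if (idx$shift[i]) {
      # cohort ageing: inflow credited to the next band of the target stock
      newS[idx$tgt[i], -1L] <- newS[idx$tgt[i], -1L] + flux[-nb]
    } else if (idx$tgt[i] > 0L) {
      newS[idx$tgt[i], ] <- newS[idx$tgt[i], ] + flux
    } else if (idx$tgt_acc[i] > 0L) {
      A[idx$tgt_acc[i], ] <- A[idx$tgt_acc[i], ] + flux
    }
    if (idx$cnt[i] > 0L)
      A[idx$cnt[i], ] <- A[idx$cnt[i], ] + flux
  }
  if (check && any(newS < -1e-7 * max(S, 1)))
    stop("negative stock after step at t = ", t,
         " (outflow capping failure)")
  newS[newS < 0] <- 0
  list(S = newS, A = A)
}

#' Advance a CompartmentState by one Euler step
#'
#' Each stock changes by `(inflows - outflows) * dt`; outflows from a stock
#' are jointly capped at its current content (proportional scaling on
#' breach); accumulators only increase.
#'
#' @param state a [CompartmentState-class].
#' @param spec a [ModelSpec-class].
#' @param prm effective parameter values (the `values` list of a
#'   [ParameterSet-class], already strategy-adjusted).
#' @param dt step size in years (> 0).
#' @return The updated [CompartmentState-class] at `time + dt`.
#' @export
stepState <- function(state, spec, prm, dt) {
  stopifnot(dt > 0)
  idx <- index_flows(spec)
  res <- step_raw(state@stocks, state@acc, idx, prm, state@time, dt)
  new("CompartmentState", stocks = res$S, acc = res$A,
      time = state@time + dt)
}

#' Simulate a model over a horizon
#'
#' Deterministic explicit-Euler integration of `spec` from `initial`,
#' recording state and all accumulators at every step. At each step the
#' effective parameters are obtained from [effectiveParameters()] before the
#' flows are evaluated, so ramped strategy overlays apply continuously.
#'
#' @param initial a [CompartmentState-class]; if `NULL`, built by
#'   [initialState()] from `params`.
#' @param spec a [ModelSpec-class]; if `NULL`, built by [cvdModelSpec()].
#' @param params a [ParameterSet-class].
#' @param scenario a [Scenario-class]; `NULL` or an empty scenario is the
#'   base case.
#' @param horizon years to simulate (a multiple of `dt`); defaults to the
#'   parameter set's full window.
#' @param dt step size in years; defaults to `params@meta$dt`.
#' @return A [Trajectory-class].
#' @export
simulateModel <- function(params, scenario = NULL, spec = NULL,
                          initial = NULL, horizon = NULL, dt = NULL) {
  if (is.null(spec)) spec <- cvdModelSpec(params)
  if (is.null(initial)) initial <- initialState(params, spec)
  if (is.null(dt)) dt <- params@meta$dt
  t0 <- initial@time
  if (is.null(horizon)) horizon <- params@meta$end_year - t0
  stopifnot(dt > 0, horizon >= 0)
  nstep <- round(horizon / dt)
  if (abs(nstep * dt - horizon) > 1e-8)
    stop("horizon must be a multiple of dt")
  strategies <- resolveScenario(scenario, params)
  label <- if (is.null(scenario)) "base_case" else scenario@label
  idx <- index_flows(spec)
  nb <- length(spec@bands)
  S <- initial@stocks; A <- initial@acc
  stocksArr <- array(0, c(nrow(S), nb, nstep + 1L),
                     dimnames = list(spec@stocks, spec@bands, NULL))
  accArr <- array(0, c(nrow(A), nb, nstep + 1L),
                  dimnames = list(spec@accumulators, spec@bands, NULL))
  stocksArr[, , 1L] <- S; accArr[, , 1L] <- A
  times <- t0 + dt * (0:nstep)
  for (k in seq_len(nstep)) {
    t <- times[k]
    prm <- effective_values(params, strategies, t)
    res <- tryCatch(step_raw(S, A, idx, prm, t, dt),
                    error = function(e)
                      stop("simulation failed at t = ", t, ": ",
                           conditionMessage(e), call. = FALSE))
    S <- res$S; A <- res$A
    stocksArr[, , k + 1L] <- S
    accArr[, , k + 1L] <- A
  }
  new("Trajectory", times = times, stocks = stocksArr, acc = accArr,
      bands = spec@bands, label = label, dt = dt)
}

#' @describeIn simulateModel Recorded time points of a trajectory.
#' @export
setMethod("trajTimes", "Trajectory", function(x) x@times)

#' @describeIn simulateModel Person counts of one stock over time
#'   (bands x time matrix).
#' @param stock stock id.
#' @export
setMethod("stockSeries", "Trajectory", function(x, stock)
  x@stocks[stock, , ])

#' @describeIn simulateModel Cumulative accumulator totals over time
#'   (summed over bands).
#' @param acc accumulator id (or vector; rows are summed).
#' @export
setMethod("accSeries", "Trajectory", function(x, acc) {
  m <- x@acc[acc, , , drop = FALSE]
  apply(m, 3, sum)
})

#' Annual series from a trajectory
#'
#' Differences the named cumulative accumulator at integer calendar years,
#' yielding persons/year for each year `[y, y+1)` covered by the trajectory.
#'
#' @param x a [Trajectory-class].
#' @param series accumulator id, or one of the composites
#'   `"deaths_cvd"` (pre-hospital + in-hospital + community) and
#'   `"hospitalisations"` (all acute + chronic).
#' @return named numeric vector, names = starting year of each interval.
#' @export
setMethod("annualSeries", "Trajectory", function(x, series) {
  cum <- cumulativeSeries(x, series)
  last <- x@times[length(x@times)]
  yrs <- floor(x@times[1]):floor(last)
  yrs <- yrs[yrs >= x@times[1] - 1e-9 & yrs + 1 <= last + 1e-9]
  at <- function(y) stats::approx(x@times, cum, xout = y)$y
  vals <- vapply(yrs, function(y) at(y + 1) - at(y), numeric(1))
  stats::setNames(vals, yrs)
})

# cumulative accumulator series (summed over bands), with composites
cumulativeSeries <- function(x, series) {
  comps <- list(
    deaths_cvd = c("deaths_prehospital", "deaths_inhospital",
                   "deaths_community"),
    hospitalisations = c("hosp_acs_initial", "hosp_acs_recurrent",
                         "hosp_stroke_initial", "hosp_stroke_recurrent",
                         "hosp_chronic"),
    hospitalisations_acute = c("hosp_acs_initial", "hosp_acs_recurrent",
                               "hosp_stroke_initial", "hosp_stroke_recurrent"))
  ids <- if (series %in% names(comps)) comps[[series]] else series
  accSeries(x, ids)
}

#' Long-format data.frame of a trajectory
#'
#' @param x a [Trajectory-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns `year`, `series`, `band`, `value`.
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  grid <- function(arr, what) {
    d <- dimnames(arr)
    data.frame(year = rep(x@times, each = dim(arr)[1] * dim(arr)[2]),
               series = rep(d[[1]], times = dim(arr)[2] * dim(arr)[3]),
               band = rep(rep(d[[2]], each = dim(arr)[1]),
                          times = dim(arr)[3]),
               value = as.vector(arr), kind = what)
  }
  rbind(grid(x@stocks, "stock"), grid(x@acc, "accumulator"))
}

#' Export a trajectory as long-format CSV
#'
#' @param traj a [Trajectory-class].
#' @param file output path.
#' @param annual if `TRUE` (default) write compact annual rows (stocks at
#'   integer years, annual flows for key accumulators); otherwise every step.
#' @return `file`, invisibly.
#' @export
exportTrajectoryCSV <- function(traj, file, annual = TRUE) {
  if (!annual) {
    utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
    return(invisible(file))
  }
  yrs <- floor(traj@times[1]):floor(traj@times[length(traj@times)])
  rows <- list()
  for (s in dimnames(traj@stocks)[[1]]) {
    tot <- apply(traj@stocks[s, , , drop = FALSE], 3, sum)
    v <- stats::approx(traj@times, tot, xout = yrs)$y
    rows[[length(rows) + 1L]] <-
      data.frame(year = yrs, series = s, value = v, kind = "stock")
  }
  for (a in c(dimnames(traj@acc)[[1]], "deaths_cvd", "hospitalisations")) {
    ann <- annualSeries(traj, a)
    rows[[length(rows) + 1L]] <-
      data.frame(year = as.numeric(names(ann)), series = a,
                 value = as.numeric(ann), kind = "annual_flow")
  }
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
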