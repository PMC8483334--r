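#' @include strategies.R
NULL

#' Discount factor
#'
#' `(1 + rate)^(-t)` for `t` years since the economic base year. Flows are
#' discounted at their mid-step accumulation time; times before the base
#' year yield factors > 1 but economic summaries only cumulate from the base
#' year onward.
#'
#' @param t years since the base year (vectorised; `t >= 0` for discounting
#'   proper).
#' @param rate annual discount rate (default 0.05); `rate <= -1` is rejected.
#' @return discount factor(s).
#' @export
discountFactor <- function(t, rate = 0.05) {
  if (rate <= -1) stop("discount rate must exceed -1")
  (1 + rate)^(-t)
}

# map each living stock to its utility-weight class
stock_utility <- function(ec) {
  u <- ec$utility
  w <- c(well = u$well, chronic = u$chronic, chronic_hosp = u$chronic_hosp)
  acute <- stats::setNames(rep(u$acute, 8),
                           c("pre_acs_init", "pre_acs_rec",
                             "pre_stroke_init", "pre_stroke_rec",
                             "hosp_acs_init", "hosp_acs_rec",
                             "hosp_stroke_init", "hosp_stroke_rec"))
  c(w, acute)
}

# per-step person-years per stock (stocks x steps), Euler-consistent:
# state at step start times dt
person_year_steps <- function(traj) {
  nt <- length(traj@times)
  py <- apply(traj@stocks[, , -nt, drop = FALSE], c(1, 3), sum) * traj@dt
  py
}

# per-step accumulator increments summed over bands (accs x steps)
acc_increment_steps <- function(traj) {
  tot <- apply(traj@acc, c(1, 3), sum)
  tot[, -1, drop = FALSE] - tot[, -ncol(tot), drop = FALSE]
}

mid_step_discount <- function(traj, ec) {
  nt <- length(traj@times)
  mid <- (traj@times[-nt] + traj@times[-1]) / 2
  discountFactor(mid - ec$base_year, ec$discount_rate)
}

#' Discounted QALY stream of a trajectory
#'
#' Per step, QALYs accrue as persons x utility weight x dt, discounted at
#' the mid-step time. Every living stock must have a utility weight.
#'
#' @param traj a [Trajectory-class].
#' @param params a [ParameterSet-class] (economics block).
#' @return list: `series` (discounted QALYs per step), `total`, and
#'   `times` (step midpoints).
#' @export
qalyStream <- function(traj, params) {
  ec <- params@values$economics
  w <- stock_utility(ec)
  py <- person_year_steps(traj)
  occupied <- rownames(py)[rowSums(py) > 0]
  missing <- setdiff(occupied, names(w))
  if (length(missing))
    stop("no utility weight for occupied stock(s): ",
         paste(missing, collapse = ", "))
  disc <- mid_step_discount(traj, ec)
  series <- colSums(py[names(w), , drop = FALSE] * w) * disc
  nt <- length(traj@times)
  list(series = series, total = sum(series),
       times = (traj@times[-nt] + traj@times[-1]) / 2)
}

#' Discounted cost and productivity streams of a trajectory
#'
#' Flow-linked costs (per hospitalisation by type, per rehabilitation
#' participant) and stock-linked costs (ongoing management of the
#' disease-free and chronic populations per person-year), each split across
#' the three payers (Commonwealth, state/territory, consumer); household
#' costs (out-of-pocket plus carer time per person-year); and friction-cost
#' productivity losses (chronic person-years in working-age bands plus a
#' per-death friction value, weighted by the working share of each band).
#' All streams are discounted at mid-step times.
#'
#' @param traj a [Trajectory-class].
#' @param params a [ParameterSet-class].
#' @return list with per-step vectors: `health_service` (total),
#'   `by_payer` (3 x steps matrix), `by_component` (hospitalisation,
#'   rehabilitation, management), `household`, `productivity_loss`, `times`.
#' @export
costStreams <- function(traj, params) {
  ec <- params@values$economics
  uc <- ec$unit_costs
  disc <- mid_step_discount(traj, ec)
  inc <- acc_increment_steps(traj)
  py <- person_year_steps(traj)

  hosp <- (inc["hosp_acs_initial", ] + inc["hosp_acs_recurrent", ]) *
    uc$acute_hosp$acs +
    (inc["hosp_stroke_initial", ] + inc["hosp_stroke_recurrent", ]) *
    uc$acute_hosp$stroke +
    inc["hosp_chronic", ] * uc$chronic_hosp
  rehab <- inc["acute_discharges", ] * ec$rehab_participation * uc$rehab
  mgmt <- py["well", ] * uc$management_py$well +
    (py["chronic", ] + py["chronic_hosp", ]) * uc$management_py$chronic

  hosp <- hosp * disc; rehab <- rehab * disc; mgmt <- mgmt * disc
  comp <- rbind(hospitalisation = hosp, rehabilitation = rehab,
                management = mgmt)
  payers <- c("commonwealth", "state_territory", "consumer")
  split_of <- function(cat) unlist(ec$payer_split[[cat]])[payers]
  by_payer <- outer(split_of("hosp"), hosp) +
    outer(split_of("rehab"), rehab) +
    outer(split_of("management"), mgmt)
  rownames(by_payer) <- payers

  hh <- (py["chronic", ] + py["chronic_hosp", ]) * ec$household_py$chronic +
    py["well", ] * ec$household_py$well
  hh <- hh * disc

  ws <- ec$productivity$working_share
  nt <- length(traj@times)
  chronic_py_b <- (traj@stocks["chronic", , -nt] +
                   traj@stocks["chronic_hosp", , -nt]) * traj@dt
  death_acc <- traj@acc["deaths_prehospital", , ] +
    traj@acc["deaths_inhospital", , ] + traj@acc["deaths_community", , ]
  death_inc_b <- death_acc[, -1, drop = FALSE] -
    death_acc[, -ncol(death_acc), drop = FALSE]
  prod_loss <- (colSums(chronic_py_b * ws) *
                  ec$productivity$value_per_chronic_py +
                colSums(death_inc_b * ws) *
                  ec$productivity$friction_per_death) * disc

  list(health_service = hosp + rehab + mgmt, by_payer = by_payer,
       by_component = comp, household = hh, productivity_loss = prod_loss,
       times = (traj@times[-nt] + traj@times[-1]) / 2)
}

#' Net benefit of a scenario against the base case
#'
#' At each checkpoint (years after the economic base year), cumulates the
#' discounted streams from the base year to the checkpoint and applies the
#' two accounting identities: net benefit (health system) = monetised QALY
#' gain minus the health-service cost delta (all payers); net benefit
#' (societal) = the health-system figure minus the household cost delta plus
#' the productivity gain. Implementation costs of the strategies themselves
#' are not modelled.
#'
#' @param scTraj scenario [Trajectory-class].
#' @param baseTraj base-case [Trajectory-class] on the same grid and
#'   parameter draw.
#' @param params a [ParameterSet-class].
#' @param checkpoints years after the base year (default
#'   `params@meta$checkpoints`).
#' @return data.frame, one row per checkpoint: `checkpoint`,
#'   `qaly_gain`, `monetised_qaly`, `health_cost_delta`,
#'   `cost_delta_commonwealth`, `cost_delta_state_territory`,
#'   `cost_delta_consumer`, `household_delta`, `productivity_gain`,
#'   `net_benefit_health_system`, `net_benefit_societal` (currency, AU$).
#' @export
netBenefit <- function(scTraj, baseTraj, params,
                       checkpoints = NULL) {
  if (!isTRUE(all.equal(scTraj@times, baseTraj@times)))
    stop("trajectories are on different time grids")
  ec <- params@values$economics
  if (is.null(checkpoints)) checkpoints <- params@meta$checkpoints
  q_sc <- qalyStream(scTraj, params); q_b <- qalyStream(baseTraj, params)
  c_sc <- costStreams(scTraj, params); c_b <- costStreams(baseTraj, params)
  tmid <- q_sc$times
  rows <- lapply(checkpoints, function(cp) {
    w <- tmid >= ec$base_year & tmid <= ec$base_year + cp
    qg <- sum(q_sc$series[w] - q_b$series[w])
    hs <- sum(c_sc$health_service[w] - c_b$health_service[w])
    payer <- rowSums(c_sc$by_payer[, w, drop = FALSE]) -
      rowSums(c_b$by_payer[, w, drop = FALSE])
    hh <- sum(c_sc$household[w] - c_b$household[w])
    pg <- sum(c_b$productivity_loss[w] - c_sc$productivity_loss[w])
    mq <- qg * ec$qaly_value
    data.frame(checkpoint = cp, qaly_gain = qg, monetised_qaly = mq,
               health_cost_delta = hs,
               cost_delta_commonwealth = payer[["commonwealth"]],
               cost_delta_state_territory = payer[["state_territory"]],
               cost_delta_consumer = payer[["consumer"]],
               household_delta = hh, productivity_gain = pg,
               net_benefit_health_system = mq - hs,
               net_benefit_societal = mq - hs - hh + pg)
  })
  do.call(rbind, rows)
}

#' Export net-benefit summaries in a strategy-group table layout
#'
#' Rows are scenarios (strategy groups), columns perspective x checkpoint,
#' values in AU$ billions with two decimals.
#'
#' @param summaries named list of data.frames from [netBenefit()] (names =
#'   scenario labels).
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
exportNetBenefitCSV <- function(summaries, file) {
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    out <- data.frame(scenario = nm)
    for (i in seq_len(nrow(s))) {
      cp <- s$checkpoint[i]
      out[[paste0("health_system_", cp, "y")]] <-
        round(s$net_benefit_health_system[i] / 1e9, 2)
      out[[paste0("societal_", cp, "y")]] <-
        round(s$net_benefit_societal[i] / 1e9, 2)
    }
    out
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
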