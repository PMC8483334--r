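#' @include demography.R
NULL

ACCUMULATORS <- c("deaths_prehospital", "deaths_inhospital",
                  "deaths_community", "deaths_noncvd",
                  "hosp_acs_initial", "hosp_acs_recurrent",
                  "hosp_stroke_initial", "hosp_stroke_recurrent",
                  "hosp_chronic", "acute_discharges",
                  "entries", "migration_in", "migration_out")

# Transient acute stages use fractional hazard allocation: a stage with mean
# residence tau and case fatality p exits at total hazard 1/tau, split into a
# death hazard p/tau and a continuation hazard (1-p)/tau. The branching
# probability is then exactly p for any dt -> 0, and the proportional outflow
# cap preserves the split at coarse dt.
stage_hazards <- function(p, tau) list(death = p / tau, onward = (1 - p) / tau)

check_prob <- function(p, what, t) {
  if (any(p < 0) || any(p > 1))
    stop(what, " outside [0,1] after strategy adjustment at t = ", t)
  p
}

#' Natural-history flow contributions
#'
#' Wires the CVD core: initial incidence (disease-free to acute
#' pre-hospital, by event type), recurrence (chronic community to acute
#' pre-hospital), pre-hospital branching between death and admission,
#' in-hospital branching between death and chronic survival (every acute
#' in-hospital survivor moves to the chronic community state; there is no
#' return to disease-free), chronic hospitalisation with a short in-hospital
#' stay, and chronic community CVD deaths. Admission flows increment the
#' hospitalisation accumulators; discharges increment `acute_discharges`.
#'
#' @return list of [FlowSpec-class] objects.
#' @export
naturalHistoryFlows <- function() {
  flows <- list()
  add <- function(f) flows[[length(flows) + 1L]] <<- f
  for (ev in c("acs", "stroke")) {
    ev_ <- ev
    add(flowSpec(paste0("incidence_initial_", ev_), "well",
                 paste0("pre_", ev_, "_init"),
                 local({ e <- ev_; function(S, prm, t)
                   prm$natural_history$incidence_initial[[e]] *
                     prm$natural_history$scale$incidence_initial *
                     S["well", ] })))
    add(flowSpec(paste0("incidence_recurrent_", ev_), "chronic",
                 paste0("pre_", ev_, "_rec"),
                 local({ e <- ev_; function(S, prm, t)
                   prm$natural_history$incidence_recurrent[[e]] *
                     prm$natural_history$scale$incidence_recurrent *
                     S["chronic", ] })))
    for (ir in c("init", "rec")) {
      key <- paste0(ev_, "_", if (ir == "init") "initial" else "recurrent")
      pre <- paste0("pre_", ev_, "_", ir)
      hos <- paste0("hosp_", ev_, "_", ir)
      hospAcc <- paste0("hosp_", key)
      add(flowSpec(paste0("prehospital_death_", ev_, "_", ir), pre,
                   "deaths_prehospital",
                   local({ k <- key; p_ <- pre; function(S, prm, t) {
                     nh <- prm$natural_history
                     p <- check_prob(nh$cfr_prehospital[[k]],
                                     "pre-hospital case fatality", t)
                     stage_hazards(p, nh$residence_prehospital)$death *
                       S[p_, ]
                   } })))
      add(flowSpec(paste0("admission_", ev_, "_", ir), pre, hos,
                   local({ k <- key; p_ <- pre; function(S, prm, t) {
                     nh <- prm$natural_history
                     p <- check_prob(nh$cfr_prehospital[[k]],
                                     "pre-hospital case fatality", t)
                     stage_hazards(p, nh$residence_prehospital)$onward *
                       S[p_, ]
                   } }),
                   countAcc = hospAcc))
      add(flowSpec(paste0("inhospital_death_", ev_, "_", ir), hos,
                   "deaths_inhospital",
                   local({ k <- key; h_ <- hos; e <- ev_
                     function(S, prm, t) {
                       nh <- prm$natural_history
                       p <- check_prob(nh$cfr_inhospital[[k]],
                                       "in-hospital case fatality", t)
                       stage_hazards(p, nh$residence_inhospital[[e]])$death *
                         S[h_, ]
                     } })))
      add(flowSpec(paste0("discharge_", ev_, "_", ir), hos, "chronic",
                   local({ k <- key; h_ <- hos; e <- ev_
                     function(S, prm, t) {
                       nh <- prm$natural_history
                       p <- check_prob(nh$cfr_inhospital[[k]],
                                       "in-hospital case fatality", t)
                       stage_hazards(p, nh$residence_inhospital[[e]])$onward *
                         S[h_, ]
                     } }),
                   countAcc = "acute_discharges"))
    }
  }
  add(flowSpec("chronic_admission", "chronic", "chronic_hosp",
               function(S, prm, t)
                 prm$natural_history$chronic_hosp_rate *
                   prm$natural_history$scale$chronic_hosp *
                   S["chronic", ],
               countAcc = "hosp_chronic"))
  add(flowSpec("chronic_inhospital_death", "chronic_hosp",
               "deaths_inhospital",
               function(S, prm, t) {
                 nh <- prm$natural_history
                 p <- check_prob(nh$chronic_inhosp_death_prob,
                                 "chronic in-hospital death probability", t)
                 stage_hazards(p, nh$chronic_inhosp_stay)$death *
                   S["chronic_hosp", ]
               }))
  add(flowSpec("chronic_discharge", "chronic_hosp", "chronic",
               function(S, prm, t) {
                 nh <- prm$natural_history
                 p <- nh$chronic_inhosp_death_prob
                 stage_hazards(p, nh$chronic_inhosp_stay)$onward *
                   S["chronic_hosp", ]
               }))
  add(flowSpec("community_death", "chronic", "deaths_community",
               function(S, prm, t)
                 prm$natural_history$community_death_rate * S["chronic", ]))
  flows
}

#' Assemble the full CVD ModelSpec
#'
#' Combines the demographic plumbing and the CVD natural-history core into
#' one declarative [ModelSpec-class] over the 5-year age bands 40-44 to 85+.
#'
#' @param params a [ParameterSet-class] (supplies the time grid).
#' @return A [ModelSpec-class].
#' @export
cvdModelSpec <- function(params) {
  modelSpec(stocks = LIVING_STOCKS,
            accumulators = ACCUMULATORS,
            flows = c(demographyFlows(), naturalHistoryFlows()),
            bands = AGE_BANDS,
            timeGrid = c(start = params@meta$start_year,
                         end = params@meta$end_year,
                         dt = params@meta$dt))
}

#' Initial CompartmentState from a ParameterSet
#'
#' The initial population per band is split between the disease-free and
#' chronic community stocks according to
#' `natural_history.initial_prevalence`; acute stages start empty.
#'
#' @param params a [ParameterSet-class].
#' @param spec the [ModelSpec-class] (built if missing).
#' @return A [CompartmentState-class] at `params@meta$start_year`.
#' @export
initialState <- function(params, spec = NULL) {
  if (is.null(spec)) spec <- cvdModelSpec(params)
  pop <- getParam(params, "demography.initial_population")
  prev <- getParam(params, "natural_history.initial_prevalence")
  nb <- length(AGE_BANDS)
  S <- matrix(0, length(spec@stocks), nb,
              dimnames = list(spec@stocks, AGE_BANDS))
  S["well", ] <- pop * (1 - prev)
  S["chronic", ] <- pop * prev
  compartmentState(S, time = params@meta$start_year, spec = spec)
}

#' Death-place split over a window
#'
#' Proportions of cumulative CVD deaths occurring in the pre-hospital stage
#' of acute events, in hospital, and in the community, computed from the
#' death accumulators over `window = c(from, to)` (calendar years).
#'
#' @param traj a [Trajectory-class].
#' @param window numeric length-2, calendar years; defaults to the full
#'   trajectory.
#' @return named numeric: `prehospital`, `inhospital`, `community`
#'   (non-negative, summing to 1).
#' @export
deathSplitSummary <- function(traj, window = NULL) {
  d <- window_totals(traj, c("deaths_prehospital", "deaths_inhospital",
                             "deaths_community"), window)
  if (sum(d) <= 0) stop("no CVD deaths in window")
  stats::setNames(d / sum(d), c("prehospital", "inhospital", "community"))
}

#' Acute/chronic hospitalisation mix over a window
#'
#' @inheritParams deathSplitSummary
#' @return named numeric: `acute`, `chronic`, summing to 1.
#' @export
hospitalisationMix <- function(traj, window = NULL) {
  acute <- sum(window_totals(traj, c("hosp_acs_initial", "hosp_acs_recurrent",
                                     "hosp_stroke_initial",
                                     "hosp_stroke_recurrent"), window))
  chronic <- window_totals(traj, "hosp_chronic", window)
  tot <- acute + chronic
  if (tot <= 0) stop("no hospitalisations in window")
  stats::setNames(c(acute, chronic) / tot, c("acute", "chronic"))
}

# cumulative accumulator increments over a calendar-year window
window_totals <- function(traj, accs, window = NULL) {
  if (is.null(window)) window <- range(traj@times)
  vapply(accs, function(a) {
    cum <- accSeries(traj, a)
    at <- function(y) stats::approx(traj@times, cum, xout = y)$y
    at(window[2]) - at(window[1])
  }, numeric(1))
}
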