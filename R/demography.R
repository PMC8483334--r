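#' @include engine.R
NULL

# Living stocks of the CVD structure (accumulators excluded).
LIVING_STOCKS <- c("well",
                   "pre_acs_init", "pre_acs_rec",
                   "pre_stroke_init", "pre_stroke_rec",
                   "hosp_acs_init", "hosp_acs_rec",
                   "hosp_stroke_init", "hosp_stroke_rec",
                   "chronic", "chronic_hosp")

AGE_BANDS <- c("40-44", "45-49", "50-54", "55-59", "60-64",
               "65-69", "70-74", "75-79", "80-84", "85+")
BAND_WIDTH <- 5

# entry inflow (persons/year turning 40) at calendar year t
entry_inflow <- function(prm, t) {
  d <- prm$demography
  d$entry_inflow_base * (1 + d$entry_growth)^(t - d$reference_year)
}

#' Demographic flow contributions
#'
#' Builds the open-population plumbing shared by every configuration of the
#' model: ageing-in of 40-year-olds (disease-free stock, first band only),
#' band-to-band cohort ageing at `1 / band width` per year for every living
#' stock (the open 85+ band has no ageing outflow), net migration
#' proportional to band population (split into an inflow and an outflow so
#' rates stay non-negative; applied to the disease-free stock by default,
#' configurable via `demography.migration_applies_to`), and competing
#' non-CVD mortality from every living stock.
#'
#' @param stocks character vector of living stock ids to wire.
#' @return list of [FlowSpec-class] objects.
#' @export
demographyFlows <- function(stocks = LIVING_STOCKS) {
  flows <- list()
  nb <- length(AGE_BANDS)
  flows[[length(flows) + 1L]] <- flowSpec(
    "entry", "external", "well",
    function(S, prm, t) c(entry_inflow(prm, t), rep(0, nb - 1L)),
    countAcc = "entries")
  for (s in stocks) {
    flows[[length(flows) + 1L]] <- local({
      s_ <- s
      flowSpec(paste0("ageing_", s_), s_, s_,
               function(S, prm, t) {
                 r <- S[s_, ] / BAND_WIDTH
                 r[length(r)] <- 0  # open terminal band
                 r
               },
               bandShift = TRUE)
    })
    flows[[length(flows) + 1L]] <- local({
      s_ <- s
      flowSpec(paste0("deaths_noncvd_", s_), s_, "deaths_noncvd",
               function(S, prm, t)
                 prm$demography$background_mortality * S[s_, ])
    })
  }
  migration_stocks <- function(prm)
    if (identical(prm$demography$migration_applies_to, "all"))
      LIVING_STOCKS else "well"
  for (s in stocks) {
    flows[[length(flows) + 1L]] <- local({
      s_ <- s
      flowSpec(paste0("migration_in_", s_), "external", s_,
               function(S, prm, t) {
                 if (!s_ %in% migration_stocks(prm)) return(rep(0, ncol(S)))
                 pmax(prm$demography$net_migration_rate, 0) * S[s_, ]
               },
               countAcc = "migration_in")
    })
    flows[[length(flows) + 1L]] <- local({
      s_ <- s
      flowSpec(paste0("migration_out_", s_), s_, "external",
               function(S, prm, t) {
                 if (!s_ %in% migration_stocks(prm)) return(rep(0, ncol(S)))
                 pmax(-prm$demography$net_migration_rate, 0) * S[s_, ]
               },
               countAcc = "migration_out")
    })
  }
  flows
}

#' Project the base population with CVD dynamics disabled
#'
#' Demography-only projection used for structural validation: all CVD
#' incidence, recurrence, hospitalisation and CVD-death parameters are set
#' to zero and the population evolves under ageing, migration and non-CVD
#' mortality alone.
#'
#' @param params a [ParameterSet-class].
#' @param horizon years to project (default: full window).
#' @param dt step size (default `params@meta$dt`).
#' @return matrix bands x years of population at integer calendar years,
#'   plus attribute `"total"` (named numeric by year).
#' @export
projectBasePopulation <- function(params, horizon = NULL, dt = NULL) {
  p <- params
  nb <- length(AGE_BANDS)
  for (path in c("natural_history.incidence_initial.acs",
                 "natural_history.incidence_initial.stroke",
                 "natural_history.incidence_recurrent.acs",
                 "natural_history.incidence_recurrent.stroke",
                 "natural_history.chronic_hosp_rate",
                 "natural_history.community_death_rate"))
    p <- setParam(p, path, rep(0, nb))
  p <- setParam(p, "natural_history.initial_prevalence", rep(0, nb))
  traj <- simulateModel(p, horizon = horizon, dt = dt)
  yrs <- floor(traj@times[1]):floor(traj@times[length(traj@times)])
  tot <- apply(traj@stocks, c(2, 3), sum)  # bands x time
  out <- vapply(yrs, function(y) {
    i <- which.min(abs(traj@times - y))
    tot[, i]
  }, numeric(nb))
  dimnames(out) <- list(AGE_BANDS, yrs)
  attr(out, "total") <- stats::setNames(colSums(out), yrs)
  out
}

#' Export a projected population to CSV
#'
#' @param pop matrix returned by [projectBasePopulation()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportPopulationCSV <- function(pop, file) {
  df <- data.frame(band = rep(rownames(pop), ncol(pop)),
                   year = rep(as.numeric(colnames(pop)), each = nrow(pop)),
                   population = as.vector(pop))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
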