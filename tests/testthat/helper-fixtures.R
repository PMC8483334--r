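# Shared fixtures, built once per test run and memoised (simulations are
# deterministic, so caching is safe).

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

fx_default <- function() fx_memo("default", function()
  generateDefaultParams(seed = 1))

fx_params <- function() fx_default()$params

fx_spec <- function() fx_memo("spec", function() cvdModelSpec(fx_params()))

fx_base <- function() fx_memo("base", function()
  simulateModel(fx_params(), spec = fx_spec()))

fx_group <- function(label) fx_memo(paste0("grp_", label), function()
  simulateModel(fx_params(), namedScenario(label), spec = fx_spec()))

# A minimal linear two-stock chain A -> B -> sink with constant hazards,
# for closed-form oracles.
chain_spec <- function(a, b, dt = 0.01, end = 10) {
  flows <- list(
    flowSpec("AtoB", "A", "B", function(S, prm, t) a * S["A", ]),
    flowSpec("Bout", "B", "sink", function(S, prm, t) b * S["B", ]))
  modelSpec(stocks = c("A", "B"), accumulators = "sink", flows = flows,
            bands = "all", timeGrid = c(start = 0, end = end, dt = dt))
}

chain_state <- function(spec, A0 = 1000, B0 = 0) {
  compartmentState(matrix(c(A0, B0), 2, 1,
                          dimnames = list(c("A", "B"), "all")),
                   time = 0, spec = spec)
}

# run a hand-built spec without strategy machinery
run_spec <- function(spec, state, horizon, dt) {
  params <- ParameterSet(list(demography = list(dummy = 0)),
                         meta = list(start_year = 0, end_year = horizon,
                                     dt = dt))
  simulateModel(params, spec = spec, initial = state, horizon = horizon,
                dt = dt)
}

# parameter set for an isolated acute cohort: no demography, no incidence
cohort_params <- function(cfr_pre = 0.4, cfr_in = 0.2) {
  p <- fx_params()
  nb <- length(getParam(p, "demography.initial_population"))
  p <- setParam(p, "demography.entry_inflow_base", 0)
  p <- setParam(p, "demography.net_migration_rate", rep(0, nb))
  p <- setParam(p, "demography.background_mortality", rep(1e-12, nb))
  for (ev in c("acs", "stroke")) {
    p <- setParam(p, paste0("natural_history.incidence_initial.", ev),
                  rep(0, nb))
    p <- setParam(p, paste0("natural_history.incidence_recurrent.", ev),
                  rep(0, nb))
  }
  p <- setParam(p, "natural_history.chronic_hosp_rate", rep(0, nb))
  p <- setParam(p, "natural_history.community_death_rate", rep(0, nb))
  for (k in c("acs_initial", "acs_recurrent", "stroke_initial",
              "stroke_recurrent")) {
    p <- setParam(p, paste0("natural_history.cfr_prehospital.", k), cfr_pre)
    p <- setParam(p, paste0("natural_history.cfr_inhospital.", k), cfr_in)
  }
  p <- setParam(p, "natural_history.initial_prevalence", rep(0, nb))
  p <- setParam(p, "demography.initial_population", rep(0, nb))
  p
}

# place a cohort into one stock of an otherwise empty model
cohort_state <- function(params, stock, n = 1000) {
  spec <- cvdModelSpec(params)
  st <- initialState(params, spec)
  st@stocks[stock, 1] <- n
  st
}
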