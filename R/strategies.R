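#' @include natural_history.R
NULL

STRATEGY_GROUPS <- c(salt = "supportive_environment",
                     physical_activity = "supportive_environment",
                     smoking = "supportive_environment",
                     defibrillator = "acute_response",
                     prehospital_delay = "acute_response",
                     prescription = "medication_treatment",
                     adherence = "medication_treatment",
                     rehab = "medication_treatment")

# All case-fatality parameter paths for acute events.
acute_cfr_paths <- function() {
  keys <- c("acs_initial", "acs_recurrent", "stroke_initial",
            "stroke_recurrent")
  c(paste0("natural_history.cfr_prehospital.", keys),
    paste0("natural_history.cfr_inhospital.", keys))
}

incidence_paths <- function(which = c("initial", "recurrent")) {
  unlist(lapply(which, function(w)
    paste0("natural_history.incidence_", w, c(".acs", ".stroke"))))
}

# Incidence multiplier when a binary risk factor's prevalence moves from p0
# to p1 with relative risk rr for the exposed: ratio of population-average
# relative risks.
prevalence_shift_multiplier <- function(p0, p1, rr) {
  ((1 - p1) + p1 * rr) / ((1 - p0) + p0 * rr)
}

# Incidence multiplier when the treated (risk ratio rr_t) share among an
# eligible pool rises by d_treated.
treatment_uptake_multiplier <- function(t0, d_treated, rr_t) {
  base <- (1 - t0) + t0 * rr_t
  pmax((base - d_treated * (1 - rr_t)) / base, 0)
}

#' Rollout fraction of a strategy at time t
#'
#' Zero before `rolloutStart`; a linear ramp to 1 over `rampDuration`; 1
#' thereafter. If `riskLag > 0` the emitted fraction is the first-order
#' lagged response to the ramp (time constant `riskLag`), capturing risks
#' that decline gradually after exposure changes; it approaches 1 only
#' asymptotically. Strategies with `rampShape = "exponential"` (the
#' prescribed-trajectory smoking glide) use `1 - exp(-3 * dt / duration)`,
#' reaching ~95% of full effect at `rampDuration`.
#'
#' @param t calendar year (vectorised).
#' @param spec a [StrategySpec-class].
#' @return effect fraction in [0, 1].
#' @export
rampFraction <- function(t, spec) {
  u <- t - spec@rolloutStart
  D <- spec@rampDuration
  if (spec@rampShape == "exponential") {
    tau <- D / 3
    return(ifelse(u <= 0, 0, 1 - exp(-u / tau)))
  }
  ramp <- pmin(pmax(u / D, 0), 1)
  tau <- spec@riskLag
  if (tau <= 0) return(ramp)
  # exact first-order response to a unit ramp-and-hold input
  during <- (u - tau + tau * exp(-u / tau)) / D
  after <- 1 - (tau / D) * (1 - exp(-D / tau)) * exp(-(u - D) / tau)
  ifelse(u <= 0, 0, ifelse(u <= D, during, after))
}

#' Build the library of the eight default strategies
#'
#' Reads the strategy magnitude and risk-link blocks of `params` and returns
#' the eight named [StrategySpec-class] objects in their three reporting
#' groups: supportive environment (salt reformulation, physical activity,
#' smoking), acute response (public-access defibrillators, pre-hospital
#' delay), and preventive medication/treatment (prescription, adherence,
#' cardiac rehabilitation). Full-effect multipliers are derived from the
#' parameterised risk links (risk-factor prevalences and relative risks), so
#' sampled magnitudes propagate automatically in the PSA.
#'
#' @param params a [ParameterSet-class].
#' @return named list of [StrategySpec-class], length 8.
#' @export
buildStrategyLibrary <- function(params) {
  st <- params@values$strategies
  if (is.null(st)) stop("parameter set lacks a strategies block")
  lk <- st$links
  need <- c("salt", "physical_activity", "smoking", "defibrillator",
            "prehospital_delay", "prescription", "adherence", "rehab")
  miss <- setdiff(need, names(st))
  if (length(miss))
    stop("missing strategy magnitude block(s): ", paste(miss, collapse = ", "))
  start <- st$rollout_start
  # immediate = TRUE marks targets that track rollout directly (costs,
  # service uptake); risk effects follow the lagged ramp
  tg <- function(paths, m, e = 1, immediate = FALSE)
    lapply(paths, function(p) list(path = p, multiplier = m, eligible = e,
                                   immediate = immediate))
  lib <- list()

  # sodium -10% over 4 y -> blood-pressure-mediated incidence reduction
  m_salt <- 1 - (st$salt$sodium_reduction_pct / 10) *
    (1 - lk$salt_incidence_rr_per_10pct)
  lib$salt <- new("StrategySpec", name = "salt",
    group = "supportive_environment",
    targets = tg(incidence_paths(), m_salt),
    rolloutStart = start, rampDuration = st$salt$ramp_duration,
    riskLag = st$salt$risk_lag)

  # two levers each shaving percentage points off the inactive proportion
  dI <- st$physical_activity$levers *
    st$physical_activity$pp_reduction_per_lever / 100
  m_pa <- prevalence_shift_multiplier(
    lk$inactive_prevalence, max(lk$inactive_prevalence - dI, 0),
    lk$inactivity_rr)
  lib$physical_activity <- new("StrategySpec", name = "physical_activity",
    group = "supportive_environment",
    targets = tg(incidence_paths(), m_pa),
    rolloutStart = start,
    rampDuration = st$physical_activity$ramp_duration,
    riskLag = st$physical_activity$risk_lag)

  # prescribed prevalence glide to the ~6% floor over 20 y
  m_sm <- prevalence_shift_multiplier(
    lk$smoking_prevalence, st$smoking$target_prevalence_pct / 100,
    lk$smoking_rr)
  lib$smoking <- new("StrategySpec", name = "smoking",
    group = "supportive_environment",
    targets = tg(incidence_paths(), m_sm),
    rolloutStart = start, rampDuration = st$smoking$glide_years,
    riskLag = 0, rampShape = "exponential", rampOverride = TRUE)

  # halves deaths after out-of-hospital cardiac arrest (the arrest share of
  # pre-hospital ACS deaths is the eligible fraction)
  lib$defibrillator <- new("StrategySpec", name = "defibrillator",
    group = "acute_response",
    targets = tg(paste0("natural_history.cfr_prehospital.",
                        c("acs_initial", "acs_recurrent")),
                 1 - st$defibrillator$death_reduction, lk$ohca_share),
    rolloutStart = start, rampDuration = st$defibrillator$ramp_duration,
    riskLag = 0)

  # pre-hospital delay to a 2 h target lowers acute death probabilities
  # (among the time-critical-amenable fraction of acute deaths)
  lib$prehospital_delay <- new("StrategySpec", name = "prehospital_delay",
    group = "acute_response",
    targets = tg(acute_cfr_paths(), 1 - st$prehospital_delay$death_reduction,
                 lk$delay_amenable),
    rolloutStart = start,
    rampDuration = st$prehospital_delay$ramp_duration, riskLag = 0)

  # +5-10 percentage points of eligible adults on preventive medication
  m_rx <- treatment_uptake_multiplier(
    lk$treated_prevalence, st$prescription$pp_increase / 100,
    lk$treatment_rr)
  lib$prescription <- new("StrategySpec", name = "prescription",
    group = "medication_treatment",
    targets = c(tg(incidence_paths(), m_rx, lk$eligible_fraction),
                tg(c("economics.unit_costs.management_py.well",
                     "economics.unit_costs.management_py.chronic"),
                   st$prescription$cost_multiplier, immediate = TRUE)),
    rolloutStart = start, rampDuration = st$prescription$ramp_duration,
    riskLag = st$prescription$risk_lag)

  # +10-20% relative adherence among the treated
  d_adh <- lk$treated_prevalence * lk$adherence_baseline *
    st$adherence$rel_increase_pct / 100
  base_adh <- 1 - lk$treated_prevalence * lk$adherence_baseline *
    (1 - lk$treatment_rr)
  m_adh <- (base_adh - d_adh * (1 - lk$treatment_rr)) / base_adh
  lib$adherence <- new("StrategySpec", name = "adherence",
    group = "medication_treatment",
    targets = c(tg(incidence_paths(), m_adh),
                tg(c("economics.unit_costs.management_py.chronic"),
                   st$adherence$cost_multiplier, immediate = TRUE)),
    rolloutStart = start, rampDuration = st$adherence$ramp_duration,
    riskLag = st$adherence$risk_lag)

  # +15-30% relative referral/attendance/completion of cardiac rehab,
  # lowering recurrent myocardial infarction risk
  d_rehab <- lk$rehab_completion * st$rehab$rel_increase_pct / 100
  m_rehab <- ((1 - (lk$rehab_completion + d_rehab)) +
                (lk$rehab_completion + d_rehab) * lk$rehab_rr) /
    ((1 - lk$rehab_completion) + lk$rehab_completion * lk$rehab_rr)
  lib$rehab <- new("StrategySpec", name = "rehab",
    group = "medication_treatment",
    targets = c(tg("natural_history.incidence_recurrent.acs", m_rehab),
                tg("economics.rehab_participation",
                   1 + st$rehab$rel_increase_pct / 100, immediate = TRUE)),
    rolloutStart = start, rampDuration = st$rehab$ramp_duration,
    riskLag = st$rehab$risk_lag)

  lib[need]
}

#' Construct a Scenario
#'
#' @param active character vector of strategy names (resolved against
#'   [buildStrategyLibrary()] at simulation time) and/or
#'   [StrategySpec-class] objects.
#' @param label scenario label.
#' @param overrides named list (by strategy) of overrides:
#'   `rolloutStart`, `rampDuration`.
#' @return A [Scenario-class].
#' @export
makeScenario <- function(active = character(), label = "scenario",
                         overrides = list()) {
  if (!is.list(active)) active <- as.list(active)
  new("Scenario", label = label, active = active, overrides = overrides)
}

#' Reserved scenario labels
#'
#' `base_case` (no strategies), one scenario per strategy group
#' (`supportive_environment`, `pre_hospital` alias of the acute-response
#' group, `medication_treatment`), and `all` (all eight strategies).
#'
#' @param label one of the reserved labels or a single strategy name.
#' @return A [Scenario-class].
#' @export
namedScenario <- function(label) {
  groups <- split(names(STRATEGY_GROUPS), STRATEGY_GROUPS)
  switch(label,
    base_case = makeScenario(character(), "base_case"),
    supportive_environment =
      makeScenario(groups$supportive_environment, "supportive_environment"),
    pre_hospital = ,
    acute_response = makeScenario(groups$acute_response, label),
    medication_treatment =
      makeScenario(groups$medication_treatment, "medication_treatment"),
    all = makeScenario(names(STRATEGY_GROUPS), "all"),
    {
      if (!label %in% names(STRATEGY_GROUPS))
        stop("unknown scenario label: ", label)
      makeScenario(label, label)
    })
}

# Resolve a Scenario to a list of StrategySpec against params.
resolveScenario <- function(scenario, params) {
  if (is.null(scenario) || !length(scenario@active)) return(list())
  lib <- NULL
  out <- lapply(scenario@active, function(a) {
    if (is(a, "StrategySpec")) return(a)
    if (is.null(lib)) lib <<- buildStrategyLibrary(params)
    sp <- lib[[as.character(a)]]
    if (is.null(sp)) stop("unknown strategy name: ", a)
    ov <- scenario@overrides[[as.character(a)]]
    if (!is.null(ov)) {
      if (!is.null(ov$rolloutStart)) sp@rolloutStart <- ov$rolloutStart
      if (!is.null(ov$rampDuration)) sp@rampDuration <- ov$rampDuration
    }
    sp
  })
  names(out) <- vapply(out, function(s) s@name, character(1))
  out
}

# probability-valued parameter paths get clamped to [0,1]
is_prob_path <- function(path)
  grepl("\\.cfr_|death_prob", path)

# Core overlay: combined factor per targeted path at time t, applied to a
# copy of the values list. Strategies combine multiplicatively:
# p_eff = p * prod_i (1 - e_i * f_i(t) * (1 - m_i)).
effective_values <- function(params, strategies, t) {
  vals <- params@values
  if (!length(strategies)) return(vals)
  factors <- list()
  for (sp in strategies) {
    f_lag <- rampFraction(t, sp)
    sp_imm <- sp; sp_imm@riskLag <- 0
    f_imm <- rampFraction(t, sp_imm)
    if (f_imm <= 0) next
    for (tgint in sp@targets) {
      f <- if (isTRUE(tgint$immediate)) f_imm else f_lag
      fac <- 1 - tgint$eligible * f * (1 - tgint$multiplier)
      p <- tgint$path
      factors[[p]] <- if (is.null(factors[[p]])) fac else factors[[p]] * fac
    }
  }
  for (p in names(factors)) {
    keys <- split_path(p)
    v <- get_at(vals, keys) * factors[[p]]
    if (is_prob_path(p)) v <- pmin(pmax(v, 0), 1)
    vals <- set_at(vals, keys, v)
  }
  vals
}

#' Strategy-adjusted parameters at a time point
#'
#' Applies every active strategy's eligibility-weighted, ramp-scaled
#' relative effect to its targeted parameters, combining strategies
#' multiplicatively; probability-valued parameters are clamped to [0, 1].
#' An empty scenario returns `base` unchanged. The result is independent of
#' the order of strategies.
#'
#' @param base a [ParameterSet-class].
#' @param scenario a [Scenario-class] (or `NULL` for base case).
#' @param t calendar year.
#' @return A [ParameterSet-class] with adjusted values.
#' @export
effectiveParameters <- function(base, scenario, t) {
  strategies <- resolveScenario(scenario, base)
  for (sp in strategies)
    for (tgint in sp@targets) get_at(base@values, split_path(tgint$path))
  base@values <- effective_values(base, strategies, t)
  base
}
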