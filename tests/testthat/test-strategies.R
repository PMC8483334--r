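mk_strategy <- function(lag = 0, start = 2019, dur = 4, shape = "linear",
                        targets = list()) {
  new("StrategySpec", name = "s", group = "acute_response",
      targets = targets, rolloutStart = start, rampDuration = dur,
      riskLag = lag, rampShape = shape,
      rampOverride = shape == "exponential")
}

test_that("ramp fraction is 0 before rollout, linear during, 1 after", {
  sp <- mk_strategy(dur = 4)
  expect_equal(rampFraction(2018.9, sp), 0)
  expect_equal(rampFraction(2021, sp), 0.5)
  expect_equal(rampFraction(2030, sp), 1)
})

test_that("risk-lagged ramp matches a numerically integrated first-order response", {
  skip_if_not_installed("deSolve")
  sp <- mk_strategy(lag = 3, dur = 4)
  ode <- deSolve::ode(
    y = c(e = 0), times = seq(0, 15, 0.05),
    func = function(t, y, parms) {
      r <- min(max(t / 4, 0), 1)
      list((r - y) / 3)
    }, parms = NULL, method = "lsoda")
  got <- rampFraction(2019 + ode[, "time"], sp)
  expect_lt(max(abs(got - ode[, "e"])), 1e-4)
  # strictly below 1 at the end of the ramp, approaching 1 later
  expect_lt(rampFraction(2023, sp), 1)
  expect_gt(rampFraction(2060, sp), 0.999)
})

test_that("the strategy library has eight members in a 3/2/3 grouping", {
  lib <- buildStrategyLibrary(fx_params())
  expect_length(lib, 8)
  groups <- table(vapply(lib, function(s) s@group, character(1)))
  expect_equal(as.integer(groups[c("supportive_environment",
                                   "acute_response",
                                   "medication_treatment")]),
               c(3L, 2L, 3L))
  durs <- vapply(lib, function(s) s@rampDuration, numeric(1))
  over <- vapply(lib, function(s) s@rampOverride, logical(1))
  expect_true(all(durs[!over] >= 2 & durs[!over] <= 10))
  expect_true(all(vapply(lib, function(s)
    all(vapply(s@targets, function(tg) tg$multiplier, numeric(1)) > 0),
    logical(1))))
})

test_that("strategy overlays follow the eligibility-weighted multiplicative rule", {
  p <- fx_params()
  lk <- p@values$strategies$links

  # defibrillator at full effect: pre-hospital ACS deaths x (1 - e * 0.5)
  sc <- namedScenario("defibrillator")
  eff <- effectiveParameters(p, sc, t = 2040)
  expect_equal(getParam(eff, "natural_history.cfr_prehospital.acs_initial"),
               getParam(p, "natural_history.cfr_prehospital.acs_initial") *
                 (1 - lk$ohca_share * 0.5))

  # pre-hospital delay at full effect: acute death probabilities x
  # (1 - amenable * 0.2)
  eff <- effectiveParameters(p, namedScenario("prehospital_delay"), 2040)
  for (path in cvdflow:::acute_cfr_paths())
    expect_equal(getParam(eff, path),
                 getParam(p, path) * (1 - lk$delay_amenable * 0.2))

  # two equal strategies on one path combine multiplicatively (0.9^2)
  s1 <- mk_strategy(targets = list(list(
    path = "natural_history.cfr_inhospital.acs_initial",
    multiplier = 0.9, eligible = 1)))
  s2 <- s1; s2@name <- "s2"
  sc <- makeScenario(list(s1, s2), "pair")
  eff <- effectiveParameters(p, sc, 2040)
  expect_equal(getParam(eff, "natural_history.cfr_inhospital.acs_initial"),
               getParam(p, "natural_history.cfr_inhospital.acs_initial") *
                 0.81)
})

test_that("empty scenarios change nothing and order does not matter", {
  p <- fx_params()
  expect_identical(effectiveParameters(p, makeScenario(), 2030)@values,
                   p@values)
  a <- effectiveParameters(p, makeScenario(c("salt", "smoking",
                                             "defibrillator")), 2027)
  b <- effectiveParameters(p, makeScenario(c("defibrillator", "salt",
                                             "smoking")), 2027)
  expect_equal(a@values, b@values)
})

test_that("unresolved target paths are an error", {
  s <- mk_strategy(targets = list(list(path = "natural_history.nope",
                                       multiplier = 0.9, eligible = 1)))
  expect_error(effectiveParameters(fx_params(), makeScenario(list(s)), 2030),
               "not found")
  expect_error(namedScenario("warp_drive"), "unknown")
})

test_that("probabilities stay clamped to [0,1] under extreme overlays", {
  s <- mk_strategy(targets = list(list(
    path = "natural_history.cfr_prehospital.acs_initial",
    multiplier = 20, eligible = 1)))
  eff <- effectiveParameters(fx_params(), makeScenario(list(s)), 2040)
  expect_lte(getParam(eff, "natural_history.cfr_prehospital.acs_initial"), 1)
})

test_that("every single strategy weakly reduces cumulative CVD deaths", {
  p <- fx_params()
  spec <- fx_spec()
  base <- accSeries(fx_base(), c("deaths_prehospital", "deaths_inhospital",
                                 "deaths_community"))
  for (nm in names(cvdflow:::STRATEGY_GROUPS)) {
    tr <- simulateModel(p, namedScenario(nm), spec = spec)
    d <- accSeries(tr, c("deaths_prehospital", "deaths_inhospital",
                         "deaths_community"))
    expect_true(all(d <= base + 1e-6), label = paste("deaths under", nm))
  }
})

test_that("the acute-response group trades deaths for extra hospitalisations", {
  tr <- fx_group("pre_hospital")
  base <- fx_base()
  expect_gt(relativeReduction(tr, base, "deaths", 20, 2019), 0)
  hosp_sc <- cvdflow:::window_totals(tr, "hosp_chronic", c(2019, 2039))
  hosp_b <- cvdflow:::window_totals(base, "hosp_chronic", c(2019, 2039))
  expect_gt(hosp_sc, hosp_b)
  expect_lt(relativeReduction(tr, base, "hospitalisations", 20, 2019), 0)
})
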