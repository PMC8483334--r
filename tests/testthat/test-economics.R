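test_that("discounting identities hold", {
  expect_equal(discountFactor(0), 1)
  expect_equal(discountFactor(1, 0.05), 1 / 1.05)
  expect_error(discountFactor(1, -1.2), "exceed")
  # discounting shrinks any positive stream
  s <- runif(50, 1, 2)
  expect_lt(sum(s * discountFactor(seq_along(s), 0.05)), sum(s))
})

test_that("a constant unit stream matches the annuity closed form", {
  # 1/yr for 20 y discounted at 5%, accrued mid-step: compare against the
  # exact integral of (1.05)^(-t) over [0,20] evaluated by quadrature
  dt <- 0.1; r <- 0.05
  mids <- seq(dt / 2, 20 - dt / 2, by = dt)
  got <- sum(dt * discountFactor(mids, r))
  exact <- stats::integrate(function(t) (1 + r)^(-t), 0, 20)$value
  expect_equal(got, exact, tolerance = 1e-4)
})

test_that("QALY accounting is utility-weighted person-time", {
  p <- fx_params()
  traj <- simulateModel(p, horizon = 3)
  q <- qalyStream(traj, p)
  expect_length(q$series, length(traj@times) - 1)
  # identical trajectories cancel exactly
  nb <- netBenefit(traj, traj, p, checkpoints = 3)
  expect_equal(nb$qaly_gain, 0)
  expect_equal(nb$net_benefit_health_system, 0)
  expect_equal(nb$net_benefit_societal, 0)
  # 2 undiscounted QALYs are worth AU$100,000 at the stated threshold
  expect_equal(2 * getParam(p, "economics.qaly_value"), 100000)
})

test_that("moving a person-year from chronic to disease-free gains w_f - w_c", {
  p <- fx_params()
  p <- setParam(p, "economics.discount_rate", 0)
  u <- p@values$economics$utility
  # one person for one year in chronic vs in well, empty model otherwise
  pc <- cohort_params(); pc <- setParam(pc, "economics.discount_rate", 0)
  pc <- setParam(pc, "demography.background_mortality", rep(0, 10))
  s1 <- cohort_state(pc, "chronic", 1)
  s2 <- cohort_state(pc, "well", 1)
  pc2 <- setParam(pc, "natural_history.chronic_hosp_rate", rep(0, 10))
  t1 <- simulateModel(pc2, initial = s1, horizon = 1, dt = 0.1)
  t2 <- simulateModel(pc2, initial = s2, horizon = 1, dt = 0.1)
  gain <- qalyStream(t2, pc2)$total - qalyStream(t1, pc2)$total
  expect_equal(gain, u$well - u$chronic, tolerance = 1e-9)
})

test_that("payer-stratified costs close to the total", {
  p <- fx_params()
  traj <- simulateModel(p, horizon = 12)
  cs <- costStreams(traj, p)
  expect_lt(max(abs(colSums(cs$by_payer) - cs$health_service)) /
              max(cs$health_service), 1e-9)
  expect_equal(unname(colSums(cs$by_component)), unname(cs$health_service))
})

test_that("zero unit costs produce zero cost streams", {
  p <- fx_params()
  for (path in c("economics.unit_costs.acute_hosp.acs",
                 "economics.unit_costs.acute_hosp.stroke",
                 "economics.unit_costs.chronic_hosp",
                 "economics.unit_costs.rehab",
                 "economics.unit_costs.management_py.well",
                 "economics.unit_costs.management_py.chronic"))
    p <- setParam(p, path, 0)
  cs <- costStreams(simulateModel(p, horizon = 5), p)
  expect_equal(max(abs(cs$health_service)), 0)
})

test_that("prevention saves hospitalisation costs while management costs rise", {
  p <- fx_params()
  base <- fx_base()
  tr <- fx_group("medication_treatment")
  cs <- costStreams(tr, p); cb <- costStreams(base, p)
  w <- cs$times >= 2019
  expect_lt(sum(cs$by_component["hospitalisation", w]) -
              sum(cb$by_component["hospitalisation", w]), 0)
  # the medication strategies raise ongoing management/medication spend
  eff <- effectiveParameters(p, namedScenario("medication_treatment"), 2040)
  expect_gt(getParam(eff, "economics.unit_costs.management_py.chronic"),
            getParam(p, "economics.unit_costs.management_py.chronic"))
})

test_that("net-benefit identities and perspective ordering hold on a real comparison", {
  p <- fx_params()
  nb <- netBenefit(fx_group("supportive_environment"), fx_base(), p)
  expect_equal(nb$net_benefit_health_system,
               nb$monetised_qaly - nb$health_cost_delta)
  expect_equal(nb$net_benefit_societal,
               nb$monetised_qaly - nb$health_cost_delta -
                 nb$household_delta + nb$productivity_gain)
  expect_equal(nb$health_cost_delta,
               nb$cost_delta_commonwealth + nb$cost_delta_state_territory +
                 nb$cost_delta_consumer, tolerance = 1e-9)
  # prevention: productivity gain exceeds the (negative) household delta,
  # so the societal perspective dominates
  i20 <- nb$checkpoint == 20
  expect_gte(nb$productivity_gain[i20], nb$household_delta[i20])
  expect_gte(nb$net_benefit_societal[i20], nb$net_benefit_health_system[i20])
  expect_error(netBenefit(fx_base(),
                          simulateModel(p, horizon = 5), p),
               "different time grids")
})
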