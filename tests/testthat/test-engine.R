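test_that("structural validation flags dangling endpoints and unit mismatches", {
  ok <- validateSpec(fx_spec())
  expect_true(ok$ok)
  expect_identical(nrow(ok$findings), 0L)

  bad <- modelSpec(
    stocks = c("well", "chronicCVD"), accumulators = c("deaths", "cost"),
    flows = list(
      flowSpec("f1", "well", "chronicCVD2", function(S, prm, t) 0),
      flowSpec("f2", "cost", "well", function(S, prm, t) 0)),
    bands = "all", timeGrid = c(start = 0, end = 1, dt = 0.1),
    accUnits = c(deaths = "persons", cost = "currency"))
  rep <- validateSpec(bad)
  expect_false(rep$ok)
  expect_true(any(rep$findings$kind == "dangling_endpoint" &
                    grepl("chronicCVD2", rep$findings$detail)))
  expect_true(any(rep$findings$kind == "unit_mismatch" &
                    grepl("cost", rep$findings$detail)))

  money <- modelSpec(
    stocks = "well", accumulators = "spend",
    flows = list(flowSpec("f", "well", "spend", function(S, prm, t) 0)),
    bands = "all", timeGrid = c(start = 0, end = 1, dt = 0.1),
    accUnits = c(spend = "currency"))
  expect_true(any(validateSpec(money)$findings$kind == "unit_mismatch"))
})

test_that("zero rates leave the state unchanged and a single Euler step is exact", {
  spec <- chain_spec(0, 0)
  st <- chain_state(spec, 100, 0)
  out <- stepState(st, spec, list(), dt = 1)
  expect_equal(out@stocks, st@stocks)
  expect_equal(out@time, 1)

  spec <- chain_spec(0.1, 0)
  out <- stepState(chain_state(spec, 100, 0), spec, list(), dt = 1)
  expect_equal(out@stocks["A", 1][[1]], 90)
  expect_equal(out@stocks["B", 1][[1]], 10)
})

test_that("joint outflow capping preserves non-negativity and branching shares", {
  flows <- list(
    flowSpec("f1", "A", "B", function(S, prm, t) 30 * S["A", ]),
    flowSpec("f2", "A", "sink", function(S, prm, t) 10 * S["A", ]))
  spec <- modelSpec(c("A", "B"), "sink", flows, "all",
                    c(start = 0, end = 1, dt = 0.1))
  out <- stepState(chain_state(spec, 100, 0), spec, list(), dt = 0.1)
  # demanded outflow is 4x the content; scaled to drain exactly, 3:1 split
  expect_gte(min(out@stocks), 0)
  expect_equal(out@stocks["A", ][[1]], 0)
  expect_equal(out@stocks["B", ][[1]], 75)
  expect_equal(out@acc["sink", ][[1]], 25)
})

test_that("negative rate rules are rejected", {
  flows <- list(flowSpec("f", "A", "B", function(S, prm, t) -1))
  spec <- modelSpec(c("A", "B"), "sink", flows, "all",
                    c(start = 0, end = 1, dt = 0.1))
  expect_error(stepState(chain_state(spec), spec, list(), dt = 0.1),
               "negative rate")
})

test_that("two-stock chain matches the matrix-exponential solution", {
  skip_if_not_installed("Matrix")
  a <- 0.25; b <- 0.08
  spec <- chain_spec(a, b, dt = 0.01, end = 10)
  traj <- run_spec(spec, chain_state(spec, 1000, 200), 10, 0.01)
  M <- matrix(c(-a, a, 0, -b), 2, 2)
  exact <- as.numeric(Matrix::expm(M * 10) %*% c(1000, 200))
  got <- traj@stocks[, 1, dim(traj@stocks)[3]]
  expect_lt(max(abs(got - exact) / exact), 0.005)
})

test_that("pure-death stock converges to N*exp(-hT) as dt shrinks", {
  h <- 0.3; T <- 5; N <- 1000
  errs <- vapply(c(1, 0.1, 0.01), function(dt) {
    flows <- list(flowSpec("d", "A", "sink",
                           function(S, prm, t) h * S["A", ]))
    spec <- modelSpec(c("A", "B"), "sink", flows, "all",
                      c(start = 0, end = T, dt = dt))
    traj <- run_spec(spec, chain_state(spec, N, 0), T, dt)
    abs(traj@stocks["A", 1, dim(traj@stocks)[3]] - N * exp(-h * T))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # error shrinks with dt
  expect_lt(errs[3] / (N * exp(-h * T)), 0.005)
})

test_that("simulation is deterministic and horizon 0 returns only the start", {
  t1 <- simulateModel(fx_params(), horizon = 2)
  t2 <- simulateModel(fx_params(), horizon = 2)
  expect_identical(t1@stocks, t2@stocks)
  expect_identical(t1@acc, t2@acc)
  t0 <- simulateModel(fx_params(), horizon = 0)
  expect_length(t0@times, 1L)
})

test_that("persons are conserved at every step of a base-case run", {
  traj <- fx_base()
  tot <- apply(traj@stocks, 3, sum)
  ext_in <- accSeries(traj, c("entries", "migration_in"))
  ext_out <- accSeries(traj, "migration_out")
  deaths <- accSeries(traj, c("deaths_prehospital", "deaths_inhospital",
                              "deaths_community", "deaths_noncvd"))
  resid <- (tot - tot[1]) - (ext_in - ext_out - deaths)
  expect_lt(max(abs(resid)) / tot[1], 1e-9)
})

test_that("death and hospitalisation accumulators are non-decreasing", {
  traj <- fx_base()
  for (a in c("deaths_prehospital", "deaths_inhospital", "deaths_community",
              "hosp_chronic", "hosp_acs_initial"))
    expect_gte(min(diff(accSeries(traj, a))), 0)
})

test_that("cumulative 20-year deaths are step-size robust", {
  p <- fx_params()
  d <- vapply(c(0.1, 0.05), function(dt) {
    traj <- simulateModel(p, dt = dt)
    sum(cvdflow:::window_totals(traj, c("deaths_prehospital",
                                        "deaths_inhospital",
                                        "deaths_community"),
                                c(2019, 2039)))
  }, numeric(1))
  expect_lt(abs(d[1] - d[2]) / d[2], 0.01)
})

test_that("trajectory export writes parseable long-format CSV", {
  f <- tempfile(fileext = ".csv")
  exportTrajectoryCSV(simulateModel(fx_params(), horizon = 2), f)
  df <- read.csv(f)
  expect_true(all(c("year", "series", "value", "kind") %in% names(df)))
  expect_true("deaths_cvd" %in% df$series)
})
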