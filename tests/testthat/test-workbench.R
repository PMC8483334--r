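test_that("relative reductions follow the sign convention", {
  base <- fx_base()
  expect_equal(relativeReduction(base, base, "deaths", 20), 0)
  tr <- fx_group("supportive_environment")
  rr <- relativeReduction(tr, base, "deaths", 20)
  expect_gt(rr, 0)   # positive = reduction
  # hand check against cumulative accumulators
  b <- sum(cvdflow:::window_totals(base, c("deaths_prehospital",
                                           "deaths_inhospital",
                                           "deaths_community"),
                                   c(2019, 2039)))
  s <- sum(cvdflow:::window_totals(tr, c("deaths_prehospital",
                                         "deaths_inhospital",
                                         "deaths_community"),
                                   c(2019, 2039)))
  expect_equal(rr, 100 * (b - s) / b)
  expect_error(relativeReduction(tr, base, "lives", 20), "unknown outcome")
})

test_that("benefits accrue with delay: 20-year reductions dominate 3-year ones", {
  base <- fx_base()
  for (lab in c("supportive_environment", "pre_hospital",
                "medication_treatment")) {
    tr <- fx_group(lab)
    r3 <- relativeReduction(tr, base, "deaths", 3)
    r20 <- relativeReduction(tr, base, "deaths", 20)
    expect_gte(r20, 2 * r3, label = paste("deaths ratio for", lab))
  }
  # hospitalisation reductions likewise for the prevention groups
  for (lab in c("supportive_environment", "medication_treatment")) {
    tr <- fx_group(lab)
    expect_gte(relativeReduction(tr, base, "hospitalisations", 20),
               2 * relativeReduction(tr, base, "hospitalisations", 3),
               label = paste("hospitalisations ratio for", lab))
  }
})

test_that("the synthetic generator is deterministic and self-consistent", {
  g1 <- generateDefaultParams(seed = 3)
  g2 <- generateDefaultParams(seed = 3)
  expect_identical(g1$params@values, g2$params@values)
  expect_identical(g1$targets@deaths, g2$targets@deaths)
  g3 <- generateDefaultParams(seed = 4)
  expect_false(identical(g1$targets@deaths, g3$targets@deaths))
  expect_true(validateSpec(cvdModelSpec(g1$params))$ok)
  # target noise is small and multiplicative around the model's own base case
  traj <- simulateModel(g1$params, horizon = 7)
  clean <- annualSeries(traj, "deaths_cvd")[as.character(2011:2017)]
  expect_lt(max(abs(log(g1$targets@deaths / clean))), 5 * 0.02)
})

test_that("parameter files round-trip and unknown keys are rejected", {
  p <- fx_params()
  f <- tempfile(fileext = ".yaml")
  writeParameterSet(p, f)
  p2 <- readParameterSet(f)
  expect_equal(p2@values, p@values, tolerance = 1e-12)
  expect_equal(p2@meta$checkpoints, p@meta$checkpoints)
  expect_equal(nrow(p2@uncertainty), nrow(p@uncertainty))
  doc <- yaml::read_yaml(f)
  doc$natural_histroy <- list(typo = 1)    # misspelt block
  f2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, f2)
  expect_error(readParameterSet(f2), "unknown key")
  doc$natural_histroy <- NULL
  doc$schema_version <- NULL
  yaml::write_yaml(doc, f2)
  expect_error(readParameterSet(f2), "schema_version")
  expect_error(setParam(p, "natural_history.typo_rate", 1), "not found")
})

test_that("the CLI drives fixtures, validate, simulate and compare end to end", {
  out <- file.path(tempdir(), "cli-test")
  unlink(out, recursive = TRUE)
  expect_equal(cvdCli(c("fixtures", "--out", out, "--seed", "2")), 0L)
  pfile <- file.path(out, "params.yaml")
  expect_true(file.exists(pfile))
  expect_true(file.exists(file.path(out, "calibration_targets.csv")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2L)
  expect_equal(man$package, "cvdflow")

  expect_equal(cvdCli(c("validate", "--params", pfile, "--out", out)), 0L)

  expect_equal(cvdCli(c("simulate", "--params", pfile, "--scenario",
                        "base_case", "--out", out, "--dt", "0.25")), 0L)
  traj_csv <- file.path(out, "trajectory_base_case.csv")
  expect_true(file.exists(traj_csv))
  expect_gt(nrow(read.csv(traj_csv)), 100)

  expect_equal(cvdCli(c("compare", "--params", pfile, "--scenario",
                        "supportive_environment", "--out", out,
                        "--checkpoints", "3,10,20")), 0L)
  oc <- read.csv(file.path(out, "outcomes_supportive_environment.csv"))
  expect_equal(nrow(oc), 6L)  # 3 checkpoints x 2 outcomes
  nbz <- read.csv(file.path(out, "net_benefit_supportive_environment.csv"))
  expect_true(all(c("health_system_20y", "societal_20y") %in% names(nbz)))

  expect_equal(cvdCli("nonsense"), 1L)
})
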