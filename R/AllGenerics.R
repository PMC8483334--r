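#' @include AllClasses.R
NULL

setGeneric("getParam", function(x, path) standardGeneric("getParam"))
setGeneric("setParam", function(x, path, value) standardGeneric("setParam"))
setGeneric("validateSpec", function(spec) standardGeneric("validateSpec"))
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))
setGeneric("stockSeries", function(x, stock) standardGeneric("stockSeries"))
setGeneric("accSeries", function(x, acc) standardGeneric("accSeries"))
setGeneric("annualSeries", function(x, series) standardGeneric("annualSeries"))

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet (schema", object@meta$schema_version, ")\n")
  cat("  window:", object@meta$start_year, "-", object@meta$end_year,
      " dt =", object@meta$dt, "y\n")
  cat("  blocks:", paste(names(object@values), collapse = ", "), "\n")
  cat("  uncertain parameters:", nrow(object@uncertainty), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:", length(object@stocks), "stocks x",
      length(object@bands), "age bands,",
      length(object@accumulators), "accumulators,",
      length(object@flows), "flows\n")
  cat("  time grid:", object@timeGrid[["start"]], "-",
      object@timeGrid[["end"]], " dt =", object@timeGrid[["dt"]], "y\n")
})

setMethod("show", "CompartmentState", function(object) {
  cat("CompartmentState at t =", object@time, "\n")
  cat("  total persons:", format(sum(object@stocks), big.mark = ","), "\n")
})

setMethod("show", "StrategySpec", function(object) {
  cat("StrategySpec", object@name, "[", object@group, "]\n")
  cat("  rollout", object@rolloutStart, "+", object@rampDuration, "y ramp (",
      object@rampShape, "), risk lag", object@riskLag, "y\n")
  for (tg in object@targets)
    cat("   ", tg$path, "x", signif(tg$multiplier, 4),
        "(eligible", tg$eligible, ")\n")
})

setMethod("show", "Scenario", function(object) {
  nm <- vapply(object@active, function(a)
    if (is(a, "StrategySpec")) a@name else as.character(a), character(1))
  cat("Scenario", object@label, ":",
      if (length(nm)) paste(nm, collapse = ", ") else "(base case)", "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory [", object@label, "]:",
      length(object@times), "time points,",
      object@times[1], "-", object@times[length(object@times)], "\n")
})

setMethod("show", "PsaResult", function(object) {
  cat("PsaResult:", object@n, "draws (seed", object@seed, ")\n")
  print(utils::head(object@summary, 12))
})

setMethod("show", "CalibrationTargets", function(object) {
  cat("CalibrationTargets", object@source, ":",
      object@years[1], "-", object@years[length(object@years)], "\n")
})
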