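#' @include AllClasses.R AllGenerics.R
NULL

PARAM_BLOCKS <- c("demography", "natural_history", "strategies", "economics")
SCHEMA_VERSION <- "1.0"

#' Construct a ParameterSet
#'
#' @param values nested list of parameter blocks (`demography`,
#'   `natural_history`, `strategies`, `economics`).
#' @param uncertainty data.frame with columns `path`, `dist`, `lo`, `hi`
#'   (may have zero rows).
#' @param meta list of metadata; missing entries are filled with defaults
#'   (simulation window 2011-2039, dt 0.1 y, rollout start 2019,
#'   checkpoints 3/10/20 y).
#' @return A [ParameterSet-class].
#' @export
ParameterSet <- function(values, uncertainty = NULL, meta = list()) {
  if (is.null(uncertainty))
    uncertainty <- data.frame(path = character(), dist = character(),
                              lo = numeric(), hi = numeric())
  defaults <- list(schema_version = SCHEMA_VERSION, start_year = 2011,
                   end_year = 2039, dt = 0.1, rollout_start = 2019,
                   checkpoints = c(3, 10, 20))
  meta <- utils::modifyList(defaults, meta)
  unknown <- setdiff(names(values), PARAM_BLOCKS)
  if (length(unknown))
    stop("unknown parameter block(s): ", paste(unknown, collapse = ", "))
  new("ParameterSet", values = values, uncertainty = uncertainty, meta = meta)
}

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

get_at <- function(lst, keys) {
  for (k in keys) {
    if (!is.list(lst) || is.null(lst[[k]]))
      stop("parameter path not found: ", paste(keys, collapse = "."))
    lst <- lst[[k]]
  }
  lst
}

set_at <- function(lst, keys, value) {
  if (length(keys) == 1L) {
    if (is.null(lst[[keys]]))
      stop("parameter path not found: ", keys)
    lst[[keys]] <- value
  } else {
    if (!is.list(lst[[keys[1L]]]))
      stop("parameter path not found: ", paste(keys, collapse = "."))
    lst[[keys[1L]]] <- set_at(lst[[keys[1L]]], keys[-1L], value)
  }
  lst
}

#' @describeIn ParameterSet Read one entry by dot-separated path.
#' @param x a ParameterSet.
#' @param path dot-separated path, e.g.
#'   `"natural_history.cfr_prehospital.acs_initial"`.
#' @export
setMethod("getParam", "ParameterSet", function(x, path)
  get_at(x@values, split_path(path)))

#' @describeIn ParameterSet Replace one entry by path (errors on unknown
#'   paths, catching typos).
#' @param value replacement value.
#' @export
setMethod("setParam", "ParameterSet", function(x, path, value) {
  x@values <- set_at(x@values, split_path(path), value)
  x
})

#' Convert a stage probability to a constant hazard
#'
#' Standard conversion of a probability `p` of an event over a period `tau`
#' into the constant hazard that reproduces it: `-log(1 - p) / tau`.
#' Used where inputs arrive as period probabilities. Branching between
#' competing exits of a transient stage uses fractional hazard allocation
#' instead (see the methods vignette), so that stage case-fatality
#' probabilities are honoured exactly.
#'
#' @param p probability in [0, 1).
#' @param tau period length in years.
#' @return hazard per year.
#' @export
probToHazard <- function(p, tau) {
  stopifnot(all(p >= 0), all(p < 1), all(tau > 0))
  -log(1 - p) / tau
}

#' Write a ParameterSet to a YAML file
#'
#' The file carries a `schema_version` key and the blocks
#' `meta`, `demography`, `natural_history`, `strategies`, `economics`,
#' `uncertainty`.
#'
#' @param params a [ParameterSet-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeParameterSet <- function(params, file) {
  doc <- c(list(schema_version = params@meta$schema_version,
                meta = params@meta[setdiff(names(params@meta), "schema_version")]),
           params@values,
           list(uncertainty = if (nrow(params@uncertainty))
             lapply(seq_len(nrow(params@uncertainty)), function(i)
               as.list(params@uncertainty[i, ])) else list()))
  yaml::write_yaml(doc, file, precision = 15)
  invisible(file)
}

#' Read a ParameterSet from a YAML file
#'
#' Unknown top-level keys are errors (they are almost always typos in
#' parameter paths); a missing or unsupported `schema_version` is an error.
#'
#' @param file path to a YAML parameter file written by [writeParameterSet()].
#' @return A [ParameterSet-class].
#' @export
readParameterSet <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$schema_version))
    stop("parameter file lacks schema_version")
  if (!identical(as.character(doc$schema_version), SCHEMA_VERSION))
    stop("unsupported schema_version: ", doc$schema_version)
  known <- c("schema_version", "meta", PARAM_BLOCKS, "uncertainty")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  unc <- if (length(doc$uncertainty))
    do.call(rbind, lapply(doc$uncertainty, as.data.frame))
  else NULL
  meta <- doc$meta
  meta$schema_version <- as.character(doc$schema_version)
  meta$checkpoints <- as.numeric(unlist(meta$checkpoints))
  ParameterSet(doc[PARAM_BLOCKS], unc, meta)
}
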