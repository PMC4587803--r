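## Declarative model/experiment configuration (YAML or JSON via yaml::read_yaml,
## which parses both). Schema "micca/1":
##
##   schema: micca/1
##   model:
##     name: <label>
##     states: [r, p]
##     parameters: {kr: 1.0, ...}
##     rhs: {r: "kr - gr * r", ...}          # one expression per state
##     initial: {r: 0, p: 0}                 # numbers or parameter expressions
##     steady_state: {r: "kr / gr", ...}     # optional closed form
##     inputs: {u9: {type: constant, value: 0}, ...}   # optional defaults
##   experiments:
##     - name: decay
##       observe: [r, p]
##       times: [0.5, 1, 2]                  # or {from, to, length, spacing}
##       initial: {r: 10, p: 20}             # optional overrides
##       overrides: {ki: 0}                  # optional pinned parameters
##       inputs: {u9: {type: constant, value: 0}}
##       sd: 1
##       steady_state: false

configStop <- function(field, msg) {
  stop(sprintf("config field '%s': %s", field, msg), call. = FALSE)
}

#' Read a model + experiments configuration file
#'
#' Parses a YAML (or JSON) declaration of an ODE model and its experiments
#' (schema `micca/1`, documented in the package sources and the example
#' files under `inst/extdata/`). RHS and initial-condition expressions are
#' parsed symbolically, giving analytic Jacobians for the sensitivity
#' system whenever possible.
#'
#' @param path path to the configuration file.
#' @return list with elements `model` (an [odeModel()]) and `experiments`
#'   (named list of [experiment()]s).
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema) || !identical(cfg$schema, "micca/1"))
    configStop("schema", "expected 'micca/1'")
  mc <- cfg$model
  if (is.null(mc)) configStop("model", "missing")
  states <- as.character(unlist(mc$states))
  if (!length(states)) configStop("model.states", "at least one state required")
  if (is.null(mc$rhs) || !length(mc$rhs))
    configStop("model.rhs",
               "no state equations; supply one expression per state (for the bundled NF-kB stub these must be filled in from the published supplementary model)")
  if (is.null(mc$parameters) || !length(mc$parameters))
    configStop("model.parameters", "named parameter values required")
  params <- unlist(mc$parameters)
  if (!is.numeric(params)) configStop("model.parameters", "values must be numeric")
  rhs <- vapply(mc$rhs, as.character, "")
  if (!setequal(names(rhs), states))
    configStop("model.rhs", "must give exactly one expression per state")
  initial <- parseConfigInitial(mc$initial, states)
  inputs <- parseConfigInputs(mc$inputs, "model.inputs")
  ss <- NULL
  if (!is.null(mc$steady_state)) {
    ss <- vapply(mc$steady_state, as.character, "")
    if (!setequal(names(ss), states))
      configStop("model.steady_state", "must give one expression per state")
  }
  model <- odeModel(states = states, params = params, rhs = rhs[states],
                    initial = initial, inputs = inputs, steady_state = ss,
                    name = if (is.null(mc$name)) "model" else mc$name)

  exps <- cfg$experiments
  if (is.null(exps) || !length(exps)) configStop("experiments", "at least one required")
  experiments <- list()
  for (i in seq_along(exps)) {
    e <- exps[[i]]
    field <- sprintf("experiments[%d]", i)
    if (is.null(e$observe)) configStop(paste0(field, ".observe"), "missing")
    times <- parseConfigTimes(e$times, paste0(field, ".times"))
    ov <- if (is.null(e$overrides)) NULL else unlist(e$overrides)
    ini <- if (is.null(e$initial)) NULL else unlist(e$initial)
    nm <- if (is.null(e$name)) sprintf("experiment_%d", i) else e$name
    experiments[[nm]] <- experiment(
      observe = as.character(unlist(e$observe)), times = times, name = nm,
      inputs = parseConfigInputs(e$inputs, paste0(field, ".inputs")),
      overrides = ov, initial = ini,
      sd = if (is.null(e$sd)) 1 else e$sd,
      steady_state = isTRUE(e$steady_state)
    )
  }
  list(model = model, experiments = experiments)
}

parseConfigInitial <- function(x, states) {
  if (is.null(x)) return(NULL)
  vals <- unlist(x)
  if (is.numeric(vals)) return(vals[states])
  setNames(as.character(vals)[match(states, names(vals))], states)
}

parseConfigTimes <- function(x, field) {
  if (is.null(x)) configStop(field, "missing")
  if (is.list(x) && !is.null(x$from)) {
    for (f in c("from", "to", "length"))
      if (is.null(x[[f]])) configStop(field, paste0("grid spec needs '", f, "'"))
    if (identical(x$spacing, "log")) {
      if (x$from <= 0) configStop(field, "log spacing needs from > 0")
      return(exp(seq(log(x$from), log(x$to), length.out = x$length)))
    }
    return(seq(x$from, x$to, length.out = x$length))
  }
  as.numeric(unlist(x))
}

parseConfigInputs <- function(x, field) {
  if (is.null(x) || !length(x)) return(list())
  out <- list()
  for (nm in names(x)) {
    spec <- x[[nm]]
    f <- paste0(field, ".", nm)
    if (is.null(spec$type)) configStop(f, "input needs a 'type'")
    out[[nm]] <- switch(spec$type,
      constant = constantInput(if (is.null(spec$value)) 0 else spec$value),
      piecewise_linear = piecewiseLinear(as.numeric(unlist(spec$times)),
                                         as.numeric(unlist(spec$values))),
      piecewise_constant = piecewiseConstant(as.numeric(unlist(spec$times)),
                                             as.numeric(unlist(spec$values))),
      configStop(f, paste0("unknown input type '", spec$type, "'"))
    )
  }
  out
}
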