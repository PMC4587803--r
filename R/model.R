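#' Declare an ODE model
#'
#' A model is a set of states, a named vector of reference parameter values
#' and one right-hand-side expression per state, written in terms of state
#' names, parameter names, input names and `t`. Expressions are parsed and
#' differentiated symbolically, so the Jacobians \eqn{\partial F/\partial y}
#' and \eqn{\partial F/\partial \theta} needed by forward sensitivity
#' analysis are available analytically whenever [stats::D()] can handle the
#' expression; otherwise a finite-difference fallback is used downstream.
#'
#' @param states character vector of state names (length k >= 1).
#' @param params named numeric vector of reference parameter values
#'   \eqn{\theta^*} (length l >= 1).
#' @param rhs named character vector of RHS expressions, one per state
#'   (names must match `states`).
#' @param initial initial condition: a named numeric vector, or named
#'   character expressions in the parameters (evaluated at simulation time).
#'   Defaults to all zeros.
#' @param inputs named list of default input signal functions `u(t)` (see
#'   [piecewiseLinear()]); input names may appear in `rhs`.
#' @param steady_state optional named character vector of closed-form
#'   steady-state expressions in the parameters, one per state (an algebraic
#'   hook for models that have one; simulation never requires it).
#' @param name model label used in printing and reports.
#' @return an object of class `OdeModel`.
#' @examples
#' m <- odeModel(
#'   states = "y", params = c(gamma = 1),
#'   rhs = c(y = "-gamma * y"), initial = c(y = 1)
#' )
#' @seealso [experiment()], [simulateExperiment()], [forwardSensitivities()]
#' @export
odeModel <- function(states, params, rhs, initial = NULL, inputs = list(),
                     steady_state = NULL, name = "model") {
  stopifnot(is.character(states), length(states) >= 1L, !anyDuplicated(states))
  if (is.null(names(params)) || any(names(params) == ""))
    stop("`params` must be a fully named numeric vector")
  stopifnot(is.numeric(params), length(params) >= 1L, !anyDuplicated(names(params)))
  if (any(!is.finite(params))) stop("non-finite reference parameter value")
  if (length(intersect(states, names(params))))
    stop("state and parameter names must not overlap")
  if (is.null(names(rhs)) && length(rhs) == length(states)) names(rhs) <- states
  if (!setequal(names(rhs), states))
    stop("`rhs` must supply exactly one expression per state")
  rhs <- rhs[states]
  if (length(inputs)) {
    stopifnot(is.list(inputs), !is.null(names(inputs)))
    if (!all(vapply(inputs, is.function, TRUE)))
      stop("model inputs must be functions of time")
  }

  exprs <- lapply(rhs, function(s) parse(text = s)[[1]])
  symb <- TRUE
  dy <- dth <- NULL
  tr <- try({
    dy  <- lapply(exprs, function(e) lapply(states, function(v) stats::D(e, v)))
    dth <- lapply(exprs, function(e) lapply(names(params), function(v) stats::D(e, v)))
  }, silent = TRUE)
  if (inherits(tr, "try-error")) { symb <- FALSE; dy <- dth <- NULL }

  init <- parseInitial(initial, states, names(params))

  ss_exprs <- NULL
  if (!is.null(steady_state)) {
    if (!setequal(names(steady_state), states))
      stop("`steady_state` must give one expression per state")
    ss_exprs <- lapply(steady_state[states], function(s) parse(text = s)[[1]])
  }

  structure(list(
    name = name, states = states, params = params, rhs_text = rhs,
    rhs_exprs = exprs, jac_y = dy, jac_theta = dth, symbolic = symb,
    initial = init, inputs = inputs, steady_state = ss_exprs
  ), class = "OdeModel")
}

parseInitial <- function(initial, states, param_names) {
  k <- length(states)
  if (is.null(initial)) initial <- setNames(rep(0, k), states)
  if (is.numeric(initial)) {
    if (is.null(names(initial)) && length(initial) == k) names(initial) <- states
    if (!setequal(names(initial), states))
      stop("`initial` must cover every state")
    return(list(type = "numeric", values = initial[states]))
  }
  if (is.character(initial)) {
    if (!setequal(names(initial), states))
      stop("`initial` must cover every state")
    ex <- lapply(initial[states], function(s) parse(text = s)[[1]])
    dex <- try(lapply(ex, function(e) lapply(param_names, function(v) stats::D(e, v))),
               silent = TRUE)
    if (inherits(dex, "try-error")) dex <- NULL
    return(list(type = "expr", exprs = ex, dexprs = dex))
  }
  stop("`initial` must be numeric or character expressions")
}

#' @export
print.OdeModel <- function(x, ...) {
  cat(sprintf("OdeModel '%s': %d state(s), %d parameter(s)\n",
              x$name, length(x$states), length(x$params)))
  for (s in x$states) cat(sprintf("  d%s/dt = %s\n", s, x$rhs_text[[s]]))
  cat("  theta*:", paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", "), "\n")
  if (length(x$inputs)) cat("  inputs:", paste(names(x$inputs), collapse = ", "), "\n")
  invisible(x)
}

#' Declare an experiment
#'
#' An experiment fixes which states are observed, at which times, under what
#' stimulation and genetic perturbation, and with what observation error
#' scale. Observations are gathered time-major: all observed components at
#' `times[1]`, then at `times[2]`, and so on — the ordering used consistently
#' by [extractObservations()] and [buildSensitivityMatrix()].
#'
#' @param observe state names (or indices) observed, q >= 1 of them.
#' @param times strictly increasing observation times, all > 0 unless 0 is
#'   the first entry.
#' @param name experiment label.
#' @param inputs named list of input functions overriding the model defaults
#'   for this experiment (e.g. a different stimulation profile, or
#'   `constantInput(0)` for a knockout of an upstream species).
#' @param overrides named numeric vector pinning parameters to known values
#'   in this condition (e.g. a rate set to 0 for a genetic knockout). A
#'   pinned parameter is treated as known, so this experiment carries no
#'   information about it: its sensitivity column is zero in this block.
#' @param initial named numeric vector replacing (part of) the model's
#'   initial condition, e.g. concentrations pushed above steady state.
#' @param sd observation error scale sigma > 0 (default 1, unit-variance
#'   Gaussian error); sensitivity rows of this experiment are divided by it.
#' @param steady_state if `TRUE` the experiment is meant to sample a steady
#'   state: after simulation the residual \eqn{\|dy/dt\|_\infty} at the last
#'   time is checked against \eqn{10^{-10}\,\|y\|_\infty} and a warning is
#'   raised when the system has not settled.
#' @return an object of class `Experiment`.
#' @export
experiment <- function(observe, times, name = "", inputs = NULL,
                       overrides = NULL, initial = NULL, sd = 1,
                       steady_state = FALSE) {
  stopifnot(length(observe) >= 1L, length(times) >= 1L)
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (any(times < 0)) stop("observation times must be non-negative")
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0) stop("`sd` must be a positive scalar")
  if (!is.null(overrides) &&
      (is.null(names(overrides)) || !is.numeric(overrides)))
    stop("`overrides` must be a named numeric vector")
  if (!is.null(initial) && (is.null(names(initial)) || !is.numeric(initial)))
    stop("`initial` must be a named numeric vector")
  if (!is.null(inputs) && length(inputs) &&
      (!is.list(inputs) || is.null(names(inputs))))
    stop("`inputs` must be a named list of functions")
  structure(list(
    name = name, observe = observe, times = as.numeric(times),
    inputs = inputs, overrides = overrides, initial = initial,
    sd = sd, steady_state = isTRUE(steady_state)
  ), class = "Experiment")
}

#' @export
print.Experiment <- function(x, ...) {
  cat(sprintf("Experiment '%s': observe {%s} at %d time(s), sd=%g\n",
              x$name, paste(x$observe, collapse = ", "), length(x$times), x$sd))
  if (length(x$overrides))
    cat("  overrides:", paste(sprintf("%s=%g", names(x$overrides), x$overrides),
                              collapse = ", "), "\n")
  invisible(x)
}

## ---- evaluation helpers ------------------------------------------------

effectiveParams <- function(model, exp) {
  th <- model$params
  if (length(exp$overrides)) {
    unknown <- setdiff(names(exp$overrides), names(th))
    if (length(unknown))
      stop("override of unknown parameter(s): ", paste(unknown, collapse = ", "))
    th[names(exp$overrides)] <- exp$overrides
  }
  th
}

effectiveInputs <- function(model, exp) {
  ins <- model$inputs
  if (length(exp$inputs)) {
    for (nm in names(exp$inputs)) ins[[nm]] <- exp$inputs[[nm]]
  }
  ins
}

evalInputs <- function(inputs, t) {
  if (!length(inputs)) return(list())
  lapply(inputs, function(f) f(t))
}

rhsEnv <- function(model, t, y, theta, uvals) {
  e <- c(as.list(theta), setNames(as.list(y), model$states), uvals, list(t = t))
  e
}

evalRhs <- function(model, t, y, theta, uvals) {
  env <- rhsEnv(model, t, y, theta, uvals)
  vapply(model$rhs_exprs, function(ex) eval(ex, env), 0)
}

evalJacY <- function(model, t, y, theta, uvals) {
  env <- rhsEnv(model, t, y, theta, uvals)
  k <- length(model$states)
  J <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    J[i, j] <- eval(model$jac_y[[i]][[j]], env)
  J
}

evalJacTheta <- function(model, t, y, theta, uvals) {
  env <- rhsEnv(model, t, y, theta, uvals)
  k <- length(model$states); l <- length(model$params)
  J <- matrix(0, k, l)
  for (i in seq_len(k)) for (j in seq_len(l))
    J[i, j] <- eval(model$jac_theta[[i]][[j]], env)
  J
}

evalInitialCondition <- function(model, exp, theta) {
  init <- model$initial
  y0 <- if (init$type == "numeric") init$values
        else vapply(init$exprs, function(ex) eval(ex, as.list(theta)), 0)
  y0 <- setNames(as.numeric(y0), model$states)
  if (length(exp$initial)) {
    unknown <- setdiff(names(exp$initial), model$states)
    if (length(unknown))
      stop("initial override of unknown state(s): ", paste(unknown, collapse = ", "))
    y0[names(exp$initial)] <- exp$initial
  }
  y0
}

## d y(0) / d theta, a k x l matrix; experiment-overridden states contribute 0
initialSensitivity <- function(model, exp, theta) {
  k <- length(model$states); l <- length(model$params)
  Z0 <- matrix(0, k, l)
  init <- model$initial
  if (init$type == "expr") {
    if (!is.null(init$dexprs)) {
      for (i in seq_len(k)) for (j in seq_len(l))
        Z0[i, j] <- eval(init$dexprs[[i]][[j]], as.list(theta))
    } else {
      h <- 1e-6 * abs(theta) + 1e-12
      for (j in seq_len(l)) {
        tp <- tm <- theta
        tp[j] <- theta[j] + h[j]; tm[j] <- theta[j] - h[j]
        yp <- vapply(init$exprs, function(ex) eval(ex, as.list(tp)), 0)
        ym <- vapply(init$exprs, function(ex) eval(ex, as.list(tm)), 0)
        Z0[, j] <- (yp - ym) / (2 * h[j])
      }
    }
  }
  if (length(exp$initial)) Z0[match(names(exp$initial), model$states), ] <- 0
  Z0
}

## ---- simulation --------------------------------------------------------

## Piecewise integration across declared input breakpoints with a
## stiff-capable solver (lsoda). `system` maps (t, state) -> d(state)/dt over
## a state vector of arbitrary length (plain or augmented).
integrateSystem <- function(system, y0, times, breakpoints,
                            rtol = 1e-8, atol = 1e-10) {
  t_max <- max(times)
  bounds <- sort(unique(c(0, breakpoints[breakpoints > 0 & breakpoints < t_max], t_max)))
  want <- sort(unique(c(0, times)))
  out <- matrix(NA_real_, length(want), length(y0))
  out[1, ] <- y0
  cur <- y0
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    tt <- sort(unique(c(lo, want[want > lo & want <= hi], hi)))
    sol <- deSolve::ode(
      y = cur, times = tt,
      func = function(t, y, p) list(system(t, y)),
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("ODE solver failed on time span [%g, %g]", lo, hi))
    if (any(!is.finite(sol[, -1])))
      stop(sprintf("non-finite solution on time span [%g, %g]", lo, hi))
    idx <- match(tt[tt %in% want], want)
    out[idx, ] <- sol[match(tt[tt %in% want], sol[, 1]), -1, drop = FALSE]
    cur <- as.numeric(sol[nrow(sol), -1])
  }
  list(times = want, values = out)
}

#' Simulate an experiment
#'
#' Integrates the model under the experiment's input profiles, parameter
#' overrides and initial-condition overrides, and returns the states at the
#' requested observation times. A stiff-capable solver (`lsoda`) is used
#' with tight tolerances because downstream canonical correlations close to
#' 1 are sensitive to trajectory accuracy.
#'
#' @param model an [odeModel()].
#' @param exp an [experiment()].
#' @param rtol,atol relative and absolute solver tolerances.
#' @return an object of class `Trajectory`: `times`, and `states`
#'   (an n x k matrix). For steady-state experiments the residual check
#'   result is attached as attribute `"steady_residual"`.
#' @export
simulateExperiment <- function(model, exp, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "OdeModel"), inherits(exp, "Experiment"))
  observedIndices(model, exp)  # validate early
  theta <- effectiveParams(model, exp)
  inputs <- effectiveInputs(model, exp)
  y0 <- evalInitialCondition(model, exp, theta)
  sys <- function(t, y) {
    u <- evalInputs(inputs, t)
    dy <- evalRhs(model, t, y, theta, u)
    if (any(!is.finite(dy)))
      stop(sprintf("non-finite RHS at t=%g", t))
    dy
  }
  sol <- integrateSystem(sys, y0, exp$times, inputBreakpoints(inputs, max(exp$times)),
                         rtol = rtol, atol = atol)
  keep <- match(exp$times, sol$times)
  states <- sol$values[keep, , drop = FALSE]
  colnames(states) <- model$states
  traj <- structure(list(times = exp$times, states = states,
                         experiment = exp$name),
                    class = "Trajectory")
  if (exp$steady_state) {
    yT <- states[nrow(states), ]
    res <- max(abs(sys(max(exp$times), yT)))
    lim <- 1e-10 * max(abs(yT))
    attr(traj, "steady_residual") <- c(residual = res, limit = lim)
    if (res >= lim)
      warning(sprintf(
        "steady-state residual %.3g exceeds %.3g at t=%g; extend the horizon",
        res, lim, max(exp$times)))
  }
  traj
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%d time point(s), %d state(s))\n",
              length(x$times), ncol(x$states)))
  print(head(cbind(time = x$times, x$states)))
  invisible(x)
}

#' @export
as.data.frame.Trajectory <- function(x, ...) {
  k <- ncol(x$states)
  data.frame(
    time = rep(x$times, each = k),
    state = rep(colnames(x$states), times = length(x$times)),
    value = as.vector(t(x$states)),
    experiment_id = x$experiment,
    stringsAsFactors = FALSE
  )
}

observedIndices <- function(model, exp) {
  obs <- exp$observe
  if (is.character(obs)) {
    idx <- match(obs, model$states)
    if (anyNA(idx)) stop("observed state(s) not in model: ",
                         paste(obs[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(obs)
    if (any(idx < 1L | idx > length(model$states)))
      stop("observed state index out of range")
  }
  idx
}

#' Extract the observation vector Y
#'
#' Flattens the observed components of a trajectory into the observation
#' vector \eqn{Y = (y^{(q)}(t_1), \ldots, y^{(q)}(t_n))}, time-major: all
#' observed components at the first time, then at the second, etc. Length is
#' always q * n.
#'
#' @param traj a `Trajectory` from [simulateExperiment()].
#' @param model the model the trajectory came from.
#' @param exp the experiment defining observed components and times.
#' @return numeric vector of length q * n with a `"labels"` attribute
#'   (data frame of time and state per entry).
#' @export
extractObservations <- function(traj, model, exp) {
  idx <- observedIndices(model, exp)
  if (!all(exp$times %in% traj$times))
    stop("trajectory does not cover all experiment times")
  rows <- match(exp$times, traj$times)
  Y <- as.vector(t(traj$states[rows, idx, drop = FALSE]))
  attr(Y, "labels") <- data.frame(
    time = rep(exp$times, each = length(idx)),
    state = rep(model$states[idx], times = length(exp$times)),
    stringsAsFactors = FALSE
  )
  Y
}

#' Closed-form steady state, when the model declares one
#'
#' Evaluates the model's algebraic steady-state expressions at a parameter
#' vector (reference values by default). Models without the algebraic hook
#' must use a steady-state [experiment()] instead.
#'
#' @param model an [odeModel()] constructed with `steady_state=`.
#' @param theta parameter vector; defaults to the reference values.
#' @return named numeric vector of steady-state levels.
#' @export
steadyState <- function(model, theta = NULL) {
  if (is.null(model$steady_state))
    stop("model '", model$name, "' declares no closed-form steady state")
  if (is.null(theta)) theta <- model$params
  vapply(model$steady_state, function(ex) eval(ex, as.list(theta)), 0)
}
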