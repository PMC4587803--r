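#' Forward sensitivity analysis
#'
#' Solves the augmented forward-sensitivity system
#' \deqn{\dot z_i = (\partial F/\partial y)\, z_i + \partial F/\partial \theta_i,
#'       \qquad z_i(0) = \partial y(0)/\partial \theta_i,}
#' jointly for all parameters (one system of k(l+1) states per experiment),
#' and returns the state trajectory together with \eqn{z_i(t)} at the
#' experiment's observation times. Parameters pinned by the experiment's
#' `overrides` are known in that condition, so their sensitivity columns are
#' zero in this block.
#'
#' @param model an [odeModel()]; analytic Jacobians are used when the RHS
#'   could be differentiated symbolically.
#' @param exp an [experiment()].
#' @param fd_fallback when symbolic Jacobians are unavailable, approximate
#'   \eqn{\partial F/\partial y} and \eqn{\partial F/\partial\theta} by
#'   central differences of the RHS inside the augmented system; set to
#'   `FALSE` to error instead.
#' @param rtol,atol solver tolerances.
#' @return list of class `Sensitivities`: `times`, `y` (n x k states),
#'   `Z` (n x k x l array of \eqn{\partial y_j(t)/\partial\theta_i}),
#'   `overridden` (parameter names pinned in this experiment).
#' @export
forwardSensitivities <- function(model, exp, fd_fallback = TRUE,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "OdeModel"), inherits(exp, "Experiment"))
  k <- length(model$states); l <- length(model$params)
  theta <- effectiveParams(model, exp)
  inputs <- effectiveInputs(model, exp)
  if (!model$symbolic && !fd_fallback)
    stop("symbolic Jacobians unavailable for model '", model$name,
         "' and finite-difference fallback is disabled")
  jacY <- if (model$symbolic) evalJacY else fdJacY
  jacT <- if (model$symbolic) evalJacTheta else fdJacTheta

  y0 <- evalInitialCondition(model, exp, theta)
  Z0 <- initialSensitivity(model, exp, theta)
  sys <- function(t, s) {
    y <- s[seq_len(k)]
    Z <- matrix(s[-seq_len(k)], k, l)
    u <- evalInputs(inputs, t)
    dy <- evalRhs(model, t, y, theta, u)
    if (any(!is.finite(dy))) stop(sprintf("non-finite RHS at t=%g", t))
    dZ <- jacY(model, t, y, theta, u) %*% Z + jacT(model, t, y, theta, u)
    c(dy, as.vector(dZ))
  }
  sol <- integrateSystem(sys, c(y0, as.vector(Z0)), exp$times,
                         inputBreakpoints(inputs, max(exp$times)),
                         rtol = rtol, atol = atol)
  keep <- match(exp$times, sol$times)
  n <- length(exp$times)
  y <- sol$values[keep, seq_len(k), drop = FALSE]
  colnames(y) <- model$states
  Z <- array(sol$values[keep, -seq_len(k)], dim = c(n, k, l),
             dimnames = list(NULL, model$states, names(model$params)))
  over <- intersect(names(exp$overrides), names(model$params))
  if (length(over)) Z[, , over] <- 0
  structure(list(times = exp$times, y = y, Z = Z, overridden = over),
            class = "Sensitivities")
}

fdJacY <- function(model, t, y, theta, u) {
  k <- length(y)
  J <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-7 * max(abs(y[j]), 1)
    yp <- ym <- y; yp[j] <- y[j] + h; ym[j] <- y[j] - h
    J[, j] <- (evalRhs(model, t, yp, theta, u) - evalRhs(model, t, ym, theta, u)) / (2 * h)
  }
  J
}

fdJacTheta <- function(model, t, y, theta, u) {
  l <- length(theta)
  J <- matrix(0, length(y), l)
  for (j in seq_len(l)) {
    h <- 1e-7 * max(abs(theta[j]), 1)
    tp <- tm <- theta; tp[j] <- theta[j] + h; tm[j] <- theta[j] - h
    J[, j] <- (evalRhs(model, t, y, tp, u) - evalRhs(model, t, y, tm, u)) / (2 * h)
  }
  J
}

#' Finite-difference sensitivities (independent oracle)
#'
#' Central differences of the simulated trajectory with relative step
#' \eqn{h = 10^{-6}\,\theta_i^*}. Used to cross-validate
#' [forwardSensitivities()]; not intended as the production path.
#'
#' @inheritParams forwardSensitivities
#' @param rel_step relative perturbation size.
#' @return the same shape as [forwardSensitivities()].
#' @export
finiteDifferenceSensitivities <- function(model, exp, rel_step = 1e-6,
                                          rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "OdeModel"), inherits(exp, "Experiment"))
  if (any(model$params <= 0))
    stop("finite-difference oracle requires theta* in the positive orthant")
  k <- length(model$states); l <- length(model$params)
  n <- length(exp$times)
  Z <- array(0, dim = c(n, k, l),
             dimnames = list(NULL, model$states, names(model$params)))
  simAt <- function(th) {
    m2 <- model; m2$params <- th
    tr <- simulateExperiment(m2, exp, rtol = rtol, atol = atol)
    if (any(!is.finite(tr$states))) stop("non-finite simulated values")
    tr$states
  }
  for (j in seq_len(l)) {
    h <- rel_step * model$params[j]
    tp <- tm <- model$params
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    Z[, , j] <- (simAt(tp) - simAt(tm)) / (2 * h)
  }
  base <- simulateExperiment(model, exp, rtol = rtol, atol = atol)
  structure(list(times = exp$times, y = base$states, Z = Z,
                 overridden = intersect(names(exp$overrides), names(model$params))),
            class = "Sensitivities")
}

#' Build the stacked sensitivity matrix S
#'
#' Evaluates the sensitivity time-courses at each experiment's observed
#' components and times, flattens them in the documented time-major order,
#' divides each experiment's rows by its error scale sigma, stacks the
#' blocks vertically, and (by default) converts columns to the logarithmic
#' parametrisation by multiplying column i with the reference value
#' \eqn{\theta_i^*} (chain rule for \eqn{\log\theta_i}), so that column
#' norms bound relative estimation error.
#'
#' @param model an [odeModel()].
#' @param experiments a single [experiment()] or a list of them.
#' @param log_scale analyse sensitivities with respect to \eqn{\log\theta}
#'   (default, matching the package's identifiability conventions); requires
#'   strictly positive reference values.
#' @param method `"forward"` (augmented system) or `"fd"` (the
#'   finite-difference oracle).
#' @param ... passed to the sensitivity backend.
#' @return object of class `SensitivityMatrix`: `values` (R x l matrix,
#'   R = sum of q*n over experiments), `param_names`, `log_scale`,
#'   `row_info` (experiment, time, state per row).
#' @export
buildSensitivityMatrix <- function(model, experiments, log_scale = TRUE,
                                   method = c("forward", "fd"), ...) {
  method <- match.arg(method)
  if (inherits(experiments, "Experiment")) experiments <- list(experiments)
  stopifnot(length(experiments) >= 1L)
  if (log_scale && any(model$params <= 0))
    stop("log-parametrisation requires strictly positive reference values")
  backend <- switch(method, forward = forwardSensitivities,
                    fd = finiteDifferenceSensitivities)
  blocks <- vector("list", length(experiments))
  infos <- vector("list", length(experiments))
  for (e in seq_along(experiments)) {
    exp <- experiments[[e]]
    idx <- observedIndices(model, exp)
    fs <- backend(model, exp, ...)
    n <- length(exp$times); q <- length(idx); l <- length(model$params)
    B <- matrix(0, n * q, l)
    r <- 0L
    for (ti in seq_len(n)) for (j in idx) {
      r <- r + 1L
      B[r, ] <- fs$Z[ti, j, ]
    }
    blocks[[e]] <- B / exp$sd
    infos[[e]] <- data.frame(
      experiment = if (nzchar(exp$name)) exp$name else paste0("experiment_", e),
      time = rep(exp$times, each = q),
      state = rep(model$states[idx], times = n),
      sd = exp$sd, stringsAsFactors = FALSE
    )
  }
  V <- do.call(rbind, blocks)
  if (log_scale) V <- V %*% diag(model$params, length(model$params))
  colnames(V) <- names(model$params)
  structure(list(values = V, param_names = names(model$params),
                 log_scale = log_scale, row_info = do.call(rbind, infos),
                 theta = model$params),
            class = "SensitivityMatrix")
}

#' @export
print.SensitivityMatrix <- function(x, ...) {
  cat(sprintf("SensitivityMatrix: %d observation row(s) x %d parameter(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) " (log-parametrisation)" else ""))
  cat("  experiments:", paste(unique(x$row_info$experiment), collapse = ", "), "\n")
  cat("  column norms:", paste(sprintf("%s=%.3g", x$param_names,
                                       sqrt(colSums(x$values^2))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.SensitivityMatrix <- function(x, ...) {
  cbind(x$row_info, as.data.frame(x$values))
}

#' Fisher information matrix
#'
#' \eqn{FI(\theta) = S^T S} for the sigma-scaled sensitivity matrix (Gaussian
#' observation error). Diagonal entries are the squared sensitivity norms
#' \eqn{\|S_i\|^2}; off-diagonal entries give pairwise cosines when
#' normalised.
#'
#' @param S a [buildSensitivityMatrix()] result (or a plain matrix).
#' @return l x l symmetric matrix.
#' @export
fim <- function(S) {
  V <- sensValues(S)
  crossprod(V)
}

sensValues <- function(S) {
  if (inherits(S, "SensitivityMatrix")) S$values
  else if (is.matrix(S)) S
  else stop("expected a SensitivityMatrix or a matrix")
}

#' Write a sensitivity matrix (and its FIM) to CSV
#'
#' @param S a `SensitivityMatrix`.
#' @param file path for the sensitivity CSV (row labels + one column per
#'   parameter).
#' @param fim_file optional path for the FIM as CSV.
#' @return `file`, invisibly.
#' @export
writeSensitivityCSV <- function(S, file, fim_file = NULL) {
  stopifnot(inherits(S, "SensitivityMatrix"))
  utils::write.csv(as.data.frame(S), file, row.names = FALSE)
  if (!is.null(fim_file))
    utils::write.csv(as.data.frame(fim(S)), fim_file, row.names = FALSE)
  invisible(file)
}
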