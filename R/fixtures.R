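#' Built-in gene expression fixture
#'
#' A two-state gene expression model: mRNA `r` is produced at rate `kr` and
#' degraded at rate `gr`; protein `p` is translated from mRNA at rate `kp`
#' and degraded at rate `gp`:
#' \deqn{dr/dt = k_r - \gamma_r r, \qquad dp/dt = k_p r - \gamma_p p,}
#' with closed-form steady state \eqn{(k_r/\gamma_r,\; k_r k_p/(\gamma_r
#' \gamma_p))}. Reference rates are order-1 with mRNA turning over faster
#' than protein (kr = 1, kp = 1, gr = 2, gp = 0.3, model units).
#'
#' Two canonical experiments are bundled:
#' \describe{
#'   \item{steady_state}{both states observed once after the system has
#'     settled (t = 100; the residual check of [experiment()] applies). At
#'     steady state only the ratios kr/gr and kp/gp are constrained, so
#'     every parameter can be fully compensated within the pair structure
#'     and none is identifiable at delta = 0.95.}
#'   \item{decay}{both concentrations pushed well above steady state
#'     (r(0) = 10, p(0) = 20) and the relaxation transient sampled on a
#'     log-spaced grid (24 times in \[0.05, 20\]), which breaks the ratio
#'     compensations and renders all four parameters identifiable at
#'     (0.95, 1).}
#' }
#'
#' @return a `FixtureSpec` list: `name`, `model` ([odeModel()]),
#'   `experiments` (named list).
#' @export
geneExpressionFixture <- function() {
  model <- odeModel(
    states = c("r", "p"),
    params = c(kr = 1, kp = 1, gr = 2, gp = 0.3),
    rhs = c(r = "kr - gr * r", p = "kp * r - gp * p"),
    initial = c(r = 0, p = 0),
    steady_state = c(r = "kr / gr", p = "kr * kp / (gr * gp)"),
    name = "gene_expression"
  )
  experiments <- list(
    steady_state = experiment(
      observe = c("r", "p"), times = 100, name = "steady_state",
      steady_state = TRUE
    ),
    decay = experiment(
      observe = c("r", "p"),
      times = exp(seq(log(0.05), log(20), length.out = 24)),
      initial = c(r = 10, p = 20),
      name = "decay"
    )
  )
  structure(list(name = "gene_expression", model = model,
                 experiments = experiments), class = "FixtureSpec")
}

#' Built-in IKKK activation fixture
#'
#' A single-ODE sub-model of kinase (IKKK) activation under cytokine
#' stimulation:
#' \deqn{\dot y_1 = ka\, u_{16}(t)\, (KN - y_1)\, \frac{ka20}{ka20 + u_9(t)}
#'       - ki\, y_1,}
#' where \eqn{u_{16}(t)} is the activated-receptor time-course and
#' \eqn{u_9(t)} the cytoplasmic A20 protein level, both supplied as
#' documented synthetic stand-in forcing profiles (a smooth receptor pulse
#' peaking early, and a saturating A20 rise). Parameters: activation rate
#' `ka`, total kinase level `KN`, inhibition constant `ka20`, inactivation
#' rate `ki`.
#'
#' Three canonical experiments observe \eqn{y_1} on a common grid:
#' \describe{
#'   \item{wild_type}{both forcings at their defaults. A20 feedback keeps
#'     the activated fraction low, so ka, KN and ki act near-redundantly
#'     and all fail the delta-condition.}
#'   \item{a20_knockout}{\eqn{u_9 \equiv 0}, making the inhibitory factor
#'     identically 1 (so this block carries no information about ka20) and
#'     letting activation approach saturation at KN.}
#'   \item{knockout_blocked_phosphatase}{additionally the inactivation
#'     branch is blocked (`ki` pinned to 0), isolating the activation
#'     kinetics. Stacking all three experiments renders ka, KN and ki
#'     identifiable at (0.95, 1).}
#' }
#'
#' @return a `FixtureSpec` list (see [geneExpressionFixture()]).
#' @export
ikkkFixture <- function() {
  receptor_pulse <- function(t) (t / 2) * exp(1 - t / 2)
  a20_rise <- function(t) 2 * t^2 / (4 + t^2)
  model <- odeModel(
    states = "y1",
    params = c(ka = 1, KN = 1, ka20 = 0.1, ki = 0.5),
    rhs = c(y1 = "ka * u16 * (KN - y1) * ka20 / (ka20 + u9) - ki * y1"),
    initial = c(y1 = 0),
    inputs = list(u16 = receptor_pulse, u9 = a20_rise),
    name = "ikkk"
  )
  grid <- seq(0.5, 12, length.out = 24)
  experiments <- list(
    wild_type = experiment(
      observe = "y1", times = grid, name = "wild_type"
    ),
    a20_knockout = experiment(
      observe = "y1", times = grid, name = "a20_knockout",
      inputs = list(u9 = constantInput(0))
    ),
    knockout_blocked_phosphatase = experiment(
      observe = "y1", times = grid, name = "knockout_blocked_phosphatase",
      inputs = list(u9 = constantInput(0)),
      overrides = c(ki = 0)
    )
  )
  structure(list(name = "ikkk", model = model, experiments = experiments),
            class = "FixtureSpec")
}

#' Seeded random linear-chain fixture with planted compensations
#'
#' Generates a linear mass-action chain \eqn{y_1 \to y_2 \to \cdots} with
#' per-edge transfer rates and a terminal clearance rate, all drawn
#' log-uniformly from \[0.3, 3\] under the given seed. The chain starts
#' from \eqn{y(0) = (1, 0, \ldots, 0)} and every state is observed on a
#' fixed transient grid, so generically the sensitivity matrix has full
#' column rank and every merge sits at positive height.
#'
#' `planted_pairs` replaces that many rates \eqn{r_j} by ratios
#' \eqn{a_j/b_j} of two fresh parameters. The observable depends on the
#' pair only through the ratio, so in log-parametrisation the two
#' sensitivity columns are exact negatives: a guaranteed \eqn{\rho = 1}
#' pair that clustering must merge at (numerically) zero height and
#' resolve by pruning exactly one member — ground truth for the
#' clustering tests.
#'
#' @param seed integer seed (fixture is reproducible bit-for-bit per seed).
#' @param n_states chain length, >= 2.
#' @param planted_pairs number of rates replaced by ratio pairs (0 to
#'   `n_states`).
#' @return a `FixtureSpec` list; the planted pair parameter names are in
#'   `$planted` (list of character pairs). The single bundled experiment is
#'   named `transient`.
#' @export
randomChainFixture <- function(seed = 1L, n_states = 4L, planted_pairs = 0L) {
  stopifnot(n_states >= 2L)
  if (planted_pairs < 0L || planted_pairs > n_states)
    stop(sprintf("cannot plant %d pair(s) into %d rate(s)",
                 planted_pairs, n_states))
  set.seed(seed)
  rates <- exp(stats::runif(n_states, log(0.3), log(3)))
  states <- paste0("y", seq_len(n_states))
  params <- numeric(0)
  rate_sym <- character(n_states)
  planted <- list()
  for (j in seq_len(n_states)) {
    if (j <= planted_pairs) {
      scale <- exp(stats::runif(1, log(0.5), log(2)))
      a <- rates[j] * scale; b <- scale
      params[paste0("a", j)] <- a
      params[paste0("b", j)] <- b
      rate_sym[j] <- sprintf("(a%d / b%d)", j, j)
      planted[[length(planted) + 1L]] <- c(paste0("a", j), paste0("b", j))
    } else {
      params[paste0("r", j)] <- rates[j]
      rate_sym[j] <- paste0("r", j)
    }
  }
  rhs <- character(n_states)
  rhs[1] <- sprintf("-%s * y1", rate_sym[1])
  if (n_states > 1L) {
    for (i in 2:n_states)
      rhs[i] <- sprintf("%s * y%d - %s * y%d",
                        rate_sym[i - 1L], i - 1L, rate_sym[i], i)
  }
  names(rhs) <- states
  init <- setNames(c(1, rep(0, n_states - 1L)), states)
  model <- odeModel(states = states, params = params, rhs = rhs,
                    initial = init,
                    name = sprintf("chain_seed%d", seed))
  experiments <- list(
    transient = experiment(observe = states,
                           times = seq(0.5, 10, length.out = 8),
                           name = "transient")
  )
  structure(list(name = model$name, model = model, experiments = experiments,
                 planted = planted), class = "FixtureSpec")
}

#' @export
print.FixtureSpec <- function(x, ...) {
  cat(sprintf("FixtureSpec '%s': %d experiment(s): %s\n", x$name,
              length(x$experiments), paste(names(x$experiments), collapse = ", ")))
  print(x$model)
  invisible(x)
}

fixtureByName <- function(name, seed = 1L) {
  switch(name,
    gene_expression = geneExpressionFixture(),
    ikkk = ikkkFixture(),
    random_chain = randomChainFixture(seed = seed),
    stop("unknown fixture '", name,
         "'; available: gene_expression, ikkk, random_chain")
  )
}
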