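test_that("forward sensitivities match closed forms", {
  # z_gamma(t) = -t exp(-gamma t) for pure decay
  m <- odeModel("y", c(gamma = 0.7), c(y = "-gamma * y"), initial = c(y = 1))
  e <- experiment("y", times = seq(0.5, 5, by = 0.5))
  fw <- forwardSensitivities(m, e)
  expect_equal(fw$Z[, 1, 1], -e$times * exp(-0.7 * e$times), tolerance = 1e-7)

  # a parameter absent from RHS and initial condition has z identically 0
  m2 <- odeModel("y", c(gamma = 0.7, unused = 3), c(y = "-gamma * y"),
                 initial = c(y = 1))
  fw2 <- forwardSensitivities(m2, e)
  expect_equal(max(abs(fw2$Z[, 1, "unused"])), 0)

  # steady-state sensitivity of mRNA w.r.t. kr is 1/gr (raw scale)
  fx <- geneExpressionFixture()
  fss <- forwardSensitivities(fx$model, fx$experiments$steady_state)
  expect_equal(fss$Z[1, "r", "kr"], 1 / 2, tolerance = 1e-7)
})

test_that("forward and finite-difference sensitivities agree on all fixtures", {
  fixtures <- list(geneExpressionFixture(), ikkkFixture(),
                   randomChainFixture(seed = 11, n_states = 3))
  for (fx in fixtures) {
    for (nm in names(fx$experiments)) {
      fw <- forwardSensitivities(fx$model, fx$experiments[[nm]])
      fd <- finiteDifferenceSensitivities(fx$model, fx$experiments[[nm]])
      rel <- max(abs(fw$Z - fd$Z)) / max(abs(fw$Z))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("steady-state log-scale matrix matches the analytic column pattern", {
  fx <- geneExpressionFixture()
  S <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  Y <- unname(steadyState(fx$model))
  expected <- cbind(kr = Y, kp = c(0, Y[2]), gr = -Y, gp = c(0, -Y[2]))
  expect_equal(unname(S$values), unname(expected), tolerance = 1e-6)
})

test_that("stacking experiments is additive in the FIM", {
  fx <- geneExpressionFixture()
  S1 <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  S2 <- buildSensitivityMatrix(fx$model, fx$experiments["decay"])
  S12 <- buildSensitivityMatrix(fx$model, fx$experiments)
  expect_equal(fim(S12), fim(S1) + fim(S2), tolerance = 1e-14)

  # duplicated experiment doubles the FIM
  Sdup <- buildSensitivityMatrix(fx$model,
                                 fx$experiments[c("decay", "decay")])
  expect_equal(fim(Sdup), 2 * fim(S2), tolerance = 1e-14)
})

test_that("scaling contracts hold: sigma and log-parametrisation", {
  fx <- geneExpressionFixture()
  e1 <- fx$experiments$decay
  e2 <- e1; e2$sd <- 2
  S1 <- buildSensitivityMatrix(fx$model, e1)
  S2 <- buildSensitivityMatrix(fx$model, e2)
  expect_equal(S2$values, S1$values / 2, tolerance = 1e-14)

  raw <- buildSensitivityMatrix(fx$model, e1, log_scale = FALSE)
  logd <- raw$values %*% diag(fx$model$params, 4)
  expect_equal(unname(S1$values), unname(logd), tolerance = 1e-14)
})

test_that("overridden parameters carry no information in their block", {
  ik <- ikkkFixture()
  fw <- forwardSensitivities(ik$model,
                             ik$experiments$knockout_blocked_phosphatase)
  expect_equal(max(abs(fw$Z[, , "ki"])), 0)
  # and the A20-knockout block is insensitive to ka20 (factor identically 1)
  fko <- forwardSensitivities(ik$model, ik$experiments$a20_knockout)
  expect_lt(max(abs(fko$Z[, , "ka20"])), 1e-9)
})

test_that("sensitivity matrices round-trip to CSV with row labels", {
  fx <- geneExpressionFixture()
  S <- buildSensitivityMatrix(fx$model, fx$experiments)
  csv <- tempfile(fileext = ".csv"); fimcsv <- tempfile(fileext = ".csv")
  writeSensitivityCSV(S, csv, fim_file = fimcsv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(S$values))
  expect_equal(as.matrix(back[, S$param_names]), S$values,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$experiment, S$row_info$experiment)
  fimback <- utils::read.csv(fimcsv)
  expect_equal(as.matrix(fimback), fim(S), ignore_attr = TRUE,
               tolerance = 1e-12)
  unlink(c(csv, fimcsv))
})

test_that("log-parametrisation refuses non-positive reference values", {
  m <- odeModel("y", c(k = -1), c(y = "k * y"), initial = c(y = 1))
  e <- experiment("y", times = 1)
  expect_error(buildSensitivityMatrix(m, e), "strictly positive")
  expect_silent(buildSensitivityMatrix(m, e, log_scale = FALSE))
})
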