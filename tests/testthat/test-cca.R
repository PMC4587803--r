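test_that("canonical correlations recover exact geometric cases", {
  # orthogonal singletons
  S <- cbind(a = c(1, 0, 0), b = c(0, 1, 0))
  expect_equal(canonicalCorrelations(S, "a", "b")$rhos, 0)

  # proportional with opposite sign: fully compensative, rho = 1
  fx <- geneExpressionFixture()
  Sss <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  cc <- canonicalCorrelations(Sss, "kr", "gr")
  expect_equal(cc$rhos, 1, tolerance = 1e-9)
  expect_equal(pairwiseCosine(Sss, "kr", "gr"), -1, tolerance = 1e-9)

  # a 2-dim span contains any vector: rho1 = 1 although pairwise cosines
  # are only 1/sqrt(2) (joint non-identifiability with low pairwise corr)
  S3 <- cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2))
  cc3 <- canonicalCorrelations(S3, c("a", "b"), "c")
  expect_equal(cc3$rhos, 1, tolerance = 1e-12)
  expect_equal(pairwiseCosine(S3, "a", "c"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(pairwiseCosine(S3, "b", "c"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(bruteForceRho1(S3[, c("a", "b")], S3[, "c", drop = FALSE]), 1,
               tolerance = 1e-6)

  # pairwise cosine of a column with itself
  expect_equal(pairwiseCosine(S3, "a", "a"), 1)
})

test_that("rho1 matches brute-force grid maximisation on random subspaces", {
  for (seed in 1:40) {
    inst <- randomCcaInstance(seed)
    rho <- canonicalCorrelations(inst$S, inst$A, inst$B)$rhos[1]
    expect_equal(rho, bruteForceRho1(inst$S[, inst$A, drop = FALSE],
                                     inst$S[, inst$B, drop = FALSE]),
                 tolerance = 1e-6)
  }
})

test_that("CC sets are symmetric, nested-monotone and basis-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    S <- matrix(rnorm(6 * 5), 6, 5)
    colnames(S) <- paste0("p", 1:5)
    a <- canonicalCorrelations(S, 1:2, 3:4)
    b <- canonicalCorrelations(S, 3:4, 1:2)
    expect_equal(a$rhos, b$rhos, tolerance = 1e-12)

    # enlarging B cannot decrease rho1
    big <- canonicalCorrelations(S, 1:2, 3:5)
    expect_gte(big$rhos[1] + 1e-12, a$rhos[1])

    # invertible remixing within a group leaves the rhos unchanged
    M <- matrix(rnorm(4), 2, 2)
    while (abs(det(M)) < 0.1) M <- matrix(rnorm(4), 2, 2)
    S2 <- S
    S2[, 1:2] <- S[, 1:2] %*% M
    expect_equal(canonicalCorrelations(S2, 1:2, 3:4)$rhos, a$rhos,
                 tolerance = 1e-9)
  }
})

test_that("MI-CCA evaluates the printed formula with capping at rho = 1", {
  expect_equal(as.numeric(mutualInformation(0)), 0)
  expect_equal(as.numeric(mutualInformation(0.95)), -log(1 - 0.9025),
               tolerance = 1e-12)
  capped <- mutualInformation(1)
  expect_true(attr(capped, "capped"))
  expect_gt(as.numeric(capped), 20)
  expect_false(attr(mutualInformation(0.5), "capped"))
  # m includes rank-padding zeros, which contribute log(1) = 0
  expect_equal(as.numeric(mutualInformation(c(0.95, 0))),
               -log(1 - 0.9025) / 2, tolerance = 1e-12)
})

test_that("linkage height is the normalised average dissimilarity", {
  expect_equal(linkageHeight(c(1, 1)), 0)
  expect_equal(linkageHeight(0), 1)
  expect_equal(linkageHeight(c(1, 0)), 0.5)
})

test_that("MI and height are monotone mirrors: MI = 0 iff height = 1", {
  set.seed(7)
  for (rep in 1:25) {
    rhos <- sort(runif(3), decreasing = TRUE)
    mi <- as.numeric(mutualInformation(rhos))
    h <- linkageHeight(rhos)
    expect_gte(mi, 0)
    expect_true((mi == 0) == all(rhos == 0))
    expect_true((h == 1) == all(rhos == 0))
    # raising any rho raises MI and lowers height
    r2 <- rhos; r2[2] <- min(1 - 1e-9, r2[2] + 0.1)
    expect_gte(as.numeric(mutualInformation(sort(r2, decreasing = TRUE))), mi)
    expect_lte(linkageHeight(r2), h)
  }
})

test_that("corrWithRest handles singleton, empty and degenerate groups", {
  fx <- geneExpressionFixture()
  Sss <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  expect_equal(corrWithRest(Sss, "kr", character(0)), 0)
  expect_equal(corrWithRest(Sss, "kr", "gr"), 1, tolerance = 1e-9)
  S <- cbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  expect_equal(corrWithRest(S, "a", c("b", "c")), 0, tolerance = 1e-12)
  expect_error(corrWithRest(S, "a", c("a", "b")), "must not contain")
})

test_that("zero sensitivity columns are handled as specified", {
  S <- cbind(a = c(1, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(cc <- canonicalCorrelations(S, c("a", "b"), "c"),
                 "zero sensitivity")
  expect_equal(cc$rhos[1], 1 / sqrt(2), tolerance = 1e-12)
  Z <- cbind(a = c(0, 0), b = c(0, 0))
  expect_error(suppressWarnings(canonicalCorrelations(Z, "a", "b")),
               "entirely zero")
  expect_warning(r <- corrWithRest(S, "b", c("a", "c")), "insensitive")
  expect_equal(r, 0)
  expect_error(pairwiseCosine(S, "a", "b"), "zero-norm")
})

test_that("groups must be disjoint, non-empty and within the matrix", {
  S <- cbind(a = c(1, 0), b = c(0, 1))
  expect_error(canonicalCorrelations(S, "a", "a"), "disjoint")
  expect_error(canonicalCorrelations(S, character(0), "b"), "non-empty")
  expect_error(canonicalCorrelations(S, "a", "zz"), "unknown parameter")
})
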