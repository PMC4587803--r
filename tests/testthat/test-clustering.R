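test_that("steady-state clustering pairs the compensative rate pairs at zero height", {
  fx <- geneExpressionFixture()
  S <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  tree <- clusterParameters(S, delta = 0.95, zeta = 1)
  m <- tree$merges
  # first two merges are the fully compensative pairs {kp,gp} and {kr,gr}
  first_two <- list(sort(strsplit(paste(m$left[1], m$right[1], sep = ","), ",")[[1]]),
                    sort(strsplit(paste(m$left[2], m$right[2], sep = ","), ",")[[1]]))
  expect_setequal(vapply(first_two, paste, "", collapse = "+"),
                  c("gp+kp", "gr+kr"))
  expect_lt(max(m$height[1:2]), 1e-12)
  expect_true(all(m$mi_capped[1:2]))
  # the two pairs merge at positive height (not entirely correlated)
  expect_gt(m$height[3], 0.01)
  expect_false(m$mi_capped[3])
  # each pair merge prunes its most-correlated member
  expect_setequal(tree$removed_info$parameter[tree$removed_info$step <= 2],
                  c("gp", "gr"))
})

test_that("orthogonal unit-norm columns cluster without removals at height 1", {
  S <- diag(4)
  colnames(S) <- paste0("p", 1:4)
  tree <- clusterParameters(S, delta = 0.95, zeta = 0.5)
  expect_equal(tree$merges$height, rep(1, 3))
  expect_equal(nrow(tree$removed_info), 0)
  expect_setequal(tree$identifiable, paste0("p", 1:4))
})

test_that("a jointly dependent third direction is pruned exactly once", {
  S <- cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2))
  tree <- clusterParameters(S, delta = 0.95, zeta = 0.5)
  # the pair {a,c} (or {b,c}) merges first at cos^2 = 1/2; after the second
  # merge the 3-cluster has a member fully spanned by the others
  expect_equal(nrow(tree$removed_info), 1)
  expect_equal(tree$removed_info$parameter, "c")
  expect_gte(tree$removed_info$rho, 0.95)
  expect_setequal(tree$identifiable, c("a", "b"))
})

test_that("Newick export writes heights as branch lengths", {
  S <- cbind(a = c(1, 0), b = c(sqrt(3) / 2, 1 / 2))
  tree <- clusterParameters(S, delta = 0.95, zeta = 0.5)
  expect_equal(exportTree(tree, "newick"), "(a:0.25,b:0.25);")
})

test_that("exported trees round-trip through independent parsers", {
  fx <- geneExpressionFixture()
  S <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
  tree <- clusterParameters(S)
  nwk <- exportTree(tree, "newick", annotate = FALSE)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("kr", "kp", "gr", "gp"))
  D <- ape::cophenetic.phylo(ph)
  # compensative pairs sit at (numerically) zero cophenetic distance,
  # the across-pair distance equals twice the recorded third merge height
  expect_lt(D["kr", "gr"], 1e-10)
  expect_lt(D["kp", "gp"], 1e-10)
  expect_equal(D["kr", "kp"], 2 * tree$merges$height[3], tolerance = 1e-9)

  # annotated export marks the delta-pruned leaves
  ann <- exportTree(tree, "newick")
  for (p in tree$removed_info$parameter)
    expect_match(ann, paste0(p, "\\[&removed\\]"))

  # JSON merge table reproduces the merge structure
  js <- jsonlite::fromJSON(exportTree(tree, "json"), simplifyVector = FALSE)
  expect_equal(length(js$merges), nrow(tree$merges))
  expect_equal(js$merges[[3]]$height, tree$merges$height[3])
  expect_setequal(unlist(js$identifiable), tree$identifiable)
  expect_error(exportTree(tree, "nexus"))
})

test_that("clustering is deterministic and permutation-invariant up to labels", {
  fx <- randomChainFixture(seed = 5, n_states = 4)
  S <- buildSensitivityMatrix(fx$model, fx$experiments)
  t1 <- clusterParameters(S, 0.95, 0.5)
  t2 <- clusterParameters(S, 0.95, 0.5)
  expect_identical(t1$merges, t2$merges)

  set.seed(99)
  for (rep in 1:3) {
    perm <- sample(ncol(S$values))
    Sp <- S$values[, perm]
    tp <- clusterParameters(Sp, 0.95, 0.5)
    expect_setequal(tp$identifiable, t1$identifiable)
    expect_equal(sort(tp$merges$height), sort(t1$merges$height),
                 tolerance = 1e-9)
  }
})

test_that("every parameter ends in exactly one of the two verdict sets", {
  for (seed in c(2, 9)) {
    fx <- randomChainFixture(seed = seed, n_states = 5, planted_pairs = 1)
    S <- buildSensitivityMatrix(fx$model, fx$experiments)
    tree <- clusterParameters(S, 0.95, 0.5)
    expect_setequal(c(tree$identifiable, tree$non_identifiable$parameter),
                    tree$leaves)
    expect_equal(length(tree$identifiable) + nrow(tree$non_identifiable),
                 length(tree$leaves))
    # every pruned parameter exceeded delta at the moment of pruning
    if (nrow(tree$removed_info))
      expect_true(all(tree$removed_info$rho >= 0.95))
    # a zero-height merge requires a fully compensative pair (capped MI)
    expect_true(all(tree$merges$mi_capped[tree$merges$height < 1e-10]))
  }
})

test_that("planted ratio pairs merge at zero height and lose one member", {
  for (seed in 101:106) {
    fx <- randomChainFixture(seed = seed, n_states = 4, planted_pairs = 1)
    S <- buildSensitivityMatrix(fx$model, fx$experiments)
    tree <- clusterParameters(S, 0.95, 0.5)
    pair <- fx$planted[[1]]
    first <- sort(strsplit(paste(tree$merges$left[1], tree$merges$right[1],
                                 sep = ","), ",")[[1]])
    expect_equal(first, sort(pair))
    expect_lt(tree$merges$height[1], 1e-8)
    expect_equal(sum(tree$removed_info$parameter %in% pair), 1)
  }
  expect_error(randomChainFixture(seed = 1, n_states = 3, planted_pairs = 5),
               "cannot plant")
})

test_that("screening ranks experiments by identifiability gain", {
  fx <- geneExpressionFixture()
  res <- screenExperiments(fx$model, fx$experiments["steady_state"],
                           list(fx$experiments$decay,
                                fx$experiments$steady_state))
  expect_equal(attr(res, "base_identifiable"), 0)
  # a duplicate of the base experiment changes nothing
  dup <- res[res$name == "steady_state", ]
  expect_equal(dup$n_identifiable, 0)
  # the decay experiment lifts the count from 0 to 4 and ranks first
  top <- res[res$rank == 1, ]
  expect_equal(top$name, "decay")
  expect_equal(top$n_identifiable, 4)
  expect_equal(top$gain, 4)
})

test_that("kinase perturbation experiments jointly unlock ka, KN and ki", {
  ik <- ikkkFixture()
  v_wt <- deltaZetaTest(buildSensitivityMatrix(ik$model,
                                               ik$experiments["wild_type"]))
  core <- c("ka", "KN", "ki")
  expect_false(any(v_wt$delta_pass[v_wt$parameter %in% core]))

  res <- screenExperiments(ik$model,
                           ik$experiments[c("wild_type", "a20_knockout")],
                           ik$experiments["knockout_blocked_phosphatase"])
  expect_equal(res$n_identifiable[1], 3)
  v_all <- deltaZetaTest(buildSensitivityMatrix(ik$model, ik$experiments))
  expect_true(all(v_all$identifiable[v_all$parameter %in% core]))
})

test_that("failing candidates are skipped, not fatal", {
  fx <- geneExpressionFixture()
  bad <- experiment("r", times = c(1, 2), overrides = c(nonexistent = 1),
                    name = "bad")
  expect_message(
    res <- screenExperiments(fx$model, fx$experiments["steady_state"],
                             list(bad, fx$experiments$decay)),
    "skipped")
  expect_true(is.na(res$n_identifiable[res$name == "bad"]))
  expect_equal(res$n_identifiable[res$name == "decay"], 4)
})

test_that("random profiles are reproducible and respect their range", {
  p1 <- randomProfiles(3, seq(0, 10, by = 2), range = c(0.5, 2), seed = 4)
  p2 <- randomProfiles(3, seq(0, 10, by = 2), range = c(0.5, 2), seed = 4)
  tt <- seq(0, 10, by = 0.5)
  for (i in 1:3) {
    expect_identical(p1[[i]](tt), p2[[i]](tt))
    expect_true(all(p1[[i]](tt) >= 0.5 & p1[[i]](tt) <= 2))
  }
  expect_false(identical(p1[[1]](tt), p1[[2]](tt)))
})
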