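## Run-level entry points behind the command-line script (inst/scripts/micca)
## and for scripted analyses. Every report embeds the thresholds and
## tolerances actually used; timestamps live in a separate field so two runs
## with identical settings produce byte-identical payloads.

#' Resolve a run configuration to a model and experiment list
#'
#' @param fixture name of a built-in fixture (`"gene_expression"`,
#'   `"ikkk"`, `"random_chain"`); mutually exclusive with `config`.
#' @param config path to a `micca/1` configuration file.
#' @param experiments optional character vector selecting experiments by
#'   name (default: all).
#' @param seed seed forwarded to seeded fixtures.
#' @return list with `model` and `experiments`.
#' @export
resolveRun <- function(fixture = NULL, config = NULL, experiments = NULL,
                       seed = 1L) {
  if (is.null(fixture) == is.null(config))
    stop("give exactly one of `fixture` or `config`")
  src <- if (!is.null(fixture)) {
    fx <- fixtureByName(fixture, seed = seed)
    list(model = fx$model, experiments = fx$experiments)
  } else {
    readModelConfig(config)
  }
  if (!is.null(experiments)) {
    missing <- setdiff(experiments, names(src$experiments))
    if (length(missing))
      stop("unknown experiment(s): ", paste(missing, collapse = ", "))
    src$experiments <- src$experiments[experiments]
  }
  src
}

runSettings <- function(delta, zeta, log_scale) {
  list(
    delta = delta, zeta = zeta, log_scale = log_scale,
    variance_inflation = varianceInflation(delta),
    single_param_variance_bound = singleParamVarianceBound(zeta),
    solver = list(method = "lsoda", rtol = 1e-8, atol = 1e-10),
    rank_tolerance = RANK_TOL, rho_clip = RHO_CLIP,
    package_version = as.character(utils::packageVersion("micca"))
  )
}

#' Cluster parameters of a configured model and write the artifacts
#'
#' Builds the stacked sensitivity matrix over the selected experiments,
#' runs the global (delta, zeta)-test and the modified hierarchical
#' clustering, and optionally writes: the Newick dendrogram, a JSON report
#' (settings, verdicts, merge table, identifiable sets) and a CSV of the
#' sensitivity matrix with the FIM diagonal.
#'
#' @inheritParams resolveRun
#' @param delta,zeta identifiability thresholds.
#' @param log_scale analyse in log-parametrisation.
#' @param out_tree,out_report,out_csv optional output paths.
#' @return list with `S`, `verdicts`, `tree`, `report` (the report payload
#'   as a list), invisibly.
#' @export
runCluster <- function(fixture = NULL, config = NULL, experiments = NULL,
                       delta = 0.95, zeta = 1, log_scale = TRUE, seed = 1L,
                       out_tree = NULL, out_report = NULL, out_csv = NULL) {
  checkDelta(delta); checkZeta(zeta)
  run <- resolveRun(fixture, config, experiments, seed)
  S <- buildSensitivityMatrix(run$model, run$experiments, log_scale = log_scale)
  verdicts <- deltaZetaTest(S, delta, zeta)
  tree <- clusterParameters(S, delta, zeta)
  report <- list(
    schema = "micca-report/1",
    model = run$model$name,
    experiments = names(run$experiments),
    settings = runSettings(delta, zeta, log_scale),
    verdicts = verdicts,
    merges = tree$merges,
    identifiable = tree$identifiable,
    non_identifiable = tree$non_identifiable,
    nonmonotone_steps = tree$nonmonotone_steps
  )
  if (!is.null(out_tree)) exportTree(tree, "newick", file = out_tree)
  if (!is.null(out_report)) writeReport(report, out_report)
  if (!is.null(out_csv)) writeSensitivityCSV(S, out_csv)
  invisible(list(S = S, verdicts = verdicts, tree = tree, report = report))
}

writeReport <- function(report, path) {
  payload <- c(report, list(generated = list(timestamp = format(Sys.time(), tz = "UTC"))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE), path)
  invisible(path)
}

#' Identifiability verdicts for a configured model
#'
#' @inheritParams runCluster
#' @param sweep optional list with elements `deltas` and `zetas`; when
#'   given, a threshold-robustness sweep is included.
#' @param out_report optional JSON output path.
#' @return list with `S`, `verdicts` and optionally `sweep`, invisibly.
#' @export
runIdentifiability <- function(fixture = NULL, config = NULL,
                               experiments = NULL, delta = 0.95, zeta = 1,
                               log_scale = TRUE, seed = 1L, sweep = NULL,
                               out_report = NULL) {
  checkDelta(delta); checkZeta(zeta)
  run <- resolveRun(fixture, config, experiments, seed)
  S <- buildSensitivityMatrix(run$model, run$experiments, log_scale = log_scale)
  verdicts <- deltaZetaTest(S, delta, zeta)
  sw <- if (!is.null(sweep)) deltaZetaSweep(S, sweep$deltas, sweep$zetas)
  report <- list(
    schema = "micca-report/1",
    model = run$model$name,
    experiments = names(run$experiments),
    settings = runSettings(delta, zeta, log_scale),
    verdicts = verdicts,
    sweep = sw
  )
  if (!is.null(out_report)) writeReport(report, out_report)
  invisible(list(S = S, verdicts = verdicts, sweep = sw, report = report))
}

#' Similarity between two parameter groups of a configured model
#'
#' @inheritParams runCluster
#' @param group_a,group_b parameter names (character vectors, or single
#'   comma-separated strings as passed on a command line).
#' @return list with the `CcaResult` and a JSON-ready summary, invisibly;
#'   the summary is printed as JSON when `quiet = FALSE`.
#' @param quiet suppress printing.
#' @export
runSimilarity <- function(group_a, group_b, fixture = NULL, config = NULL,
                          experiments = NULL, log_scale = TRUE, seed = 1L,
                          quiet = FALSE) {
  splitGroup <- function(g)
    if (length(g) == 1L && grepl(",", g)) trimws(strsplit(g, ",")[[1]]) else g
  run <- resolveRun(fixture, config, experiments, seed)
  S <- buildSensitivityMatrix(run$model, run$experiments, log_scale = log_scale)
  cc <- canonicalCorrelations(S, splitGroup(group_a), splitGroup(group_b))
  summary <- list(
    A = cc$groups$A, B = cc$groups$B,
    rhos = cc$rhos,
    mutual_information = as.numeric(cc$mi),
    mi_capped = isTRUE(cc$mi_capped),
    linkage_height = cc$height
  )
  if (!quiet)
    cat(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
  invisible(list(cca = cc, summary = summary))
}

#' Screen candidate stimulation profiles for a configured model
#'
#' Generates seeded random piecewise-constant input profiles for one input
#' channel, attaches each to a template experiment and ranks the resulting
#' candidate experiments by identifiable-parameter count on top of the
#' base design (see [screenExperiments()]).
#'
#' @inheritParams runCluster
#' @param base_experiments names of the experiments forming the base design.
#' @param template name of the experiment whose observation scheme the
#'   candidates copy.
#' @param input name of the input channel the random profiles drive.
#' @param n_candidates number of random profiles.
#' @param knots knot grid for the piecewise-constant profiles.
#' @param range amplitude range.
#' @param out_report optional JSON output path.
#' @return the `ScreenResult`, invisibly.
#' @export
runScreen <- function(fixture = NULL, config = NULL, base_experiments = NULL,
                      template, input, n_candidates = 20L,
                      knots = seq(0, 10, by = 2), range = c(0, 1),
                      delta = 0.95, zeta = 1, log_scale = TRUE, seed = 1L,
                      out_report = NULL) {
  run <- resolveRun(fixture, config, NULL, seed)
  if (!template %in% names(run$experiments))
    stop("unknown template experiment: ", template)
  base <- if (is.null(base_experiments)) list()
          else unname(run$experiments[base_experiments])
  profiles <- randomProfiles(n_candidates, knots, range, seed)
  candidates <- lapply(seq_along(profiles), function(i) {
    e <- run$experiments[[template]]
    e$name <- sprintf("%s_candidate_%d", template, i)
    e$inputs <- c(e$inputs[setdiff(names(e$inputs), input)],
                  setNames(profiles[i], input))
    e
  })
  res <- screenExperiments(run$model, base, candidates, delta, zeta, log_scale)
  if (!is.null(out_report))
    writeReport(list(schema = "micca-report/1", model = run$model$name,
                     settings = runSettings(delta, zeta, log_scale),
                     seed = seed, screen = as.data.frame(res),
                     base_identifiable = attr(res, "base_identifiable")),
                out_report)
  invisible(res)
}

#' Simulate configured experiments and export tidy trajectories
#'
#' @inheritParams runCluster
#' @param out_csv optional CSV path (columns time, state, value,
#'   experiment_id).
#' @return the combined tidy data frame, invisibly.
#' @export
runSimulate <- function(fixture = NULL, config = NULL, experiments = NULL,
                        seed = 1L, out_csv = NULL) {
  run <- resolveRun(fixture, config, experiments, seed)
  frames <- lapply(names(run$experiments), function(nm) {
    as.data.frame(simulateExperiment(run$model, run$experiments[[nm]]))
  })
  out <- do.call(rbind, frames)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}
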