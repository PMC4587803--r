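#' Modified hierarchical clustering of model parameters
#'
#' Agglomerative clustering driven by the MI-CCA similarity. Starting from
#' singleton clusters, the pair of clusters with the highest mutual
#' information is merged; inside every newly merged cluster the
#' delta-condition is verified for each member against the remaining
#' members, and the most-correlated member is removed (declared
#' non-identifiable) until all members satisfy \eqn{\rho < \delta}. Removed
#' parameters take no further part in similarity computations but remain as
#' annotated leaves of the dendrogram. Linkage heights are the normalised
#' dissimilarity \eqn{(1/m)\sum_i(1-\rho_i^2)} of the pre-merge CCA; height
#' monotonicity is not enforced (non-monotone steps are recorded).
#'
#' Merge ties (possible when several pairs have capped MI) are broken by
#' linkage height (ascending), then by the lexicographic pair of smallest
#' member indices. Pruning removes one parameter at a time — the member
#' with the largest within-cluster rho, ties to the larger column index —
#' and recomputes before removing another.
#'
#' Parameters failing the zeta-condition \eqn{\|S_i\| > \zeta} participate
#' in clustering (they still shape the similarity picture) but are excluded
#' from the final identifiable set.
#'
#' @param S a [buildSensitivityMatrix()] result (or plain matrix with
#'   named columns).
#' @param delta compensation threshold in (0, 1).
#' @param zeta sensitivity-norm threshold > 0.
#' @return an object of class `ClusterTree`: `merges` (per step: member
#'   names of both clusters, height, MI, capped flag, parameters removed at
#'   that step with their rho at pruning), `leaves`, `identifiable`,
#'   `non_identifiable` (data frame: parameter, reason, step),
#'   `nonmonotone_steps`, plus the thresholds used.
#' @examples
#' S <- cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2))
#' tr <- clusterParameters(S, delta = 0.95, zeta = 0.5)
#' tr$merges$height
#' @export
clusterParameters <- function(S, delta = 0.95, zeta = 1) {
  checkDelta(delta); checkZeta(zeta)
  V <- sensValues(S)
  l <- ncol(V)
  if (l < 2L) stop("clustering needs at least two parameters")
  pn <- colnames(V)
  if (is.null(pn)) pn <- paste0("p", seq_len(l))
  norms <- sqrt(colSums(V^2))
  zeta_fail <- pn[norms <= zeta]

  active <- lapply(seq_len(l), identity)      # live members per cluster
  nodes <- lapply(seq_len(l), function(i)
    list(type = "leaf", index = i, height = 0))
  removed <- character(0)
  removed_info <- data.frame(parameter = character(0), rho = numeric(0),
                             step = integer(0), stringsAsFactors = FALSE)
  merges <- list()
  nonmono <- integer(0)
  step <- 0L
  prev_height <- -Inf

  while (length(active) > 1L) {
    step <- step + 1L
    ## score every cluster pair on current live members
    best <- NULL
    nc <- length(active)
    for (i in seq_len(nc - 1L)) for (j in seq((i + 1L), nc)) {
      cc <- suppressWarnings(canonicalCorrelations(V, active[[i]], active[[j]]))
      if (any(is.nan(cc$rhos)))
        stop(sprintf("NaN similarity between clusters {%s} and {%s}",
                     paste(pn[active[[i]]], collapse = ","),
                     paste(pn[active[[j]]], collapse = ",")))
      key <- list(
        mi = if (isTRUE(cc$mi_capped)) Inf else as.numeric(cc$mi),
        height = cc$height,
        lex = sort(c(min(active[[i]]), min(active[[j]])))
      )
      if (is.null(best) || pairBeats(key, best$key)) {
        best <- list(i = i, j = j, cc = cc, key = key)
      }
    }

    merged <- sort(c(active[[best$i]], active[[best$j]]))
    ## delta-pruning inside the newly merged cluster, one member at a time
    step_removed <- character(0)
    repeat {
      if (length(merged) <= 1L) break
      rho <- vapply(seq_along(merged), function(p) {
        suppressWarnings(corrWithRest(V, merged[p], merged[-p]))
      }, 0)
      if (max(rho) < delta) break
      worst <- which(rho == max(rho))
      victim <- max(merged[worst])            # tie -> larger index
      merged <- setdiff(merged, victim)
      removed <- c(removed, pn[victim])
      step_removed <- c(step_removed, pn[victim])
      removed_info <- rbind(removed_info, data.frame(
        parameter = pn[victim], rho = max(rho), step = step,
        stringsAsFactors = FALSE))
    }
    if (!length(merged))
      stop("all parameters were removed during pruning; ",
           "no identifiable structure remains")

    h <- best$cc$height
    if (h < prev_height) nonmono <- c(nonmono, step)
    prev_height <- h
    merges[[step]] <- data.frame(
      step = step,
      left = paste(pn[sort(allMembers(nodes[[best$i]]))], collapse = ","),
      right = paste(pn[sort(allMembers(nodes[[best$j]]))], collapse = ","),
      height = h,
      mi = as.numeric(best$cc$mi),
      mi_capped = isTRUE(best$cc$mi_capped),
      removed = paste(step_removed, collapse = ","),
      stringsAsFactors = FALSE
    )
    new_node <- list(type = "node", left = nodes[[best$i]],
                     right = nodes[[best$j]], height = h, step = step)
    keep <- setdiff(seq_len(nc), c(best$i, best$j))
    active <- c(active[keep], list(merged))
    nodes <- c(nodes[keep], list(new_node))
  }

  survivors <- pn[active[[1L]]]
  identifiable <- setdiff(survivors, zeta_fail)
  zeta_only <- setdiff(intersect(survivors, zeta_fail), removed_info$parameter)
  non_id <- rbind(
    if (nrow(removed_info)) data.frame(
      parameter = removed_info$parameter,
      reason = sprintf("delta-pruned at step %d", removed_info$step),
      step = removed_info$step, stringsAsFactors = FALSE),
    if (length(zeta_only)) data.frame(
      parameter = zeta_only, reason = "zeta-fail", step = NA_integer_,
      stringsAsFactors = FALSE)
  )
  if (is.null(non_id))
    non_id <- data.frame(parameter = character(0), reason = character(0),
                         step = integer(0), stringsAsFactors = FALSE)
  structure(list(
    merges = do.call(rbind, merges),
    root = nodes[[1L]],
    leaves = pn,
    identifiable = identifiable,
    non_identifiable = non_id,
    zeta_fail = zeta_fail,
    removed_info = removed_info,
    nonmonotone_steps = nonmono,
    delta = delta, zeta = zeta
  ), class = "ClusterTree")
}

## TRUE when candidate key a beats incumbent b: higher MI, then lower
## height, then lexicographically smaller (sorted) pair of smallest indices
pairBeats <- function(a, b) {
  if (a$mi != b$mi) return(a$mi > b$mi)
  if (a$height != b$height) return(a$height < b$height)
  if (a$lex[1] != b$lex[1]) return(a$lex[1] < b$lex[1])
  a$lex[2] < b$lex[2]
}

allMembers <- function(node) {
  if (node$type == "leaf") return(node$index)
  c(allMembers(node$left), allMembers(node$right))
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree over %d parameter(s) (delta=%g, zeta=%g)\n",
              length(x$leaves), x$delta, x$zeta))
  print.data.frame(x$merges[, c("step", "left", "right", "height", "removed")],
                   digits = 4, row.names = FALSE)
  cat("identifiable:    ",
      if (length(x$identifiable)) paste(x$identifiable, collapse = ", ") else "(none)", "\n")
  cat("non-identifiable:",
      if (nrow(x$non_identifiable))
        paste(sprintf("%s (%s)", x$non_identifiable$parameter,
                      x$non_identifiable$reason), collapse = ", ")
      else "(none)", "\n")
  if (length(x$nonmonotone_steps))
    cat("non-monotone heights at step(s):",
        paste(x$nonmonotone_steps, collapse = ", "), "\n")
  invisible(x)
}

#' Export a cluster tree
#'
#' `"newick"` writes the dendrogram as a Newick string with branch lengths
#' from the recorded linkage heights (a two-leaf tree of height h is
#' `(A:h,B:h);`). Parameters pruned by the delta-condition are annotated
#' with a bracket comment `[&removed]` unless `annotate = FALSE` (plain
#' Newick, parseable by standard tree readers). `"json"` writes the merge
#' table (step, members, height, removed) for dendrogram plotting.
#'
#' @param tree a [clusterParameters()] result.
#' @param format `"newick"` or `"json"`.
#' @param file optional path; when given, the serialisation is written
#'   there and returned invisibly.
#' @param annotate mark delta-pruned leaves in the Newick output.
#' @return character scalar (the serialised tree).
#' @export
exportTree <- function(tree, format = c("newick", "json"), file = NULL,
                       annotate = TRUE) {
  stopifnot(inherits(tree, "ClusterTree"))
  format <- match.arg(format)
  out <- if (format == "newick") {
    paste0(newickString(tree$root, tree, annotate), ";")
  } else {
    m <- tree$merges
    jsonlite::toJSON(list(
      schema = "micca-tree/1",
      merges = lapply(seq_len(nrow(m)), function(r) list(
        step = m$step[r],
        left = strsplit(m$left[r], ",")[[1]],
        right = strsplit(m$right[r], ",")[[1]],
        height = m$height[r],
        removed = if (nzchar(m$removed[r])) strsplit(m$removed[r], ",")[[1]]
                  else character(0)
      )),
      identifiable = tree$identifiable,
      non_identifiable = tree$non_identifiable
    ), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

newickString <- function(node, tree, annotate) {
  if (node$type == "leaf") {
    nm <- tree$leaves[node$index]
    if (annotate && nm %in% tree$removed_info$parameter)
      nm <- paste0(nm, "[&removed]")
    return(nm)
  }
  bl <- function(child) node$height - child$height
  sprintf("(%s:%.10g,%s:%.10g)",
          newickString(node$left, tree, annotate), bl(node$left),
          newickString(node$right, tree, annotate), bl(node$right))
}

#' Screen candidate experiments for identifiability gain
#'
#' For each candidate experiment, stacks its sensitivity block on top of
#' the base experiments, reruns the global (delta, zeta)-test over all
#' parameters and reports how many parameters become identifiable. The
#' ranking is by identifiable count (descending) with candidate index as
#' the deterministic tie-break. Candidates whose simulation fails are
#' skipped with a message rather than aborting the screen.
#'
#' @param model an [odeModel()].
#' @param base list of baseline [experiment()]s (may be empty `list()`).
#' @param candidates list of candidate experiments.
#' @param delta,zeta identifiability thresholds.
#' @param log_scale passed to [buildSensitivityMatrix()].
#' @return data frame of class `ScreenResult`: candidate index, name,
#'   n_identifiable, gain over the base design, rank; the base count is
#'   attached as attribute `"base_identifiable"`.
#' @export
screenExperiments <- function(model, base, candidates, delta = 0.95,
                              zeta = 1, log_scale = TRUE) {
  checkDelta(delta); checkZeta(zeta)
  stopifnot(is.list(base), is.list(candidates), length(candidates) >= 1L)
  n_base <- if (length(base)) {
    sum(deltaZetaTest(buildSensitivityMatrix(model, base, log_scale = log_scale),
                      delta, zeta)$identifiable)
  } else 0L
  counts <- rep(NA_integer_, length(candidates))
  for (ci in seq_along(candidates)) {
    counts[ci] <- tryCatch({
      Sc <- buildSensitivityMatrix(model, c(base, candidates[ci]),
                                   log_scale = log_scale)
      sum(deltaZetaTest(Sc, delta, zeta)$identifiable)
    }, error = function(e) {
      message(sprintf("candidate %d skipped: %s", ci, conditionMessage(e)))
      NA_integer_
    })
  }
  out <- data.frame(
    candidate = seq_along(candidates),
    name = vapply(candidates, function(x)
      if (nzchar(x$name)) x$name else "", ""),
    n_identifiable = counts,
    gain = counts - n_base,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(out$n_identifiable)
  out <- out[order(!ok, -ifelse(ok, out$n_identifiable, -Inf), out$candidate), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "base_identifiable") <- n_base
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat(sprintf("Experiment screen: base design has %d identifiable parameter(s)\n",
              attr(x, "base_identifiable")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Seeded random piecewise-constant stimulation profiles
#'
#' Generates candidate input profiles for [screenExperiments()]:
#' piecewise-constant signals on a fixed knot grid with amplitudes drawn
#' uniformly from a range, reproducible per seed.
#'
#' @param n number of profiles.
#' @param times knot grid (profile is constant between consecutive knots).
#' @param range amplitude range, `c(min, max)`.
#' @param seed integer seed.
#' @return list of `n` input functions (each with breakpoints declared).
#' @export
randomProfiles <- function(n, times, range = c(0, 1), seed = 1L) {
  stopifnot(n >= 1L, length(times) >= 2L, length(range) == 2L)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    piecewiseConstant(times, stats::runif(length(times), range[1], range[2])))
}
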