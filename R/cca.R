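## Canonical correlations between parameter groups, computed as principal
## angles between the column spans of the two sensitivity sub-blocks.
## Orthonormal bases come from a rank-revealing SVD of each block and the
## CCs are the singular values of the cross-Gram matrix of the bases; this
## avoids generalized eigenproblems on near-singular FIM sub-blocks.

RANK_TOL <- 1e-10   # singular values below RANK_TOL * max are rank-noise
RHO_CLIP <- 1e-12   # rho clipped to 1 - RHO_CLIP before the MI logarithm

resolveGroup <- function(S, group, arg = "group") {
  pn <- if (inherits(S, "SensitivityMatrix")) S$param_names else colnames(sensValues(S))
  if (is.character(group)) {
    idx <- match(group, pn)
    if (anyNA(idx)) stop(arg, ": unknown parameter(s): ",
                         paste(group[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(group)
  if (!length(idx)) stop(arg, " must be non-empty")
  if (anyDuplicated(idx)) stop(arg, " contains duplicates")
  if (any(idx < 1L | idx > ncol(sensValues(S)))) stop(arg, ": index out of range")
  idx
}

## orthonormal basis of the column span; NULL when the block is (numerically) zero
orthoBasis <- function(M, tol = RANK_TOL) {
  sv <- svd(M)
  if (!length(sv$d) || max(sv$d) == 0) return(NULL)
  r <- sum(sv$d > tol * max(sv$d))
  if (r == 0L) return(NULL)
  sv$u[, seq_len(r), drop = FALSE]
}

#' Canonical correlations between two parameter groups
#'
#' The first canonical correlation \eqn{\rho_1} is the maximal cosine
#' between a linear combination of group A's sensitivity vectors and one of
#' group B's; subsequent CCs maximise the cosine in the orthogonal
#' complements of the earlier directions. Computed as cosines of principal
#' angles: singular values of \eqn{Q_A^T Q_B} for orthonormal bases of the
#' two column spans. Exactly \eqn{m = \min(|A|, |B|)} values are returned,
#' padded with 0 when the effective ranks are lower, each clipped into
#' \[0, 1\].
#'
#' @param S a [buildSensitivityMatrix()] result (or plain matrix with named
#'   columns).
#' @param A,B parameter groups (names or column indices), non-empty and
#'   disjoint.
#' @return object of class `CcaResult` with elements `rhos` (descending),
#'   `m`, `mi` (MI-CCA, nats), `mi_capped`, `height` (linkage height
#'   \eqn{(1/m)\sum_i (1-\rho_i^2)}), `rank_A`, `rank_B`, `groups`.
#' @examples
#' S <- cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1) / sqrt(2))
#' canonicalCorrelations(S, "a", "b")$rhos   # orthogonal: 0
#' @export
canonicalCorrelations <- function(S, A, B) {
  V <- sensValues(S)
  ia <- resolveGroup(S, A, "A"); ib <- resolveGroup(S, B, "B")
  if (length(intersect(ia, ib))) stop("groups A and B must be disjoint")
  m <- min(length(ia), length(ib))
  blockA <- V[, ia, drop = FALSE]; blockB <- V[, ib, drop = FALSE]
  zeroA <- colSums(blockA^2) == 0; zeroB <- colSums(blockB^2) == 0
  if (all(zeroA) && all(zeroB))
    stop("both parameter groups have entirely zero sensitivity")
  if (any(zeroA) || any(zeroB))
    warning("zero sensitivity column(s) inside a group; ",
            "canonical correlations use the span of the remaining columns")
  Qa <- orthoBasis(blockA); Qb <- orthoBasis(blockB)
  rhos <- rep(0, m)
  if (!is.null(Qa) && !is.null(Qb)) {
    d <- svd(crossprod(Qa, Qb))$d
    d <- pmin(pmax(d, 0), 1)
    take <- seq_len(min(length(d), m))
    rhos[take] <- d[take]
  }
  rhos <- sort(rhos, decreasing = TRUE)
  res <- structure(list(
    rhos = rhos, m = m,
    rank_A = if (is.null(Qa)) 0L else ncol(Qa),
    rank_B = if (is.null(Qb)) 0L else ncol(Qb),
    groups = list(A = colnames(V)[ia], B = colnames(V)[ib])
  ), class = "CcaResult")
  res$mi <- mutualInformation(res)
  res$mi_capped <- attr(res$mi, "capped")
  res$height <- linkageHeight(res)
  res
}

#' @export
print.CcaResult <- function(x, ...) {
  cat(sprintf("CcaResult: {%s} vs {%s}\n",
              paste(x$groups$A, collapse = ","), paste(x$groups$B, collapse = ",")))
  cat("  rho:", paste(sprintf("%.6f", x$rhos), collapse = " "), "\n")
  cat(sprintf("  MI = %.4g nats%s, linkage height = %.4g\n",
              as.numeric(x$mi), if (isTRUE(x$mi_capped)) " (capped)" else "",
              x$height))
  invisible(x)
}

#' MI-CCA: mutual information between estimator blocks
#'
#' The asymptotic mutual information between the maximum-likelihood
#' estimates of two parameter groups,
#' \deqn{I(\theta_A, \theta_B) = -\frac{1}{m}\sum_{i=1}^m \log(1-\rho_i^2)}
#' in nats. The expression diverges as any \eqn{\rho_i \to 1}; each
#' \eqn{\rho_i} is first clipped to \eqn{1 - 10^{-12}} and the result
#' carries a `"capped"` attribute when clipping fired, so that fully
#' compensative groups can still be ranked (ties among capped pairs are
#' broken by linkage height downstream).
#'
#' @param x a `CcaResult`, or a numeric vector of canonical correlations.
#' @return non-negative scalar (nats) with logical attribute `"capped"`.
#' @examples
#' mutualInformation(0.95)   # -log(1 - 0.95^2)
#' @export
mutualInformation <- function(x) {
  rhos <- if (inherits(x, "CcaResult")) x$rhos else as.numeric(x)
  stopifnot(length(rhos) >= 1L, all(rhos >= 0), all(rhos <= 1))
  capped <- any(rhos > 1 - RHO_CLIP)
  r <- pmin(rhos, 1 - RHO_CLIP)
  mi <- -mean(log(1 - r^2))
  structure(mi, capped = capped)
}

#' Linkage height between two parameter groups
#'
#' The normalised dissimilarity \eqn{(1/m)\sum_i (1-\rho_i^2)} used as the
#' dendrogram height: 0 when every CC equals 1 (fully mutually
#' compensative), 1 when every CC equals 0 (orthogonal groups).
#'
#' @inheritParams mutualInformation
#' @return scalar in \[0, 1\].
#' @export
linkageHeight <- function(x) {
  rhos <- if (inherits(x, "CcaResult")) x$rhos else as.numeric(x)
  stopifnot(length(rhos) >= 1L, all(rhos >= 0), all(rhos <= 1))
  mean(1 - rhos^2)
}

#' Pairwise cosine between two sensitivity vectors
#'
#' \eqn{\cos(S_i, S_j) = S_i^T S_j / (\|S_i\|\,\|S_j\|)}, the signed
#' pairwise similarity readable off the normalised FIM. Group-level
#' similarity uses canonical correlations (which are non-negative by
#' construction); sign-opposite vectors are maximally compensative.
#'
#' @param S sensitivity matrix.
#' @param i,j parameter names or column indices.
#' @return scalar in \[-1, 1\].
#' @export
pairwiseCosine <- function(S, i, j) {
  V <- sensValues(S)
  ii <- resolveGroup(S, i, "i"); jj <- resolveGroup(S, j, "j")
  stopifnot(length(ii) == 1L, length(jj) == 1L)
  ni <- sqrt(sum(V[, ii]^2)); nj <- sqrt(sum(V[, jj]^2))
  if (ni == 0) stop("zero-norm sensitivity column: ", colnames(V)[ii])
  if (nj == 0) stop("zero-norm sensitivity column: ", colnames(V)[jj])
  max(-1, min(1, sum(V[, ii] * V[, jj]) / (ni * nj)))
}

#' Canonical correlation of one parameter with a group
#'
#' \eqn{\rho(\theta_i, \theta_{rest})}: the first canonical correlation
#' between the single sensitivity vector \eqn{S_i} and the span of the
#' rest-group — the |cos| of the angle between \eqn{S_i} and its projection
#' onto that subspace. This is the quantity thresholded by the
#' delta-condition of the (delta, zeta)-identifiability test.
#'
#' @param S sensitivity matrix.
#' @param i a single parameter (name or index).
#' @param rest parameter group not containing `i`; empty is allowed and
#'   gives 0.
#' @return scalar in \[0, 1\].
#' @export
corrWithRest <- function(S, i, rest) {
  V <- sensValues(S)
  ii <- resolveGroup(S, i, "i")
  stopifnot(length(ii) == 1L)
  if (!length(rest)) return(0)
  ir <- resolveGroup(S, rest, "rest")
  if (ii %in% ir) stop("`rest` must not contain parameter ", colnames(V)[ii])
  if (sum(V[, ii]^2) == 0) {
    warning("insensitive parameter ", colnames(V)[ii],
            " (zero sensitivity); rho set to 0, the zeta-condition applies")
    return(0)
  }
  suppressWarnings(canonicalCorrelations(S, ii, ir)$rhos[1])
}
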