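# Brute-force oracle for the first canonical correlation: maximise
# |cos(u, v)| over dense grids of unit vectors in each column span
# (subspace dimension <= 2). Two grid stages: a coarse sweep of the angle
# parameterising each span, then a fine sweep around the coarse argmax.
# Independent of the principal-angle SVD route under test.

unitGrid <- function(M, centre = NULL, halfwidth = NULL, n = 401L) {
  qrM <- qr(M)
  r <- qrM$rank
  Q <- qr.Q(qrM)[, seq_len(r), drop = FALSE]
  if (r == 1L) return(Q)
  stopifnot(r == 2L)
  phi <- if (is.null(centre)) seq(0, pi, length.out = n)
         else seq(centre - halfwidth, centre + halfwidth, length.out = n)
  Q %*% rbind(cos(phi), sin(phi))
}

gridAngles <- function(M, centre = NULL, halfwidth = NULL, n = 401L) {
  if (qr(M)$rank == 1L) return(0)
  if (is.null(centre)) seq(0, pi, length.out = n)
  else seq(centre - halfwidth, centre + halfwidth, length.out = n)
}

bruteForceRho1 <- function(Sa, Sb) {
  coarse <- function(A, B, ca = NULL, cb = NULL, hw = NULL) {
    U <- unitGrid(A, ca, hw); V <- unitGrid(B, cb, hw)
    M <- abs(crossprod(U, V))
    ij <- arrayInd(which.max(M), dim(M))
    list(val = max(M),
         pa = gridAngles(A, ca, hw)[ij[1]],
         pb = gridAngles(B, cb, hw)[ij[2]])
  }
  s1 <- coarse(Sa, Sb)
  hw <- pi / 400
  s2 <- coarse(Sa, Sb, s1$pa, s1$pb, hw)
  min(s2$val, 1)
}

# random CCA instance: row dimension 2..4, group sizes 1..2, generic entries
randomCcaInstance <- function(seed) {
  set.seed(seed)
  R <- sample(2:4, 1)
  a <- sample(1:2, 1); b <- sample(1:2, 1)
  M <- matrix(stats::rnorm(R * (a + b)), R, a + b)
  colnames(M) <- paste0("p", seq_len(a + b))
  list(S = M, A = seq_len(a), B = a + seq_len(b))
}
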