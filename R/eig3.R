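# Vectorized eigendecomposition of many symmetric 3x3 matrices.
#
# Input: n x 6 matrix of unique elements in the order
# (a11, a22, a33, a12, a13, a23). Uses the trigonometric closed form for
# the characteristic cubic of a symmetric matrix; eigenvectors are
# recovered from products of shifted matrices. Exact degeneracy (isotropy
# or a repeated pair) falls back to a canonical orthonormal basis, which is
# irrelevant for rotation-invariant scalars and documented for tractography
# determinism.

.eig3_values <- function(M) {
  a11 <- M[, 1]; a22 <- M[, 2]; a33 <- M[, 3]
  a12 <- M[, 4]; a13 <- M[, 5]; a23 <- M[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  scale <- pmax(abs(a11), abs(a22), abs(a33), abs(a12), abs(a13), abs(a23), 1e-300)
  iso <- p < 1e-12 * scale
  ps <- ifelse(iso, 1, p)       # avoid 0/0; isotropic rows overwritten below
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  unname(cbind(l1, l2, l3))
}

# rows of (A - mu I)(A - nu I): any nonzero column spans the eigenspace of
# the remaining eigenvalue (for distinct eigenvalues)
.eig3_vector_for <- function(M, mu, nu) {
  a11 <- M[, 1] - mu; a22 <- M[, 2] - mu; a33 <- M[, 3] - mu
  c11 <- M[, 1] - nu; c22 <- M[, 2] - nu; c33 <- M[, 3] - nu
  a12 <- M[, 4]; a13 <- M[, 5]; a23 <- M[, 6]
  # P = (A - mu I) %*% (A - nu I), computed columnwise
  p1 <- cbind(a11 * c11 + a12 * a12 + a13 * a13,
              a12 * c11 + a22 * a12 + a23 * a13,
              a13 * c11 + a23 * a12 + a33 * a13)
  p2 <- cbind(a11 * a12 + a12 * c22 + a13 * a23,
              a12 * a12 + a22 * c22 + a23 * a23,
              a13 * a12 + a23 * c22 + a33 * a23)
  p3 <- cbind(a11 * a13 + a12 * a23 + a13 * c33,
              a12 * a13 + a22 * a23 + a23 * c33,
              a13 * a13 + a23 * a23 + a33 * c33)
  n1 <- rowSums(p1^2); n2 <- rowSums(p2^2); n3 <- rowSums(p3^2)
  best <- max.col(cbind(n1, n2, n3), ties.method = "first")
  v <- p1
  v[best == 2, ] <- p2[best == 2, , drop = FALSE]
  v[best == 3, ] <- p3[best == 3, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  bad <- !is.finite(nrm) | nrm < 1e-14 * pmax(abs(mu), abs(nu), 1e-300)
  v <- v / ifelse(nrm > 0, nrm, 1)
  list(v = v, bad = bad)
}

.eig3_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Full decomposition; returns list(values = n x 3 descending,
# vectors = list(e1, e2, e3), each n x 3 unit rows)
.eig3_sym <- function(M) {
  vals <- .eig3_values(M)
  e1 <- .eig3_vector_for(M, vals[, 2], vals[, 3])
  e3 <- .eig3_vector_for(M, vals[, 1], vals[, 2])
  bad <- e1$bad | e3$bad
  v1 <- e1$v; v3 <- e3$v
  # canonical fallback for degenerate spectra
  if (any(bad)) {
    v1[bad, ] <- rep(c(1, 0, 0), each = sum(bad))
    v3[bad, ] <- rep(c(0, 0, 1), each = sum(bad))
  }
  # re-orthogonalize v3 against v1 (numerically near-orthogonal already)
  dot <- rowSums(v1 * v3)
  v3 <- v3 - dot * v1
  nrm3 <- sqrt(rowSums(v3^2))
  deg <- nrm3 < 1e-10
  if (any(deg)) {
    # pick any direction orthogonal to v1
    alt <- cbind(-v1[, 2], v1[, 1], rep(0, nrow(v1)))
    altn <- sqrt(rowSums(alt^2))
    alt2 <- cbind(rep(0, nrow(v1)), -v1[, 3], v1[, 2])
    use2 <- altn < 1e-8
    alt[use2, ] <- alt2[use2, , drop = FALSE]
    altn <- sqrt(rowSums(alt^2))
    v3[deg, ] <- (alt / altn)[deg, , drop = FALSE]
    nrm3[deg] <- 1
  }
  v3 <- v3 / nrm3
  v2 <- .eig3_cross(v3, v1)
  list(values = vals, vectors = list(e1 = v1, e2 = v2, e3 = v3))
}
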