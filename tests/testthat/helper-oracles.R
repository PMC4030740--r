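# Independent brute-force oracles.  These deliberately re-derive every
# quantity from first principles (scalar loops, exhaustive pair counting)
# and share no code with the package internals they check.

# All (distance, product) pairs by an explicit double loop over i < j.
oraclePairs <- function(mol) {
  xyz <- atomCoords(mol)
  q <- atomCharges(mol)
  n <- nrow(xyz)
  d <- numeric(0)
  v <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- c(d, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
        v <- c(v, q[i] * q[j])
      }
    }
  }
  keep <- d > 0
  list(distance = d[keep], value = v[keep])
}

# Linear binning one pair at a time, scalar arithmetic only.
oracleLinbin <- function(distance, value, dx) {
  if (!length(distance)) return(numeric(0))
  len <- max(floor(distance / dx)) + 2
  out <- numeric(len)
  for (k in seq_along(distance)) {
    t0 <- floor(distance[k] / dx)
    lo <- t0 * dx
    hi <- (t0 + 1) * dx
    out[t0 + 1] <- out[t0 + 1] + value[k] * (hi - distance[k]) / dx
    out[t0 + 2] <- out[t0 + 2] + value[k] * (distance[k] - lo) / dx
  }
  out
}

# Full descriptor re-derivation: enumerate, sign-split, bin per pair.
oracleEncode <- function(mol, dx) {
  p <- oraclePairs(mol)
  pos <- p$value >= 0
  list(plus = oracleLinbin(p$distance[pos], p$value[pos], dx),
       minus = oracleLinbin(p$distance[!pos], p$value[!pos], dx))
}

# Min-length truncated dot product by an explicit loop.
oracleTruncDot <- function(x, y) {
  p <- min(length(x), length(y))
  s <- 0
  for (k in seq_len(p)) s <- s + x[k] * y[k]
  s
}

# Mann-Whitney pair counting AUC: P(active > decoy) + P(tie)/2 over all
# active-decoy pairs.
oracleAuc <- function(scores, labels) {
  act <- scores[labels]
  dec <- scores[!labels]
  wins <- 0
  for (a in act) for (d in dec) {
    if (a > d) wins <- wins + 1
    else if (a == d) wins <- wins + 0.5
  }
  wins / (length(act) * length(dec))
}

randomTestMolecule <- function(nAtoms, name = "m") {
  newMolecule(name,
              matrix(runif(3 * nAtoms, 0, 8), ncol = 3),
              rnorm(nAtoms, 0, 0.3))
}

# tol = NULL -> exact (bitwise) equality; otherwise maximum absolute
# per-bin deviation.
expect_descriptor_equal <- function(a, b, tol = NULL) {
  if (is.null(tol)) {
    expect_identical(lbacPlus(a), lbacPlus(b))
    expect_identical(lbacMinus(a), lbacMinus(b))
  } else {
    expect_equal(length(lbacPlus(a)), length(lbacPlus(b)))
    expect_equal(length(lbacMinus(a)), length(lbacMinus(b)))
    expect_lte(max(abs(lbacPlus(a) - lbacPlus(b)), 0), tol)
    expect_lte(max(abs(lbacMinus(a) - lbacMinus(b)), 0), tol)
  }
}
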