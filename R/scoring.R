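# Similarity scores between two LBAC descriptor pairs.  The default score
# is the cross-correlation at lag zero; because the encoding is already
# rotation-translation invariant there is no lag to scan.  Continuous
# Tanimoto/Tversky ratios are derived from the three cross-correlation dot
# products.

.checkComparable <- function(a, b) {
  stopifnot(is(a, "ChargeDescriptor"), is(b, "ChargeDescriptor"))
  if (!isTRUE(all.equal(a@dx, b@dx, tolerance = 0)) && a@dx != b@dx)
    stop(sprintf(
      "descriptors are not comparable: dx differs (%g vs %g A)",
      a@dx, b@dx))
  invisible(NULL)
}

.truncDot <- function(x, y) {
  p <- min(length(x), length(y))
  if (p == 0L) return(0)
  sum(x[seq_len(p)] * y[seq_len(p)])
}

#' Cross-correlation score at lag zero
#'
#' The sum of the elementwise products of the two positive vectors over
#' their first \eqn{p = \min(l_1, l_2)} entries plus the same for the
#' negative vectors over \eqn{q = \min(l_3, l_4)} entries.  Vector lengths
#' are molecule-dependent, so each sum is truncated to the shorter
#' operand.  The score is unbounded and sign-carrying; the self-score
#' \code{ccScore(d, d)} is the squared Euclidean norm of the concatenated
#' vectors and hence never negative.
#'
#' @param a,b [ChargeDescriptor-class] objects encoded at the same
#'   \code{dx} (an error otherwise).
#' @return single numeric score.
#' @examples
#' m <- newMolecule("m", rbind(c(0, 0, 0), c(2, 0, 0)), c(0.3, -0.3))
#' d <- encodeMolecule(m)
#' ccScore(d, d) >= 0
#' @export
ccScore <- function(a, b) {
  .checkComparable(a, b)
  .truncDot(a@lbacPlus, b@lbacPlus) + .truncDot(a@lbacMinus, b@lbacMinus)
}

#' Continuous Tanimoto similarity
#'
#' \eqn{T(a,b) = AB / (AA + BB - AB)} with \eqn{AB = CC(a,b)},
#' \eqn{AA = CC(a,a)}, \eqn{BB = CC(b,b)}.  Returns 0 when both
#' self-scores are zero (two empty descriptors) or when \eqn{AB < 0}
#' (anti-correlated descriptors; the ratio is clamped so the score stays
#' in [0, 1] whenever the self-scores are positive).
#'
#' @inheritParams ccScore
#' @return single numeric in [0, 1] under the conventions above.
#' @export
tanimotoScore <- function(a, b) {
  ab <- ccScore(a, b)
  if (ab < 0) return(0)
  aa <- ccScore(a, a)
  bb <- ccScore(b, b)
  den <- aa + bb - ab
  if (den == 0) return(0)
  ab / den
}

#' Continuous Tversky similarity
#'
#' \eqn{T_{\alpha\beta}(a,b) = AB / (AB + \alpha (AA - AB) + \beta (BB -
#' AB))} from the three cross-correlation dot products.  The asymmetric
#' presets are \eqn{(\alpha, \beta) = (1, 0)} weighting the first
#' (reference/query) descriptor and \eqn{(0, 1)} weighting the second
#' (database) one; \eqn{(0.5, 0.5)} is symmetric.  Returns 0 when the
#' denominator is zero or \eqn{AB < 0}.
#'
#' @inheritParams ccScore
#' @param alpha,beta non-negative weights on the reference and database
#'   self-terms.
#' @return single numeric score.
#' @seealso [tanimotoScore()], which is \code{alpha = beta = 1}.
#' @export
tverskyScore <- function(a, b, alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  ab <- ccScore(a, b)
  if (ab < 0) return(0)
  aa <- ccScore(a, a)
  bb <- ccScore(b, b)
  den <- ab + alpha * (aa - ab) + beta * (bb - ab)
  if (den == 0) return(0)
  ab / den
}

#' Scoring-function menu
#'
#' Resolves a scorer tag to a two-argument score function over
#' descriptors.  Available tags: \code{"CC"} (cross-correlation at lag
#' zero, the default and recommended scorer), \code{"Tanimoto"},
#' \code{"Tversky_ref"} (Tversky with all weight on the query descriptor,
#' alpha = 1, beta = 0) and \code{"Tversky_db"} (alpha = 0, beta = 1).
#' Matching is case-insensitive and accepts \code{-} for \code{_}.
#'
#' @param tag scorer name.
#' @return function \code{(a, b) -> numeric}, with the query descriptor
#'   passed first.
#' @export
scoringFunction <- function(tag = c("CC", "Tanimoto", "Tversky_ref",
                                    "Tversky_db")) {
  key <- tolower(gsub("-", "_", tag[1L]))
  switch(key,
    cc = ccScore,
    tanimoto = tanimotoScore,
    tversky_ref = function(a, b) tverskyScore(a, b, 1, 0),
    tversky_db = function(a, b) tverskyScore(a, b, 0, 1),
    stop(sprintf(
      "unknown scorer \"%s\" (use CC, Tanimoto, Tversky_ref or Tversky_db)",
      tag[1L]))
  )
}
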