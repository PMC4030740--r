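#' @import methods
NULL

#' Molecule: a named set of point charges in 3D
#'
#' A \code{Molecule} holds one 3D structure (one conformer): atom positions
#' in Angstroem, one pre-assigned partial charge per atom (elementary-charge
#' units) and an informational element/atom label.  Atom order is
#' significant only for input/output round-trips; the descriptor is
#' invariant under atom permutation.  Conformers of the same compound are
#' represented as separate \code{Molecule} objects sharing a name.
#'
#' @slot name single non-empty character, the molecule (compound) name.
#' @slot coords numeric matrix with one row per atom and columns x, y, z
#'   (Angstroem); all entries finite.
#' @slot charges numeric vector of per-atom partial charges (e); finite,
#'   may be zero or negative.
#' @slot labels character vector of atom labels (informational only).
#'
#' @seealso [newMolecule()], [readMol2()], [encodeMolecule()]
#' @export
setClass("Molecule",
  representation(
    name = "character",
    coords = "matrix",
    charges = "numeric",
    labels = "character"
  )
)

setValidity("Molecule", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  n <- nrow(object@coords)
  if (is.null(n) || n < 1L)
    msg <- c(msg, "a molecule must contain at least one atom")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "'coords' must be a numeric matrix with 3 columns")
  else if (!all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(object@charges) != n)
    msg <- c(msg, "'charges' must have one value per atom")
  else if (!all(is.finite(object@charges)))
    msg <- c(msg, "all partial charges must be finite")
  if (length(object@labels) != n)
    msg <- c(msg, "'labels' must have one value per atom")
  if (length(msg)) msg else TRUE
})

#' Raw sign-split charge autocorrelation
#'
#' The multiset of (inter-atomic distance, charge product) pairs of a
#' molecule, partitioned by the sign of the product.  Each unordered atom
#' pair \eqn{\{i,j\}}, \eqn{i \ne j}, appears exactly once; pairs at
#' distance zero (the self term and coincident atoms) are excluded.
#' Products \eqn{q_i q_j \ge 0} go to the positive part, products
#' \eqn{< 0} to the negative part.
#'
#' @slot positivePairs two-column numeric matrix (distance, value) with
#'   value >= 0.
#' @slot negativePairs two-column numeric matrix (distance, value) with
#'   value < 0.
#'
#' @seealso [autocorrelate()], [linBin()]
#' @export
setClass("ChargeAutocorrelation",
  representation(
    positivePairs = "matrix",
    negativePairs = "matrix"
  )
)

setValidity("ChargeAutocorrelation", function(object) {
  msg <- character(0)
  for (nm in c("positivePairs", "negativePairs")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || ncol(m) != 2L)
      msg <- c(msg, sprintf("'%s' must be a two-column numeric matrix", nm))
    else {
      if (!all(is.finite(m)))
        msg <- c(msg, sprintf("'%s' must be finite", nm))
      if (nrow(m) > 0L && any(m[, 1L] <= 0))
        msg <- c(msg, sprintf("'%s' distances must be > 0", nm))
    }
  }
  if (is.numeric(object@positivePairs) && nrow(object@positivePairs) > 0L &&
      any(object@positivePairs[, 2L] < 0))
    msg <- c(msg, "positive part must hold values >= 0")
  if (is.numeric(object@negativePairs) && nrow(object@negativePairs) > 0L &&
      any(object@negativePairs[, 2L] >= 0))
    msg <- c(msg, "negative part must hold values < 0")
  if (length(msg)) msg else TRUE
})

#' Linearly binned charge-autocorrelation descriptor
#'
#' The rotation-translation invariant descriptor of a molecule: the
#' positive and negative parts of its charge autocorrelation, each
#' discretized by linear binning on a grid anchored at distance 0 with
#' spacing \code{dx}.  Grid point \code{t} (0-based) represents distance
#' \code{t * dx}; vector lengths are molecule-dependent (determined by the
#' largest inter-atomic distance), and scoring truncates to the shorter of
#' the two compared vectors.
#'
#' @slot dx discretization step in Angstroem (> 0).
#' @slot lbacPlus numeric vector of binned mass from the positive part;
#'   all entries >= 0.
#' @slot lbacMinus numeric vector of binned mass from the negative part;
#'   all entries <= 0.
#'
#' @seealso [encodeMolecule()], [ccScore()]
#' @export
setClass("ChargeDescriptor",
  representation(
    dx = "numeric",
    lbacPlus = "numeric",
    lbacMinus = "numeric"
  )
)

setValidity("ChargeDescriptor", function(object) {
  msg <- character(0)
  if (length(object@dx) != 1L || !is.finite(object@dx) || object@dx <= 0)
    msg <- c(msg, "'dx' must be a single positive number")
  if (length(object@lbacPlus) && (!all(is.finite(object@lbacPlus)) ||
      any(object@lbacPlus < 0)))
    msg <- c(msg, "'lbacPlus' entries must be finite and >= 0")
  if (length(object@lbacMinus) && (!all(is.finite(object@lbacMinus)) ||
      any(object@lbacMinus > 0)))
    msg <- c(msg, "'lbacMinus' entries must be finite and <= 0")
  if (length(msg)) msg else TRUE
})

#' ROC curve of a ranked active/decoy screen
#'
#' Receiver operating characteristic of a ranked list of labelled records,
#' built by descending score with tied scores collapsed into a single step
#' (a diagonal segment across the tie block), and its trapezoidal area.
#'
#' @slot fpr numeric vector of false-positive rates in [0,1], starting at 0
#'   and ending at 1, non-decreasing.
#' @slot tpr numeric vector of true-positive rates, same length and
#'   monotonicity.
#' @slot auc single numeric in [0,1]: the trapezoidal area under the curve,
#'   equal to the probability that a random active outscores a random decoy
#'   (ties counted one half).
#'
#' @seealso [rocCurve()], [aucSummary()]
#' @export
setClass("RocCurve",
  representation(
    fpr = "numeric",
    tpr = "numeric",
    auc = "numeric"
  )
)

setValidity("RocCurve", function(object) {
  msg <- character(0)
  n <- length(object@fpr)
  if (length(object@tpr) != n || n < 2L)
    msg <- c(msg, "'fpr' and 'tpr' must be equal-length vectors (>= 2 points)")
  else {
    if (any(diff(object@fpr) < 0) || any(diff(object@tpr) < 0))
      msg <- c(msg, "ROC coordinates must be non-decreasing")
    if (abs(object@fpr[1L]) > 1e-12 || abs(object@tpr[1L]) > 1e-12 ||
        abs(object@fpr[n] - 1) > 1e-12 || abs(object@tpr[n] - 1) > 1e-12)
      msg <- c(msg, "curve must start at (0,0) and end at (1,1)")
  }
  if (length(object@auc) != 1L || !is.finite(object@auc) ||
      object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msg <- c(msg, "'auc' must be a single value in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a Molecule
#'
#' @param name single non-empty molecule name; conformers of the same
#'   compound should share a name.
#' @param coords numeric matrix (n x 3) of atom positions in Angstroem, or
#'   anything coercible to one row-wise.
#' @param charges numeric vector of n partial charges (e).
#' @param labels optional character vector of n atom labels; defaults to
#'   \code{"Du"} (dummy) for every atom.
#' @return a validated [Molecule-class] object.
#' @examples
#' m <- newMolecule("hcl-like",
#'                  coords = rbind(c(0, 0, 0), c(1.27, 0, 0)),
#'                  charges = c(0.18, -0.18))
#' nAtoms(m)
#' @export
newMolecule <- function(name, coords, charges, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("'coords' must have three columns (x, y, z)")
  storage.mode(coords) <- "double"
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (is.null(labels))
    labels <- rep("Du", nrow(coords))
  new("Molecule", name = as.character(name), coords = coords,
      charges = as.numeric(charges), labels = as.character(labels))
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule \"%s\": %d atoms, total charge %.4f e\n",
              object@name, nrow(object@coords), sum(object@charges)))
  invisible(NULL)
})

setMethod("show", "ChargeAutocorrelation", function(object) {
  cat(sprintf(
    "ChargeAutocorrelation: %d positive / %d negative pairs\n",
    nrow(object@positivePairs), nrow(object@negativePairs)))
  invisible(NULL)
})

setMethod("show", "ChargeDescriptor", function(object) {
  cat(sprintf(
    "ChargeDescriptor (dx = %g A): |LBAC+| = %d, |LBAC-| = %d, mass %+.4g / %+.4g e^2\n",
    object@dx, length(object@lbacPlus), length(object@lbacMinus),
    sum(object@lbacPlus), sum(object@lbacMinus)))
  invisible(NULL)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              length(object@fpr), object@auc))
  invisible(NULL)
})
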