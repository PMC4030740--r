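# Synthetic molecule generators: random point-charge molecules, rigid
# transforms, mirror images, charge flips, jittered conformers, and
# active/decoy screening sets.  These emulate, at toy scale, a virtual
# screening benchmark: actives are perturbed copies of the query, decoys
# are size- and charge-matched but geometrically unrelated.

#' Generate a random point-charge molecule
#'
#' Atoms are placed uniformly in a cube of side \code{box} Angstroem and
#' partial charges drawn from a zero-mean Gaussian with standard
#' deviation \code{chargeScale}, the typical magnitude of force-field
#' partial charges.  Deterministic under \code{seed}; with
#' \code{seed = NULL} the current RNG stream is used (and advanced).
#'
#' @param nAtoms number of atoms (>= 1); default 20, a typical small-
#'   molecule atom count.
#' @param box cube side in Angstroem (> 0); default 10.
#' @param chargeScale standard deviation of the charges in e (>= 0);
#'   default 0.2.
#' @param name molecule name; default \code{"random"}.
#' @param seed optional integer seed.
#' @return a [Molecule-class].
#' @export
randomMolecule <- function(nAtoms = 20L, box = 10, chargeScale = 0.2,
                           name = "random", seed = NULL) {
  stopifnot(nAtoms >= 1L, box > 0, chargeScale >= 0)
  .withSeed(seed, {
    coords <- matrix(stats::runif(3L * nAtoms, min = 0, max = box),
                     ncol = 3L)
    charges <- stats::rnorm(nAtoms, mean = 0, sd = chargeScale)
    newMolecule(name, coords, charges)
  })
}

#' Draw a uniformly random proper rotation matrix
#'
#' Uses the unit-quaternion method (four independent standard normals,
#' normalized) so the rotation is uniform over SO(3) with no axis bias.
#'
#' @param seed optional integer seed.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
randomRotation <- function(seed = NULL) {
  .withSeed(seed, {
    q <- stats::rnorm(4L)
    q <- q / sqrt(sum(q^2))
    w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), nrow = 3L, byrow = TRUE)
  })
}

#' Apply a rigid-body transform to a molecule
#'
#' Maps every atom position through a proper rotation followed by a
#' translation; charges, labels, atom order and name are unchanged, so
#' all pairwise distances (and hence the descriptor) are preserved.
#'
#' @param molecule a [Molecule-class].
#' @param rotation 3x3 orthogonal matrix with determinant +1 (checked to
#'   1e-9); default identity.
#' @param translation numeric 3-vector in Angstroem; default zero.
#' @return the transformed [Molecule-class].
#' @export
rigidTransform <- function(molecule, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  stopifnot(is(molecule, "Molecule"),
            is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("'rotation' must be orthogonal with determinant +1")
  coords <- molecule@coords %*% t(rotation)
  coords <- sweep(coords, 2L, -as.numeric(translation))
  newMolecule(molecule@name, coords, molecule@charges, molecule@labels)
}

#' Mirror image of a molecule
#'
#' Negates the x coordinate of every atom (a reflection), producing the
#' enantiomer.  All inter-atomic distances are preserved exactly, which
#' is why the descriptor cannot distinguish a molecule from its mirror
#' image.
#'
#' @param molecule a [Molecule-class].
#' @return the reflected [Molecule-class].
#' @export
mirrorMolecule <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  coords <- molecule@coords
  coords[, 1L] <- -coords[, 1L]
  newMolecule(molecule@name, coords, molecule@charges, molecule@labels)
}

#' Flip the sign of every partial charge
#'
#' All pairwise charge products \eqn{q_i q_j} are unchanged when both
#' signs flip, so the descriptor cannot distinguish a molecule from its
#' charge-reversed copy.
#'
#' @param molecule a [Molecule-class].
#' @return the charge-flipped [Molecule-class].
#' @export
flipCharges <- function(molecule) {
  stopifnot(is(molecule, "Molecule"))
  newMolecule(molecule@name, molecule@coords, -molecule@charges,
              molecule@labels)
}

#' Perturb coordinates and charges of a molecule
#'
#' Adds independent Gaussian noise to every coordinate (sd
#' \code{coordSd}, Angstroem) and every charge (sd \code{chargeSd}, e),
#' emulating an alternative conformer / charge-assignment perturbation.
#'
#' @param molecule a [Molecule-class].
#' @param coordSd,chargeSd non-negative noise standard deviations.
#' @param seed optional integer seed.
#' @return the jittered [Molecule-class].
#' @export
jitterMolecule <- function(molecule, coordSd = 0.005, chargeSd = 0.01,
                           seed = NULL) {
  stopifnot(is(molecule, "Molecule"), coordSd >= 0, chargeSd >= 0)
  .withSeed(seed, {
    n <- nrow(molecule@coords)
    coords <- molecule@coords +
      matrix(stats::rnorm(3L * n, sd = coordSd), ncol = 3L)
    charges <- molecule@charges + stats::rnorm(n, sd = chargeSd)
    newMolecule(molecule@name, coords, charges, molecule@labels)
  })
}

#' Build a synthetic active/decoy screening set
#'
#' Emulates a retrospective screening benchmark: the query is a random
#' point-charge molecule; actives are rigid-transformed (random rotation
#' + translation), then coordinate- and charge-jittered copies of the
#' query, named \code{active_1 ...}; decoys are independent random
#' molecules with the same atom count and charge spread (physically
#' matched but geometrically unrelated), named \code{decoy_1 ...}.  The
#' whole set is deterministic under \code{seed}.
#'
#' @param nAtoms,box,chargeScale query geometry, see [randomMolecule()].
#' @param nActives,nDecoys set sizes; defaults 20 and 700.
#' @param coordJitter,chargeJitter active perturbation standard
#'   deviations (Angstroem / e); defaults 0.005 and 0.01.  Set both to 0
#'   for exact rigid copies.
#' @param seed optional integer seed for the whole set.
#' @return list with elements \code{query} ([Molecule-class]) and
#'   \code{database} (list of actives then decoys).
#' @examples
#' set <- makeScreeningSet(nActives = 3, nDecoys = 10, seed = 7)
#' vapply(set$database[1:3], molName, "")
#' @export
makeScreeningSet <- function(nAtoms = 20L, box = 10, chargeScale = 0.2,
                             nActives = 20L, nDecoys = 700L,
                             coordJitter = 0.005, chargeJitter = 0.01,
                             seed = NULL) {
  stopifnot(nActives >= 0L, nDecoys >= 0L, coordJitter >= 0,
            chargeJitter >= 0)
  .withSeed(seed, {
    query <- randomMolecule(nAtoms, box, chargeScale, name = "query")
    actives <- lapply(seq_len(nActives), function(i) {
      m <- rigidTransform(query, randomRotation(),
                          translation = stats::runif(3L, -20, 20))
      m <- jitterMolecule(m, coordSd = coordJitter, chargeSd = chargeJitter)
      newMolecule(sprintf("active_%d", i), m@coords, m@charges, m@labels)
    })
    decoys <- lapply(seq_len(nDecoys), function(i) {
      randomMolecule(nAtoms, box, chargeScale,
                     name = sprintf("decoy_%d", i))
    })
    list(query = query, database = c(actives, decoys))
  })
}

#' Write a fixture set to disk
#'
#' Writes the query and database as two MOL2 files plus a plain-text
#' manifest recording the generator parameters, so a set can be
#' regenerated or audited.
#'
#' @param set list as returned by [makeScreeningSet()].
#' @param dir output directory (created if needed).
#' @param params optional named list echoed into the manifest.
#' @return invisibly, the directory path.
#' @export
writeScreeningSet <- function(set, dir, params = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMol2(list(set$query), file.path(dir, "query.mol2"))
  writeMol2(set$database, file.path(dir, "database.mol2"))
  lines <- c(sprintf("n_database %d", length(set$database)),
             vapply(names(params),
                    function(k) sprintf("%s %s", k, format(params[[k]])),
                    ""))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
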