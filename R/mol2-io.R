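# TRIPOS MOL2 reading/writing.  Only @<TRIPOS>MOLECULE and @<TRIPOS>ATOM
# are interpreted; BOND and all other record types are skipped (bonds are
# unused by the descriptor).  The partial charge is the 9th ATOM column;
# any trailing status-bit fields are ignored by column count.

# Buffered line source over a connection: bounded memory, one-line pushback,
# global line numbering for error messages.
.lineSource <- function(source, chunk = 4096L) {
  if (inherits(source, "connection")) {
    con <- source
    owned <- FALSE
  } else {
    con <- file(source, open = "rt")
    owned <- TRUE
  }
  buf <- character(0)
  pos <- 0L
  lineNo <- 0L
  pushed <- NULL
  eof <- FALSE
  list(
    nextLine = function() {
      if (!is.null(pushed)) {
        l <- pushed
        pushed <<- NULL
        return(l)
      }
      if (pos >= length(buf)) {
        if (eof) return(NULL)
        buf <<- readLines(con, n = chunk, warn = FALSE)
        pos <<- 0L
        if (length(buf) < chunk) eof <<- TRUE
        if (length(buf) == 0L) return(NULL)
      }
      pos <<- pos + 1L
      lineNo <<- lineNo + 1L
      buf[pos]
    },
    pushBack = function(l) pushed <<- l,
    lineNo = function() lineNo,
    close = function() if (owned) close(con)
  )
}

.isSectionHeader <- function(line) startsWith(line, "@<TRIPOS>")

.parseAtomRow <- function(line, lineNo) {
  fields <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  if (length(fields) < 9L)
    stop(sprintf(
      "MOL2 line %d: ATOM row has %d fields, expected at least 9 (missing charge column?)",
      lineNo, length(fields)), call. = FALSE)
  num <- suppressWarnings(as.numeric(fields[c(3L, 4L, 5L, 9L)]))
  if (anyNA(num) || !all(is.finite(num)))
    stop(sprintf(
      "MOL2 line %d: non-numeric coordinate or charge field in ATOM row",
      lineNo), call. = FALSE)
  list(label = fields[2L], x = num[1L], y = num[2L], z = num[3L],
       charge = num[4L])
}

# Parses one molecule record; the source must be positioned at (or before)
# its @<TRIPOS>MOLECULE line.  Returns NULL at end of input.
.readNextMolecule <- function(src) {
  repeat {
    line <- src$nextLine()
    if (is.null(line)) return(NULL)
    if (startsWith(line, "@<TRIPOS>MOLECULE")) break
  }
  name <- src$nextLine()
  if (is.null(name))
    stop(sprintf("MOL2 line %d: truncated MOLECULE record (no name line)",
                 src$lineNo()), call. = FALSE)
  name <- trimws(name)
  if (!nzchar(name))
    stop(sprintf("MOL2 line %d: empty molecule name", src$lineNo()),
         call. = FALSE)
  # Header lines up to the next section: counts, mol_type, charge_type, ...
  headerIdx <- 0L
  chargeType <- NA_character_
  repeat {
    line <- src$nextLine()
    if (is.null(line)) {
      src$pushBack(NULL)
      break
    }
    if (.isSectionHeader(line) || startsWith(line, "@<TRIPOS>MOLECULE")) {
      src$pushBack(line)
      break
    }
    headerIdx <- headerIdx + 1L
    if (headerIdx == 3L) chargeType <- trimws(line)
  }
  if (!is.na(chargeType) && identical(chargeType, "NO_CHARGES"))
    stop(sprintf(
      "MOL2 molecule \"%s\" (near line %d): charge type is NO_CHARGES; partial charges are required input",
      name, src$lineNo()), call. = FALSE)

  labels <- character(0)
  xyz <- numeric(0)
  charges <- numeric(0)
  sawAtoms <- FALSE
  repeat {
    line <- src$nextLine()
    if (is.null(line)) break
    if (startsWith(line, "@<TRIPOS>MOLECULE")) {
      src$pushBack(line)
      break
    }
    if (startsWith(line, "@<TRIPOS>ATOM")) {
      sawAtoms <- TRUE
      repeat {
        line <- src$nextLine()
        if (is.null(line)) break
        if (.isSectionHeader(line)) {
          src$pushBack(line)
          break
        }
        if (!nzchar(trimws(line)) || startsWith(line, "#")) next
        a <- .parseAtomRow(line, src$lineNo())
        labels <- c(labels, a$label)
        xyz <- c(xyz, a$x, a$y, a$z)
        charges <- c(charges, a$charge)
      }
    }
    # every other section type is skipped line by line
  }
  if (!sawAtoms)
    stop(sprintf(
      "MOL2 molecule \"%s\" (near line %d): no @<TRIPOS>ATOM section",
      name, src$lineNo()), call. = FALSE)
  if (length(charges) == 0L)
    stop(sprintf(
      "MOL2 molecule \"%s\" (near line %d): empty ATOM section",
      name, src$lineNo()), call. = FALSE)
  coords <- matrix(xyz, ncol = 3L, byrow = TRUE,
                   dimnames = list(NULL, c("x", "y", "z")))
  newMolecule(name, coords, charges, labels)
}

#' Read a multi-molecule TRIPOS MOL2 file
#'
#' Reads every \code{@<TRIPOS>MOLECULE} record into a [Molecule-class],
#' taking atom coordinates from columns 3-5 and the partial charge from
#' column 9 of each ATOM row.  Atoms of every element, hydrogens included,
#' are kept.  A record whose charge type is \code{NO_CHARGES}, or whose
#' ATOM rows lack the charge column, is an error: charges are required
#' input, never silently zeroed.  \code{BOND} and all other sections are
#' skipped.
#'
#' @param source path to a MOL2 file, or a readable text connection.
#' @return list of [Molecule-class] objects in file order (possibly empty).
#' @seealso [mol2Stream()] for constant-memory one-at-a-time reading,
#'   [writeMol2()].
#' @examples
#' f <- tempfile(fileext = ".mol2")
#' writeMol2(list(newMolecule("dipole", rbind(c(0, 0, 0), c(1, 0, 0)),
#'                            c(0.5, -0.5))), f)
#' mols <- readMol2(f)
#' atomCharges(mols[[1]])
#' @export
readMol2 <- function(source) {
  src <- .lineSource(source)
  on.exit(src$close())
  out <- list()
  repeat {
    m <- .readNextMolecule(src)
    if (is.null(m)) break
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Stream molecules from a MOL2 file one at a time
#'
#' Returns an iterator function over the molecules of a MOL2 file: each
#' call yields the next [Molecule-class], or \code{NULL} after the last
#' one.  Only one molecule is held in memory at a time, so arbitrarily
#' large databases can be scanned; the sequence of molecules is identical
#' to [readMol2()] on the same input.
#'
#' @inheritParams readMol2
#' @return a function of no arguments; call repeatedly until it returns
#'   \code{NULL}.  The underlying connection is closed automatically at
#'   end of input.
#' @examples
#' f <- tempfile(fileext = ".mol2")
#' writeMol2(list(newMolecule("a", cbind(0, 0, 0), 1),
#'                newMolecule("b", cbind(0, 0, 1), -1)), f)
#' it <- mol2Stream(f)
#' while (!is.null(m <- it())) print(molName(m))
#' @export
mol2Stream <- function(source) {
  src <- .lineSource(source)
  done <- FALSE
  function() {
    if (done) return(NULL)
    m <- .readNextMolecule(src)
    if (is.null(m)) {
      done <<- TRUE
      src$close()
    }
    m
  }
}

#' Write molecules to a TRIPOS MOL2 file
#'
#' Writes one \code{@<TRIPOS>MOLECULE} record per molecule with a
#' \code{USER_CHARGES} charge type and atom rows carrying coordinates and
#' partial charges at six decimal places, so a write/read round-trip
#' reproduces names and atom order exactly and numeric fields to within
#' 1e-6.
#'
#' @param molecules list of [Molecule-class] objects (a single molecule is
#'   accepted too).
#' @param sink output file path or writable text connection.
#' @return invisibly, the number of molecules written.
#' @seealso [readMol2()]
#' @export
writeMol2 <- function(molecules, sink) {
  if (is(molecules, "Molecule")) molecules <- list(molecules)
  if (!length(molecules)) stop("'molecules' must be non-empty")
  lines <- unlist(lapply(molecules, function(m) {
    stopifnot(is(m, "Molecule"))
    validObject(m)
    n <- nrow(m@coords)
    rows <- sprintf("%7d %-8s %12.6f %12.6f %12.6f %-5s %5d %-8s %12.6f",
                    seq_len(n), m@labels,
                    m@coords[, 1L], m@coords[, 2L], m@coords[, 3L],
                    m@labels, 1L, "MOL1", m@charges)
    c("@<TRIPOS>MOLECULE", m@name,
      sprintf("%d 0 0 0 0", n), "SMALL", "USER_CHARGES",
      "@<TRIPOS>ATOM", rows)
  }), use.names = FALSE)
  if (inherits(sink, "connection")) {
    writeLines(lines, sink)
  } else {
    con <- file(sink, open = "wt")
    on.exit(close(con))
    writeLines(lines, con)
  }
  invisible(length(molecules))
}
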