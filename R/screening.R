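# Rank-ordering of a compound database against a query molecule, with
# optional best-conformer filtering, plus the constant-memory streaming
# variant that scores in input order without ranking or filtering.

.asMoleculeIterator <- function(database) {
  if (is.function(database)) return(database)
  if (is(database, "Molecule")) database <- list(database)
  if (is.list(database)) {
    i <- 0L
    return(function() {
      if (i >= length(database)) return(NULL)
      i <<- i + 1L
      database[[i]]
    })
  }
  # a file path or connection: stream it
  mol2Stream(database)
}

.scoreOne <- function(mol, queryDesc, dx, scoreFun) {
  desc <- encodeMolecule(mol, dx)
  scoreFun(queryDesc, desc)
}

#' Screen a molecule database against a query
#'
#' Encodes every database molecule at step \code{dx}, scores it against
#' the query descriptor (query passed as the reference argument of the
#' scorer), optionally keeps only the best-scoring conformer among
#' molecules sharing a name, sorts by score (descending, stable: tied
#' scores keep first-seen input order) and assigns dense ranks 1..N.
#' Malformed molecules (e.g. atom-free records produced upstream) are
#' skipped with a warning and counted, not fatal.
#'
#' @param query a [Molecule-class].
#' @param database a list of molecules, a single molecule, a MOL2 file
#'   path/connection, or a molecule iterator as returned by
#'   [mol2Stream()].
#' @param dx grid spacing in Angstroem (default [DEFAULT_DX]).
#' @param scorer scorer tag, see [scoringFunction()]; default \code{"CC"}.
#' @param dedup keep only the best-scoring conformer per molecule name
#'   (default \code{TRUE}).
#' @return a \code{data.frame} with columns \code{name}, \code{score},
#'   \code{rank} (1 = best) and \code{active} (logical, all \code{NA}
#'   until [labelActives()] is applied), plus attribute
#'   \code{"skipped"} counting unreadable molecules.  Empty database
#'   gives a zero-row frame.
#' @examples
#' q <- randomMolecule(nAtoms = 8, name = "query", seed = 1)
#' db <- c(list(newMolecule("copy", atomCoords(q), atomCharges(q))),
#'         lapply(1:3, function(i)
#'           randomMolecule(nAtoms = 8, name = paste0("rand_", i), seed = i)))
#' screen(q, db)[1, ]   # the exact copy ranks first
#' @export
screen <- function(query, database, dx = DEFAULT_DX, scorer = "CC",
                   dedup = TRUE) {
  stopifnot(is(query, "Molecule"))
  scoreFun <- scoringFunction(scorer)
  queryDesc <- encodeMolecule(query, dx)
  it <- .asMoleculeIterator(database)
  names <- list()
  scores <- list()
  k <- 0L
  skipped <- 0L
  repeat {
    mol <- tryCatch(it(), error = function(e) e)
    if (is.null(mol)) break
    if (inherits(mol, "error")) stop(mol)
    sc <- tryCatch(.scoreOne(mol, queryDesc, dx, scoreFun),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      skipped <- skipped + 1L
      warning(sprintf("skipping molecule \"%s\": %s",
                      tryCatch(molName(mol), error = function(e) "?"),
                      conditionMessage(sc)), call. = FALSE)
      next
    }
    k <- k + 1L
    names[[k]] <- molName(mol)
    scores[[k]] <- sc
  }
  res <- data.frame(name = unlist(names, use.names = FALSE) %||% character(0),
                    score = unlist(scores, use.names = FALSE) %||% numeric(0),
                    stringsAsFactors = FALSE)
  if (nrow(res) && dedup) {
    # best-scoring conformer per name; ties keep the first-seen record
    best <- tapply(seq_len(nrow(res)), res$name, function(ix) {
      ix[which.max(res$score[ix])]
    })
    res <- res[sort(as.integer(best)), , drop = FALSE]
  }
  if (nrow(res)) {
    ord <- order(-res$score)            # radix: stable for ties
    res <- res[ord, , drop = FALSE]
    res$rank <- seq_len(nrow(res))
  } else {
    res$rank <- integer(0)
  }
  res$active <- rep(NA, nrow(res))
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  if (skipped > 0L)
    message(sprintf("screen: skipped %d unreadable molecule(s)", skipped))
  res
}

#' Constant-memory streaming screen
#'
#' Scores each database molecule against the query and writes one
#' tab-separated \code{name<TAB>score} line per molecule in input order.
#' No sorting, no ranking and no conformer filtering are performed, and
#' never more than one database molecule plus its descriptor is held in
#' memory, so databases of any size can be processed.
#'
#' @inheritParams screen
#' @param sink output file path or writable text connection; a header
#'   line records the query name, dx and scorer.
#' @return invisibly, the number of molecules scored.
#' @seealso [screen()] for the ranking (in-memory) variant; scores agree
#'   exactly with \code{screen(..., dedup = FALSE)}.
#' @export
screenStreaming <- function(query, database, dx = DEFAULT_DX,
                            scorer = "CC", sink = stdout()) {
  stopifnot(is(query, "Molecule"))
  scoreFun <- scoringFunction(scorer)
  queryDesc <- encodeMolecule(query, dx)
  it <- .asMoleculeIterator(database)
  if (inherits(sink, "connection")) {
    con <- sink
    owned <- FALSE
  } else {
    con <- file(sink, open = "wt")
    owned <- TRUE
  }
  if (owned) on.exit(close(con))
  writeLines(sprintf("# query=%s dx=%g scorer=%s",
                     molName(query), dx, scorer), con)
  count <- 0L
  skipped <- 0L
  repeat {
    mol <- it()
    if (is.null(mol)) break
    sc <- tryCatch(.scoreOne(mol, queryDesc, dx, scoreFun),
                   error = function(e) e)
    if (inherits(sc, "error")) {
      skipped <- skipped + 1L
      warning(sprintf("skipping molecule \"%s\": %s", molName(mol),
                      conditionMessage(sc)), call. = FALSE)
      next
    }
    writeLines(sprintf("%s\t%.17g", molName(mol), sc), con)
    count <- count + 1L
  }
  if (skipped > 0L)
    message(sprintf("streaming screen: skipped %d molecule(s)", skipped))
  invisible(count)
}

#' Label actives in a screening result by name prefix
#'
#' Sets the \code{active} flag of each record to whether its molecule
#' name starts with \code{prefix}; nothing else is altered.  Active
#' compounds in a benchmark set are conventionally identified by names
#' starting with \code{"active"}.
#'
#' @param records data.frame as returned by [screen()].
#' @param prefix non-empty name prefix (default \code{"active"}).
#' @return the records with the \code{active} column filled in.
#' @export
labelActives <- function(records, prefix = "active") {
  stopifnot(is.data.frame(records), is.character(prefix),
            length(prefix) == 1L, nzchar(prefix))
  records$active <- startsWith(records$name, prefix)
  records
}

#' Write a ranked scores table
#'
#' Tab-separated columns \code{name}, \code{score}, \code{rank} under a
#' \code{#}-prefixed header carrying the query name, dx and scorer (and
#' the AUC when supplied), so batch runs can be harvested from the files
#' alone.
#'
#' @param records data.frame from [screen()].
#' @param sink output path or writable connection.
#' @param query optional query [Molecule-class] for the header.
#' @param dx,scorer optional protocol parameters for the header.
#' @param auc optional AUC value appended to the header.
#' @return invisibly, \code{NULL}.
#' @export
writeScores <- function(records, sink, query = NULL, dx = NULL,
                        scorer = NULL, auc = NULL) {
  hdr <- "#"
  if (!is.null(query)) hdr <- paste0(hdr, " query=", molName(query))
  if (!is.null(dx)) hdr <- paste0(hdr, " dx=", format(dx))
  if (!is.null(scorer)) hdr <- paste0(hdr, " scorer=", scorer)
  if (!is.null(auc)) hdr <- paste0(hdr, sprintf(" auc=%.6f", auc))
  lines <- c(hdr, "#name\tscore\trank",
             sprintf("%s\t%.17g\t%d", records$name, records$score,
                     records$rank))
  if (inherits(sink, "connection")) writeLines(lines, sink)
  else writeLines(lines, sink)
  invisible(NULL)
}
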