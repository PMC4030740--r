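# ROC/AUC evaluation of a ranked active/decoy screen.  The curve is built
# by descending score with tied scores collapsed into one step, and the
# trapezoidal area then equals the rank-sum (Mann-Whitney) estimator
# P(score_active > score_decoy) + P(equal)/2.

#' ROC curve and AUC of a labelled screening result
#'
#' Builds the receiver operating characteristic of a screening result by
#' sweeping the score threshold downwards.  Records with tied scores are
#' handled as a single step, producing a diagonal segment across the tie
#' block, so the trapezoidal area equals the probability that a uniformly
#' chosen active outscores a uniformly chosen decoy, with ties counted
#' one half.  The result does not depend on the order of the input rows,
#' only on scores and labels, and is unchanged by any strictly increasing
#' transform of the scores.
#'
#' @param records data.frame with numeric \code{score} and logical
#'   \code{active} columns (as produced by [screen()] + [labelActives()]),
#'   or a [RocCurve-class]-ready pair given as \code{scores} and
#'   \code{labels} vectors via the two-argument form
#'   \code{rocCurve(scores, labels)}.
#' @param labels optional logical vector; when supplied, \code{records}
#'   is taken to be the numeric score vector instead.
#' @return a [RocCurve-class].
#' @section Errors: at least one active and one decoy are required; the
#'   AUC is undefined otherwise.
#' @examples
#' rc <- rocCurve(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' auc(rc)   # 1: perfect separation
#' @export
rocCurve <- function(records, labels = NULL) {
  if (is.null(labels)) {
    stopifnot(is.data.frame(records),
              all(c("score", "active") %in% names(records)))
    scores <- records$score
    labels <- records$active
  } else {
    scores <- records
  }
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(labels))
    stop("labels contain NA; apply labelActives() first")
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: need at least one active and one decoy")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # one curve point per distinct score (end of each tie block)
  blockEnd <- which(c(s[-1L] != s[-length(s)], TRUE))
  tp <- cumsum(l)[blockEnd]
  fp <- cumsum(!l)[blockEnd]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  aucVal <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  new("RocCurve", fpr = fpr, tpr = tpr, auc = aucVal)
}

#' Summarize a collection of AUCs
#'
#' Mean, median and quartiles of per-query AUC values, the standard way a
#' retrospective screen over many queries or targets is reported.
#' Quartiles use linear interpolation of order statistics (the default
#' quantile convention).
#'
#' @param aucs non-empty numeric vector of AUC values in [0, 1].
#' @return named list with \code{mean}, \code{median}, \code{q1},
#'   \code{q3} and \code{n}.
#' @export
aucSummary <- function(aucs) {
  stopifnot(is.numeric(aucs), length(aucs) >= 1L,
            all(is.finite(aucs)), all(aucs >= 0 & aucs <= 1))
  qs <- stats::quantile(aucs, probs = c(0.25, 0.5, 0.75), names = FALSE,
                        type = 7)
  list(mean = mean(aucs), median = qs[2L], q1 = qs[1L], q3 = qs[3L],
       n = length(aucs))
}

#' Write ROC points as two-column CSV
#'
#' @param roc a [RocCurve-class].
#' @param sink output path or writable connection.
#' @return invisibly, \code{NULL}.
#' @export
writeRoc <- function(roc, sink) {
  stopifnot(is(roc, "RocCurve"))
  utils::write.csv(rocPoints(roc), sink, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
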