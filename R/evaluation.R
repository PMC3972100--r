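## Ranked-classification and ranking metrics: ROC, AUC, early enrichment,
## rank correlation. Implemented directly (threshold sweep + pair counting)
## so the two AUC computations can cross-check each other on every call.

#' Receiver operating characteristic of a decision statistic
#'
#' Builds the ROC curve by sweeping a descending-score threshold; higher
#' scores mean "predicted positive". Tied scores are processed as a single
#' threshold step, producing one diagonal segment, which is equivalent to
#' giving half credit to tied positive-negative pairs. The AUC is computed
#' by the trapezoid rule and, independently, as
#' \code{(concordant + 0.5 * tied) / (nPos * nNeg)} (the Mann-Whitney
#' statistic); the call fails if the two disagree beyond 1e-12. An ideal
#' ranking gives AUC 1.0, a random one 0.5 on average.
#'
#' @param scores numeric decision values.
#' @param labels logical (TRUE = positive), or anything coercible via
#'   \code{positive}.
#' @param positive when \code{labels} is not logical, the level counted as
#'   positive.
#' @return a \linkS4class{ROCResult}.
#' @examples
#' r <- rocCurve(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
#' auc(r)           # 0.75
#' @export
rocCurve <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels length mismatch")
  if (!is.logical(labels)) {
    if (is.null(positive)) stop("supply `positive` for non-logical labels")
    labels <- labels == positive
  }
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("need at least one positive and one negative")
  ## descending threshold sweep, tie groups collapsed to one step
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  aucTrap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  ## independent pair-counting route
  rk <- rank(scores)  # average ranks for ties
  aucPairs <- (sum(rk[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  if (abs(aucTrap - aucPairs) > 1e-12)
    stop("internal AUC cross-check failed: trapezoid ", aucTrap,
         " vs pair-count ", aucPairs)
  ## early enrichment: TPR at the last curve vertex with FPR = 0; a tie
  ## group mixing classes raises FPR at that vertex, so ties between a
  ## positive and a negative count pessimistically
  tprZero <- max(tpr[fpr == 0])
  new("ROCResult", fpr = fpr, tpr = tpr, auc = aucTrap,
      nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      tprAtZeroFpr = tprZero)
}

#' @rdname rocCurve
#' @param x a \linkS4class{ROCResult}.
#' @export
setMethod("auc", "ROCResult", function(x) x@auc)

#' @rdname rocCurve
#' @export
setMethod("tprAtZeroFpr", "ROCResult", function(x) x@tprAtZeroFpr)

#' Curve points of a ROCResult
#' @param x a \linkS4class{ROCResult}.
#' @return data.frame with columns fpr, tpr.
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ROCResult"))
  data.frame(fpr = x@fpr, tpr = x@tpr)
}

#' Spearman rank correlation for congeneric-series ranking
#'
#' Rank correlation between predicted and observed binding, with average
#' ranks for ties — the statistic used to judge whether a model orders a
#' congeneric series (close structural analogues) correctly.
#'
#' @param predicted,observed equal-length numeric vectors (n >= 3).
#' @return rho in [-1, 1].
#' @examples
#' rankCorrelation(1:4, c(1, 3, 2, 4))   # 0.8
#' @export
rankCorrelation <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("constant vector: rank correlation undefined")
  stats::cor(rank(predicted), rank(observed))
}

#' Evaluation report over one or more models
#'
#' Convenience wrapper producing the delimited evaluation-report rows
#' (model, set, AUC, TPR at zero FPR, class counts) for a list of score
#' vectors against one label vector.
#'
#' @param scoreList named list of numeric decision-value vectors.
#' @param labels logical labels (TRUE = positive).
#' @param setName label for the evaluation set.
#' @return data.frame, one row per model.
#' @export
evaluationReport <- function(scoreList, labels, setName = "set") {
  stopifnot(is.list(scoreList), length(names(scoreList)) == length(scoreList))
  rows <- lapply(names(scoreList), function(nm) {
    r <- rocCurve(scoreList[[nm]], labels)
    data.frame(model = nm, set = setName, auc = auc(r),
               tpr_at_zero_fpr = tprAtZeroFpr(r),
               n_pos = r@nPos, n_neg = r@nNeg)
  })
  do.call(rbind, rows)
}
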