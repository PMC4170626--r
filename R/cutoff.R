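#' Build an empiric ROC curve from continuous methylation scores
#'
#' Candidate cutoffs are the distinct observed scores plus one sentinel
#' outside their range (below the minimum for direction "greater", above
#' the maximum for "less"), so the all-positive operating point is always
#' present. At a candidate cutoff a sample is called positive when its
#' score is strictly greater (resp. strictly less) than the cutoff; the
#' strict inequality makes score 0 - no amplification - always negative at
#' cutoff 0. Sensitivity is the called-positive fraction of true
#' positives, specificity the called-negative fraction of true negatives.
#'
#' @param ratios numeric scores, no missing values (drop them first).
#' @param labels logical (or coercible) class labels, TRUE = positive
#'   class; both classes must be present.
#' @param direction "greater" (default) or "less".
#' @param gene optional gene symbol carried through to the curve.
#' @return A \linkS4class{RocCurve}.
#' @examples
#' roc <- buildRoc(c(10, 20, 30, 0, 1, 2), rep(c(TRUE, FALSE), each = 3))
#' rocPoints(roc)
#' @export
buildRoc <- function(ratios, labels, direction = c("greater", "less"),
                     gene = "") {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(ratios) || anyNA(labels))
    stop("missing scores or labels are not allowed in a ROC curve")
  if (length(ratios) != length(labels))
    stop("'ratios' and 'labels' lengths differ")
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC is undefined with a single class")
  cand <- sort(unique(ratios))
  cand <- if (direction == "greater") c(cand[1L] - 1, cand) else
    c(cand, cand[length(cand)] + 1)
  pos <- ratios[labels]
  neg <- ratios[!labels]
  if (direction == "greater") {
    sens <- vapply(cand, function(ct) mean(pos > ct), 0)
    spec <- vapply(cand, function(ct) mean(neg <= ct), 0)
  } else {
    sens <- vapply(cand, function(ct) mean(pos < ct), 0)
    spec <- vapply(cand, function(ct) mean(neg >= ct), 0)
  }
  new("RocCurve", gene = as.character(gene),
      points = data.frame(cutoff = cand, sensitivity = sens,
                          specificity = spec),
      direction = direction, nPos = as.integer(nPos),
      nNeg = as.integer(nNeg))
}

#' Area under an empiric ROC curve
#'
#' Trapezoidal area over the (1 - specificity, sensitivity) points of the
#' curve.
#'
#' @param roc a \linkS4class{RocCurve}.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(roc) {
  stopifnot(is(roc, "RocCurve"))
  p <- roc@points
  fpr <- 1 - p$specificity
  o <- order(fpr, p$sensitivity)
  x <- c(0, fpr[o], 1)
  y <- c(0, p$sensitivity[o], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Select the empiric cutoff maximizing sensitivity + specificity
#'
#' Returns the candidate cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1, the "empiric cutoff" convention for
#' dichotomizing QMSP scores. Ties are broken first by higher specificity,
#' then by lower cutoff value, so the result is reproducible without
#' interpolation.
#'
#' @param roc a \linkS4class{RocCurve}.
#' @return A \linkS4class{MarkerCutoff}.
#' @examples
#' roc <- buildRoc(c(10, 20, 30, 0, 1, 2), rep(c(TRUE, FALSE), each = 3))
#' empiricCutoff(roc)   # cutoff 2, J = 1
#' @export
empiricCutoff <- function(roc) {
  stopifnot(is(roc, "RocCurve"))
  p <- roc@points
  j <- p$sensitivity + p$specificity - 1
  best <- order(-j, -p$specificity, p$cutoff)[1L]
  new("MarkerCutoff", gene = roc@gene, value = p$cutoff[best],
      direction = roc@direction, youden = j[best],
      sensitivity = p$sensitivity[best],
      specificity = p$specificity[best])
}

#' Build the ROC and pick the empiric cutoff in one step
#'
#' Convenience wrapper around \code{\link{buildRoc}} and
#' \code{\link{empiricCutoff}}. With \code{direction = "auto"} both
#' positivity directions are scanned and the one with the larger Youden J
#' is kept ("greater" on ties, the usual case for methylation scores that
#' rise with disease).
#'
#' @param ratios numeric scores; missing values are dropped together with
#'   their labels.
#' @param labels logical class labels, TRUE = positive class.
#' @param direction "auto", "greater" or "less".
#' @param gene optional gene symbol.
#' @return A \linkS4class{MarkerCutoff}.
#' @examples
#' selectCutoff(c(10, 20, 30, 0, 1, 2), rep(c(TRUE, FALSE), each = 3),
#'              gene = "CCND2")
#' @export
selectCutoff <- function(ratios, labels,
                         direction = c("auto", "greater", "less"),
                         gene = "") {
  direction <- match.arg(direction)
  keep <- !is.na(ratios) & !is.na(labels)
  ratios <- ratios[keep]
  labels <- labels[keep]
  if (direction != "auto")
    return(empiricCutoff(buildRoc(ratios, labels, direction, gene)))
  cg <- empiricCutoff(buildRoc(ratios, labels, "greater", gene))
  cl <- empiricCutoff(buildRoc(ratios, labels, "less", gene))
  if (youdenJ(cl) > youdenJ(cg)) cl else cg
}

#' Dichotomize scores at a cutoff
#'
#' Calls a sample methylated when its score is strictly beyond the cutoff
#' in the positive direction (\code{score > value} for direction
#' "greater"). Missing scores yield missing calls.
#'
#' @param ratios numeric scores (may contain \code{NA}).
#' @param cutoff a \linkS4class{MarkerCutoff}.
#' @return Logical vector (TRUE = methylated, NA = missing) with the
#'   cutoff's gene, value and direction attached as attributes.
#' @examples
#' cut <- selectCutoff(c(10, 20, 30, 0, 1, 2),
#'                     rep(c(TRUE, FALSE), each = 3))
#' dichotomize(c(0, 1000, NA), cut)
#' @export
dichotomize <- function(ratios, cutoff) {
  stopifnot(is(cutoff, "MarkerCutoff"))
  call <- if (cutoff@direction == "greater") ratios > cutoff@value else
    ratios < cutoff@value
  structure(call, gene = cutoff@gene, cutoff = cutoff@value,
            direction = cutoff@direction)
}
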