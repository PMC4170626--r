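#' One Q-RT-PCR expression measurement
#'
#' Triplicate target-gene and reference-gene (internal control, e.g.
#' GAPDH) Ct values for one condition. All Ct values must be determined
#' and within the cycling program.
#'
#' @param condition label, e.g. "AZA" or "PBS".
#' @param targetCt numeric replicate Ct values for the gene of interest.
#' @param referenceCt numeric replicate Ct values for the internal
#'   control.
#' @param maxCycles program length bounding valid Ct (default 40 for
#'   expression assays).
#' @return list of class \code{"ExpressionMeasurement"}.
#' @examples
#' expressionMeasurement("AZA", c(28.1, 28.3, 28.2), c(18.0, 18.1, 17.9))
#' @export
expressionMeasurement <- function(condition, targetCt, referenceCt,
                                  maxCycles = 40) {
  for (nm in c("targetCt", "referenceCt")) {
    ct <- get(nm)
    if (!length(ct) || anyNA(ct))
      stop("'", nm, "' must contain only determined Ct values")
    if (any(ct <= 0 | ct > maxCycles))
      stop("'", nm, "' out of range (0, ", maxCycles, "]")
  }
  structure(list(condition = as.character(condition),
                 targetCt = as.numeric(targetCt),
                 referenceCt = as.numeric(referenceCt)),
            class = "ExpressionMeasurement")
}

#' Relative expression by the comparative CT (2^-ddCt) method
#'
#' dCt = mean(target Ct) - mean(reference Ct) per condition;
#' ddCt = dCt(treated) - dCt(control); fold change = 2^-ddCt. The
#' reference gene cancels plate offsets, so adding a constant to every Ct
#' of a condition leaves the fold change unchanged.
#'
#' @param treated,control \code{ExpressionMeasurement} objects (see
#'   \code{\link{expressionMeasurement}}).
#' @return list with \code{fold}, \code{deltaDeltaCt}, and the per
#'   condition \code{deltaCtTreated}, \code{deltaCtControl}.
#' @examples
#' tr <- expressionMeasurement("AZA", c(27, 27, 27), c(18, 18, 18))
#' ct <- expressionMeasurement("PBS", c(30, 30, 30), c(18, 18, 18))
#' foldChange(tr, ct)$fold   # 8: three cycles earlier = 2^3
#' @export
foldChange <- function(treated, control) {
  stopifnot(inherits(treated, "ExpressionMeasurement"),
            inherits(control, "ExpressionMeasurement"))
  dT <- mean(treated$targetCt) - mean(treated$referenceCt)
  dC <- mean(control$targetCt) - mean(control$referenceCt)
  ddCt <- dT - dC
  list(fold = 2^(-ddCt), deltaDeltaCt = ddCt,
       deltaCtTreated = dT, deltaCtControl = dC)
}

#' Two-group Student t-test for replicate assay values
#'
#' Two-sided pooled-variance Student t-test ("Student t-test" in its
#' classical meaning), used to compare duplicate/triplicate averages
#' between conditions. An unequal-variance (Welch) option is available.
#' Degenerate inputs are handled explicitly: zero pooled variance with
#' equal means gives p = 1; zero variance with different means gives p = 0
#' flagged degenerate.
#'
#' @param groupA,groupB numeric replicate values, at least 2 each.
#' @param varEqual pooled-variance Student test (default TRUE); FALSE for
#'   Welch.
#' @return list with \code{statistic}, \code{p.value}, \code{degenerate}.
#' @examples
#' twoGroupTTest(c(1, 2, 3), c(4, 5, 6))
#' @export
twoGroupTTest <- function(groupA, groupB, varEqual = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 values per group")
  pooledVar <- (sum((groupA - mean(groupA))^2) +
                  sum((groupB - mean(groupB))^2)) /
    (length(groupA) + length(groupB) - 2L)
  if (pooledVar == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, p.value = 1, degenerate = FALSE))
    return(list(statistic = Inf, p.value = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = varEqual)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       degenerate = FALSE)
}

#' Significance stars for report formatting
#'
#' The star bands used in the re-expression figures: "***" below 1e-4,
#' "**" below 0.01, "*" below 0.05, otherwise "NS".
#'
#' @param p p-value(s).
#' @return character vector of star codes.
#' @export
significanceStars <- function(p) {
  ifelse(p < 1e-4, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}

#' Fold-change table from a long-format expression data set
#'
#' For every gene, computes the 2^-ddCt fold change of each treatment
#' condition against the control condition and a pooled-variance t-test on
#' the replicate dCt values.
#'
#' @param data long-format data.frame with columns \code{condition},
#'   \code{gene}, \code{replicate}, \code{ct}.
#' @param referenceGene internal control gene (default "GAPDH").
#' @param controlCondition baseline condition (default "PBS").
#' @return data.frame: gene, condition, fold, deltaDeltaCt, p.value,
#'   stars.
#' @export
foldChangeTable <- function(data, referenceGene = "GAPDH",
                            controlCondition = "PBS") {
  need <- c("condition", "gene", "replicate", "ct")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
  genes <- setdiff(unique(data$gene), referenceGene)
  conds <- setdiff(unique(data$condition), controlCondition)
  getCt <- function(cond, gene)
    data$ct[data$condition == cond & data$gene == gene]
  rows <- list()
  for (g in genes) {
    refCtrl <- getCt(controlCondition, referenceGene)
    if (!length(refCtrl))
      stop("no reference-gene wells for condition '", controlCondition, "'")
    ctrl <- expressionMeasurement(controlCondition,
                                  getCt(controlCondition, g), refCtrl)
    ## per-replicate dCt for the t-test (replicates paired by index)
    dCtCtrl <- getCt(controlCondition, g) - refCtrl
    for (cond in conds) {
      refTr <- getCt(cond, referenceGene)
      tr <- expressionMeasurement(cond, getCt(cond, g), refTr)
      fc <- foldChange(tr, ctrl)
      tt <- twoGroupTTest(getCt(cond, g) - refTr, dCtCtrl)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, fold = fc$fold,
        deltaDeltaCt = fc$deltaDeltaCt, p.value = tt$p.value,
        stars = significanceStars(tt$p.value), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
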