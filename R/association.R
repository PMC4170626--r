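#' Cross-tabulate marker calls against a binary group
#'
#' Builds the 2x2 table of group x methylation status. Samples with a
#' missing call or missing group label are excluded pairwise, so the table
#' margins equal the number of jointly observed samples.
#'
#' @param calls logical methylation calls (TRUE = methylated; NA allowed)
#'   or "+"/"-"/NA codes.
#' @param groups binary group labels (factor, character or logical); the
#'   first factor level forms the first row.
#' @return A \linkS4class{ContingencyTable2x2}.
#' @examples
#' calls <- c(TRUE, TRUE, FALSE, FALSE, TRUE, NA)
#' grp <- c("rec", "rec", "rec", "non", "non", "non")
#' tableCounts(build2x2(calls, grp))
#' @export
build2x2 <- function(calls, groups) {
  calls <- .plusToLogical(calls)
  if (length(calls) != length(groups))
    stop("'calls' and 'groups' lengths differ")
  g <- if (is.factor(groups)) groups else factor(groups)
  keep <- !is.na(calls) & !is.na(g)
  if (!any(keep))
    stop("no jointly observed samples to tabulate")
  calls <- calls[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) != 2L)
    stop("'groups' must take exactly two observed values, got: ",
         paste(levels(g), collapse = ", "))
  lev <- levels(g)
  contingency2x2(
    sum(g == lev[1L] & calls), sum(g == lev[1L] & !calls),
    sum(g == lev[2L] & calls), sum(g == lev[2L] & !calls),
    rowLabels = lev
  )
}

#' Hypergeometric probability of a 2x2 table cell
#'
#' Probability that the first cell equals \code{a} under fixed margins:
#' \code{P(A = a) = C(r1, a) C(r2, k - a) / C(N, k)} with row sums
#' \code{r1}, \code{r2} and first-column sum \code{k}. Computed with
#' log-gamma binomials for overflow safety; infeasible \code{a} has
#' probability 0.
#'
#' @param a first-cell count (vectorized).
#' @param r1,r2 row sums.
#' @param k first-column sum.
#' @return Probability (or vector of probabilities).
#' @examples
#' hypergeomPmf(0:1, r1 = 1, r2 = 1, k = 1)   # 0.5 0.5
#' @export
hypergeomPmf <- function(a, r1, r2, k) {
  feas <- a >= max(0, k - r2) & a <= min(r1, k) & a == round(a)
  out <- numeric(length(a))
  out[feas] <- exp(lchoose(r1, a[feas]) + lchoose(r2, k - a[feas]) -
                     lchoose(r1 + r2, k))
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of independence given the table margins, with
#' the probability-mass two-sided rule: the p-value is the sum of
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (up to a
#' 1 + 1e-7 relative slack absorbing floating-point ties between
#' symmetric tables). A table with a zero row or column margin admits a
#' single configuration and gives p = 1.
#'
#' @param table a \linkS4class{ContingencyTable2x2}, or a 2x2 matrix of
#'   counts.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(contingency2x2(10, 9, 2, 15))   # 0.014
#' @export
fisherExactTwoSided <- function(table) {
  m <- if (is(table, "ContingencyTable2x2")) tableCounts(table) else table
  stopifnot(is.matrix(m), identical(dim(m), c(2L, 2L)), all(m >= 0))
  a <- m[1L, 1L]
  r1 <- sum(m[1L, ])
  r2 <- sum(m[2L, ])
  k <- sum(m[, 1L])
  supp <- max(0, k - r2):min(r1, k)
  logp <- lchoose(r1, supp) + lchoose(r2, k - supp) - lchoose(r1 + r2, k)
  logObs <- logp[supp == a]
  p <- sum(exp(logp[logp <= logObs + log1p(1e-7)]))
  min(1, p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' One-degree-of-freedom chi-square test of independence, with optional
#' Yates continuity correction. Requires all margins positive; with a zero
#' margin the statistic is undefined and the exact test should be used
#' instead.
#'
#' @param table a \linkS4class{ContingencyTable2x2} or 2x2 count matrix.
#' @param correction apply the continuity correction (default FALSE).
#' @return list with \code{statistic} and \code{p.value}.
#' @examples
#' chiSquareTest(contingency2x2(10, 10, 5, 5))$p.value   # 1
#' @export
chiSquareTest <- function(table, correction = FALSE) {
  m <- if (is(table, "ContingencyTable2x2")) tableCounts(table) else table
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: the chi-square test is undefined, ",
         "use fisherExactTwoSided()")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correction))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Test association in a 2x2 table, choosing the test like a practitioner
#'
#' "Chi-square or Fisher's exact test as appropriate": the exact test
#' whenever any expected cell count is below 5 (or a margin is zero), the
#' chi-square otherwise. Both tests remain available explicitly.
#'
#' @param table a \linkS4class{ContingencyTable2x2} or 2x2 count matrix.
#' @param method "auto" (default), "fisher" or "chisq".
#' @return list with \code{p.value}, \code{method} used and the table.
#' @examples
#' associationTest(contingency2x2(10, 9, 2, 15))
#' @export
associationTest <- function(table, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  m <- if (is(table, "ContingencyTable2x2")) tableCounts(table) else table
  if (method == "auto") {
    zeroMargin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
    expected <- if (zeroMargin) 0 else
      outer(rowSums(m), colSums(m)) / sum(m)
    method <- if (zeroMargin || any(expected < 5)) "fisher" else "chisq"
  }
  p <- if (method == "fisher") fisherExactTwoSided(m) else
    chiSquareTest(m)$p.value
  list(p.value = p, method = method, table = m)
}

#' Per-marker association report for a cohort
#'
#' Cross-tabulates every marker call column against a grouping column and
#' tests each table, producing the long-format association report
#' (gene, grouping, cell counts, test used, p-value).
#'
#' @param cohort cohort data.frame with "+"/"-"/NA marker call columns.
#' @param markers marker column names.
#' @param grouping name of the binary grouping column.
#' @param method test choice passed to \code{\link{associationTest}}.
#' @return data.frame with one row per marker.
#' @examples
#' cohort <- data.frame(grp = rep(c("case", "control"), each = 4),
#'                      CCND2 = c("+", "+", "+", "-", "-", "-", "-", "-"))
#' associationReport(cohort, "CCND2", "grp")
#' @export
associationReport <- function(cohort, markers, grouping,
                              method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  rows <- lapply(markers, function(g) {
    tab <- build2x2(cohort[[g]], cohort[[grouping]])
    res <- associationTest(tab, method)
    cnt <- tableCounts(tab)
    data.frame(gene = g, grouping = grouping,
               group1 = rownames(cnt)[1L], group2 = rownames(cnt)[2L],
               a = cnt[1L, 1L], b = cnt[1L, 2L],
               c = cnt[2L, 1L], d = cnt[2L, 2L],
               test = res$method, p.value = res$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
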