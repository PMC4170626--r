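#' Combine marker calls into the any-positive panel call
#'
#' A patient is panel positive when at least one non-missing marker is
#' methylated, panel negative when every observed marker is unmethylated;
#' missing markers are ignored (never count as positive). A patient with
#' no observed marker at all gets a missing panel call.
#'
#' @param calls per-marker calls: a data.frame or matrix with one row per
#'   patient and one column per marker, either logical or "+"/"-"/NA
#'   coded; or a vector for a single patient.
#' @return Logical vector of panel calls (TRUE = positive, NA = no marker
#'   observed).
#' @examples
#' combinePanel(data.frame(CCNA1 = c(NA, NA), CCND2 = c("-", "-"),
#'                         CALCA = c("+", "-")))   # TRUE FALSE
#' @export
combinePanel <- function(calls) {
  if (is.null(dim(calls)))
    calls <- matrix(calls, nrow = 1L)
  m <- vapply(seq_len(ncol(calls)),
              function(j) .plusToLogical(calls[, j, drop = TRUE]),
              logical(nrow(calls)))
  m <- matrix(m, nrow = nrow(calls))
  anyPos <- rowSums(m, na.rm = TRUE) > 0
  noneObserved <- rowSums(!is.na(m)) == 0L
  anyPos[noneObserved] <- NA
  anyPos
}

#' Any-positive panel sensitivity on a cohort of confirmed cases
#'
#' Sensitivity = panel-positive / evaluable among confirmed cancer cases,
#' where evaluable means at least one marker observed.
#'
#' @param cohort cohort data.frame of confirmed cases.
#' @param markers marker call column names.
#' @return A \linkS4class{PanelResult} (numerator, denominator,
#'   proportion). Zero evaluable rows is an error.
#' @examples
#' cohort <- data.frame(CCND2 = c("+", "-", "-"), CALCA = c("-", "-", "+"))
#' panelSensitivity(cohort, c("CCND2", "CALCA"))   # 2/3
#' @export
panelSensitivity <- function(cohort, markers) {
  panel <- combinePanel(cohort[, markers, drop = FALSE])
  evaluable <- !is.na(panel)
  if (!any(evaluable))
    stop("no evaluable rows: every patient is missing all markers")
  .panelResult("panel sensitivity", sum(panel[evaluable]), sum(evaluable))
}

#' Cytology-negative rescue by the methylation panel
#'
#' Among cytology-negative cases, the count and fraction with a positive
#' any-positive panel call - the patients the methylation panel detects
#' that cytology misses.
#'
#' @param cohort cohort data.frame with a cytology column ("+"/"-"/NA).
#' @param markers marker call column names.
#' @param cytology name of the cytology column.
#' @return A \linkS4class{PanelResult}; with no cytology-negative rows the
#'   denominator is 0 and the result is flagged.
#' @examples
#' cohort <- data.frame(cytology = c("-", "-", "+"),
#'                      CCND2 = c("+", "-", "-"))
#' cytologyRescue(cohort, "CCND2")   # 1/2
#' @export
cytologyRescue <- function(cohort, markers, cytology = "cytology") {
  neg <- which(!is.na(cohort[[cytology]]) & cohort[[cytology]] == "-")
  if (!length(neg))
    return(.panelResult("cytology-negative rescue", 0L, 0L))
  panel <- combinePanel(cohort[neg, markers, drop = FALSE])
  .panelResult("cytology-negative rescue",
               sum(panel, na.rm = TRUE), sum(!is.na(panel)))
}

#' Diagnostic metrics of binary calls against a truth standard
#'
#' Sensitivity, specificity, positive and negative predictive value with
#' explicit numerators and denominators. A rate whose denominator is empty
#' (e.g. specificity without any true negative) is reported as \code{NA},
#' never as 0. Pairs with a missing call or missing truth are excluded.
#'
#' @param calls logical (or "+"/"-"/NA) test calls.
#' @param truth logical (or "+"/"-"/NA) truth labels.
#' @return data.frame with one row per metric: \code{metric},
#'   \code{numerator}, \code{denominator}, \code{estimate}.
#' @examples
#' diagnosticMetrics(c(TRUE, TRUE, FALSE, FALSE),
#'                   c(TRUE, FALSE, TRUE, FALSE))
#' @export
diagnosticMetrics <- function(calls, truth) {
  calls <- .plusToLogical(calls)
  truth <- .plusToLogical(truth)
  keep <- !is.na(calls) & !is.na(truth)
  calls <- calls[keep]
  truth <- truth[keep]
  rate <- function(metric, num, den)
    data.frame(metric = metric, numerator = num, denominator = den,
               estimate = if (den > 0) num / den else NA_real_,
               stringsAsFactors = FALSE)
  rbind(
    rate("sensitivity", sum(calls & truth), sum(truth)),
    rate("specificity", sum(!calls & !truth), sum(!truth)),
    rate("ppv", sum(calls & truth), sum(calls)),
    rate("npv", sum(!calls & !truth), sum(!calls))
  )
}

#' Panel report for a cohort: counts, rates and strata
#'
#' Computes the any-positive panel call for every patient and summarizes:
#' overall positivity, panel sensitivity (the cohort is taken as confirmed
#' cases), and the cytology-negative rescue when a cytology column is
#' present.
#'
#' @param cohort cohort data.frame.
#' @param markers marker call column names.
#' @param cytology name of the cytology column, or NULL if absent.
#' @return list with \code{panel} (per-patient logical calls),
#'   \code{sensitivity} and \code{rescue}
#'   (\linkS4class{PanelResult} objects; \code{rescue} NULL without
#'   cytology).
#' @export
panelReport <- function(cohort, markers, cytology = "cytology") {
  panel <- combinePanel(cohort[, markers, drop = FALSE])
  res <- list(panel = panel,
              sensitivity = panelSensitivity(cohort, markers),
              rescue = NULL)
  if (!is.null(cytology) && cytology %in% names(cohort))
    res$rescue <- cytologyRescue(cohort, markers, cytology)
  res
}
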