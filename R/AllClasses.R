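#' @import methods
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Marker specification for the cohort simulator
#'
#' Describes one methylation marker: the probability that a sample from each
#' group is truly methylated, and the distribution of the continuous
#' gene/reference x 1000 methylation score among truly methylated samples.
#' Scores of methylated samples are drawn from a log-normal distribution on
#' the x 1000 scale (QMSP scatter plots span several orders of magnitude, so
#' a heavy-tailed positive distribution is the natural model); truly
#' unmethylated samples sit at \code{backgroundRatio}, which defaults to
#' exactly 0 (no amplification of the methylation-specific amplicon).
#'
#' @slot name gene symbol.
#' @slot prevalenceCase,prevalenceControl probability that a case (resp.
#'   control) sample is truly methylated.
#' @slot ratioMeanlog,ratioSdlog log-normal parameters of the methylated
#'   score distribution (x 1000 scale).
#' @slot backgroundRatio score of truly unmethylated samples (default 0;
#'   small positive values model assay leakage).
#' @exportClass MarkerSpec
setClass("MarkerSpec",
  slots = c(
    name = "character",
    prevalenceCase = "numeric",
    prevalenceControl = "numeric",
    ratioMeanlog = "numeric",
    ratioSdlog = "numeric",
    backgroundRatio = "numeric"
  )
)

setValidity("MarkerSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty gene symbol")
  for (p in c("prevalenceCase", "prevalenceControl")) {
    v <- slot(object, p)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", p))
  }
  if (length(object@ratioSdlog) != 1L || is.na(object@ratioSdlog) ||
      object@ratioSdlog < 0)
    msg <- c(msg, "'ratioSdlog' must be >= 0")
  if (length(object@backgroundRatio) != 1L || is.na(object@backgroundRatio) ||
      object@backgroundRatio < 0)
    msg <- c(msg, "'backgroundRatio' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param name gene symbol.
#' @param prevalenceCase,prevalenceControl true methylation probabilities.
#' @param ratioMeanlog,ratioSdlog log-normal parameters of the methylated
#'   score distribution.
#' @param backgroundRatio score assigned to truly unmethylated samples.
#' @return A \linkS4class{MarkerSpec}.
#' @examples
#' markerSpec("CCND2", prevalenceCase = 0.256, prevalenceControl = 0)
#' @rdname MarkerSpec-class
#' @export
markerSpec <- function(name, prevalenceCase, prevalenceControl,
                       ratioMeanlog = log(100), ratioSdlog = 1.5,
                       backgroundRatio = 0) {
  new("MarkerSpec", name = as.character(name),
      prevalenceCase = as.numeric(prevalenceCase),
      prevalenceControl = as.numeric(prevalenceControl),
      ratioMeanlog = as.numeric(ratioMeanlog),
      ratioSdlog = as.numeric(ratioSdlog),
      backgroundRatio = as.numeric(backgroundRatio))
}

#' Simulation configuration for synthetic QMSP plates and cohorts
#'
#' Holds every parameter of the synthetic-data generator: cohort sizes,
#' marker specifications, the log-linear calibration model
#' (Ct = intercept + slope * log10(ng)), replicate Ct noise, the detection
#' limit of the cycling program, the standard dilution series, cytology
#' operating characteristics and per-marker missingness.
#'
#' Defaults emulate the urine marker study the package is built around:
#' 148 cases vs 56 controls; markers CCND2/CCNA1/CALCA with case
#' (control) methylation prevalences 0.256 (0), 0.684 (0.166) and
#' 0.635 (0.285); a 10-fold dilution series 90..0.009 ng; a
#' perfect-efficiency slope of -3.3219 cycles per log10(ng); a 50-cycle
#' program; cytology sensitivity 0.5 and specificity 0.95.
#'
#' @slot seed integer master seed; every stream of randomness is derived
#'   deterministically from it.
#' @slot nCases,nControls cohort sizes.
#' @slot markers list of \linkS4class{MarkerSpec}.
#' @slot ctNoiseSd replicate-to-replicate Ct standard deviation (cycles).
#' @slot curveSlope,curveIntercept calibration line; slope must be negative
#'   (more template, earlier Ct), intercept is the Ct at 1 ng.
#' @slot maxCycles cycling-program length; predicted Ct beyond it is
#'   reported as undetermined.
#' @slot dilutionSeries standard quantities in ng, strictly decreasing.
#' @slot cytologySensitivity,cytologySpecificity cytology operating point.
#' @slot missingRate probability that a marker measurement is missing for a
#'   patient.
#' @slot sampleInputMeanlog,sampleInputSdlog log-normal parameters of the
#'   per-sample reference-gene input amount (ng).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    seed = "integer",
    nCases = "integer",
    nControls = "integer",
    markers = "list",
    ctNoiseSd = "numeric",
    curveSlope = "numeric",
    curveIntercept = "numeric",
    maxCycles = "numeric",
    dilutionSeries = "numeric",
    cytologySensitivity = "numeric",
    cytologySpecificity = "numeric",
    missingRate = "numeric",
    sampleInputMeanlog = "numeric",
    sampleInputSdlog = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nCases < 0L || object@nControls < 0L)
    msg <- c(msg, "'nCases' and 'nControls' must be >= 0")
  if (!length(object@markers) ||
      !all(vapply(object@markers, is, logical(1), "MarkerSpec")))
    msg <- c(msg, "'markers' must be a non-empty list of MarkerSpec")
  if (object@ctNoiseSd < 0)
    msg <- c(msg, "'ctNoiseSd' must be >= 0")
  if (!is.na(object@curveSlope) && object@curveSlope >= 0)
    msg <- c(msg, "'curveSlope' must be negative")
  if (!length(object@dilutionSeries) || any(object@dilutionSeries <= 0))
    msg <- c(msg, "all dilution quantities must be > 0")
  if (length(object@dilutionSeries) > 1L &&
      any(diff(object@dilutionSeries) >= 0))
    msg <- c(msg, "'dilutionSeries' must be strictly decreasing")
  for (p in c("cytologySensitivity", "cytologySpecificity", "missingRate")) {
    v <- slot(object, p)
    if (is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("'%s' must be a probability in [0, 1]", p))
  }
  if (object@maxCycles <= 0)
    msg <- c(msg, "'maxCycles' must be positive")
  if (length(msg)) msg else TRUE
})

#' @param seed integer master seed.
#' @param nCases,nControls cohort sizes.
#' @param markers list of \linkS4class{MarkerSpec} objects.
#' @param ctNoiseSd Ct replicate noise SD in cycles.
#' @param curveSlope,curveIntercept calibration line parameters.
#' @param maxCycles detection limit of the cycling program.
#' @param dilutionSeries standard quantities (ng), strictly decreasing.
#' @param cytologySensitivity,cytologySpecificity cytology operating point.
#' @param missingRate per-marker, per-patient missingness probability.
#' @param sampleInputMeanlog,sampleInputSdlog reference input distribution.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nCases = 20, nControls = 20)
#' cfg
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(seed = 1L,
                             nCases = 148L,
                             nControls = 56L,
                             markers = defaultMarkerPanel(),
                             ctNoiseSd = 0.25,
                             curveSlope = -3.3219,
                             curveIntercept = 26,
                             maxCycles = 50,
                             dilutionSeries = c(90, 9, 0.9, 0.09, 0.009),
                             cytologySensitivity = 0.5,
                             cytologySpecificity = 0.95,
                             missingRate = 0.1,
                             sampleInputMeanlog = log(5),
                             sampleInputSdlog = 0.5) {
  new("SimulationConfig",
      seed = as.integer(seed), nCases = as.integer(nCases),
      nControls = as.integer(nControls), markers = markers,
      ctNoiseSd = as.numeric(ctNoiseSd),
      curveSlope = as.numeric(curveSlope),
      curveIntercept = as.numeric(curveIntercept),
      maxCycles = as.numeric(maxCycles),
      dilutionSeries = as.numeric(dilutionSeries),
      cytologySensitivity = as.numeric(cytologySensitivity),
      cytologySpecificity = as.numeric(cytologySpecificity),
      missingRate = as.numeric(missingRate),
      sampleInputMeanlog = as.numeric(sampleInputMeanlog),
      sampleInputSdlog = as.numeric(sampleInputSdlog))
}

#' Default three-marker urine panel
#'
#' CCND2, CCNA1 and CALCA with the case/control methylation prevalences
#' observed in urine (25.6\% vs 0\%, 68.4\% vs 16.6\%, 63.5\% vs 28.5\%).
#'
#' @return list of \linkS4class{MarkerSpec}.
#' @export
defaultMarkerPanel <- function() {
  list(
    markerSpec("CCND2", prevalenceCase = 0.256, prevalenceControl = 0),
    markerSpec("CCNA1", prevalenceCase = 0.684, prevalenceControl = 0.166),
    markerSpec("CALCA", prevalenceCase = 0.635, prevalenceControl = 0.285)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  seed:", object@seed, " cases:", object@nCases,
      " controls:", object@nControls, "\n")
  cat("  markers:", paste(vapply(object@markers, slot, "", "name"),
                          collapse = ", "), "\n")
  cat("  curve: Ct =", object@curveIntercept, "+",
      object@curveSlope, "* log10(ng), noise SD", object@ctNoiseSd,
      ", limit", object@maxCycles, "cycles\n")
  cat("  dilutions (ng):", paste(object@dilutionSeries, collapse = ", "),
      "\n")
  cat("  cytology sens/spec:", object@cytologySensitivity, "/",
      object@cytologySpecificity, "; missing rate:", object@missingRate,
      "\n")
})

## ---------------------------------------------------------------------------
## Standard curve
## ---------------------------------------------------------------------------

#' Per-gene, per-plate calibration curve
#'
#' Ordinary least-squares fit of Ct against log10(input ng) over a serial
#' dilution of in vitro methylated DNA. A fit with fewer than two usable
#' standard points, or a non-negative slope (inverted data), is flagged
#' failed rather than returned silently.
#'
#' @slot gene gene symbol.
#' @slot slope cycles per log10(ng); negative for a valid assay.
#' @slot intercept Ct at 1 ng.
#' @slot rSquared coefficient of determination of the fit.
#' @slot nPoints number of standard wells used.
#' @slot valid logical; FALSE for a failed calibration.
#' @slot reason explanation when invalid.
#' @exportClass StandardCurve
setClass("StandardCurve",
  slots = c(gene = "character", slope = "numeric", intercept = "numeric",
            rSquared = "numeric", nPoints = "integer",
            valid = "logical", reason = "character")
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (isTRUE(object@valid)) {
    if (is.na(object@slope) || object@slope >= 0)
      msg <- c(msg, "a valid curve must have a negative slope")
    if (object@nPoints < 2L)
      msg <- c(msg, "a valid curve needs at least 2 points")
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
      msg <- c(msg, "'rSquared' must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "StandardCurve", function(object) {
  if (object@valid) {
    cat(sprintf(
      "StandardCurve [%s]: Ct = %.4f %+.4f * log10(ng)  (r2 = %.4f, n = %d)\n",
      object@gene, object@intercept, object@slope, object@rSquared,
      object@nPoints))
  } else {
    cat(sprintf("StandardCurve [%s]: FAILED (%s)\n", object@gene,
                object@reason))
  }
})

## ---------------------------------------------------------------------------
## ROC curve and cutoff
## ---------------------------------------------------------------------------

#' Empiric ROC curve over observed methylation scores
#'
#' Candidate cutoffs are the distinct observed scores plus one sentinel
#' outside their range; at each candidate a sample is called positive when
#' its score is strictly beyond the cutoff in the positive direction.
#'
#' @slot gene gene symbol (may be empty).
#' @slot points data.frame with columns cutoff, sensitivity, specificity.
#' @slot direction "greater" (positive when score > cutoff) or "less".
#' @slot nPos,nNeg class sizes.
#' @exportClass RocCurve
setClass("RocCurve",
  slots = c(gene = "character", points = "data.frame",
            direction = "character", nPos = "integer", nNeg = "integer")
)

setValidity("RocCurve", function(object) {
  msg <- character()
  if (!object@direction %in% c("greater", "less"))
    msg <- c(msg, "'direction' must be \"greater\" or \"less\"")
  p <- object@points
  if (!all(c("cutoff", "sensitivity", "specificity") %in% names(p)))
    msg <- c(msg, "'points' needs cutoff, sensitivity, specificity columns")
  else if (nrow(p)) {
    if (any(p$sensitivity < 0 | p$sensitivity > 1) ||
        any(p$specificity < 0 | p$specificity > 1))
      msg <- c(msg, "sensitivities and specificities must lie in [0, 1]")
  }
  if (object@nPos < 1L || object@nNeg < 1L)
    msg <- c(msg, "both classes must be non-empty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf(
    "RocCurve%s: %d candidate cutoffs, direction \"%s\", %d pos / %d neg\n",
    if (nzchar(object@gene)) sprintf(" [%s]", object@gene) else "",
    nrow(object@points), object@direction, object@nPos, object@nNeg))
})

#' Empiric cutoff maximizing Youden J
#'
#' The cutoff retained for a gene: the candidate maximizing
#' J = sensitivity + specificity - 1, with ties broken by higher
#' specificity then by lower cutoff value.
#'
#' @slot gene gene symbol.
#' @slot value cutoff on the x 1000 score scale.
#' @slot direction "greater" or "less".
#' @slot youden J at the cutoff.
#' @slot sensitivity,specificity operating point at the cutoff.
#' @exportClass MarkerCutoff
setClass("MarkerCutoff",
  slots = c(gene = "character", value = "numeric", direction = "character",
            youden = "numeric", sensitivity = "numeric",
            specificity = "numeric")
)

setValidity("MarkerCutoff", function(object) {
  msg <- character()
  if (!object@direction %in% c("greater", "less"))
    msg <- c(msg, "'direction' must be \"greater\" or \"less\"")
  if (is.na(object@youden) || object@youden < -1 - 1e-12 ||
      object@youden > 1 + 1e-12)
    msg <- c(msg, "'youden' must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkerCutoff", function(object) {
  cat(sprintf(
    "MarkerCutoff [%s]: positive when score %s %.6g  (J = %.3f, sens = %.3f, spec = %.3f)\n",
    object@gene, if (object@direction == "greater") ">" else "<",
    object@value, object@youden, object@sensitivity, object@specificity))
})

## ---------------------------------------------------------------------------
## 2x2 contingency table
## ---------------------------------------------------------------------------

#' 2x2 cross-tabulation of marker status against a binary group
#'
#' Rows are the two groups, columns methylated/unmethylated. Cell layout:
#' a, b = first group methylated/unmethylated; c, d = second group.
#'
#' @slot counts 2x2 integer matrix with dimnames.
#' @exportClass ContingencyTable2x2
setClass("ContingencyTable2x2", slots = c(counts = "matrix"))

setValidity("ContingencyTable2x2", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m) || !identical(dim(m), c(2L, 2L)))
    msg <- c(msg, "'counts' must be a 2x2 numeric matrix")
  else {
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be non-negative integers")
    if (sum(m) < 1)
      msg <- c(msg, "the table must contain at least one observation")
  }
  if (length(msg)) msg else TRUE
})

#' @param a,b,c,d cell counts: first row (a methylated, b unmethylated),
#'   second row (c, d).
#' @param rowLabels,colLabels dimension labels.
#' @return A \linkS4class{ContingencyTable2x2}.
#' @examples
#' contingency2x2(10, 9, 2, 15,
#'                rowLabels = c("recurrent", "non-recurrent"))
#' @rdname ContingencyTable2x2-class
#' @export
contingency2x2 <- function(a, b, c, d,
                           rowLabels = c("group1", "group2"),
                           colLabels = c("methylated", "unmethylated")) {
  m <- matrix(as.integer(round(c(a, b, c, d))), nrow = 2, byrow = TRUE,
              dimnames = list(rowLabels, colLabels))
  new("ContingencyTable2x2", counts = m)
}

setMethod("show", "ContingencyTable2x2", function(object) {
  cat("ContingencyTable2x2 (N =", sum(object@counts), ")\n")
  print(object@counts)
})

## ---------------------------------------------------------------------------
## Panel result
## ---------------------------------------------------------------------------

#' Result of an any-positive panel evaluation
#'
#' @slot label what was evaluated (e.g. "panel sensitivity").
#' @slot numerator,denominator integer counts behind the estimate.
#' @slot proportion numerator/denominator (NA when the denominator is 0).
#' @slot flagged TRUE when the estimate is undefined (empty denominator).
#' @exportClass PanelResult
setClass("PanelResult",
  slots = c(label = "character", numerator = "integer",
            denominator = "integer", proportion = "numeric",
            flagged = "logical")
)

setValidity("PanelResult", function(object) {
  msg <- character()
  if (object@numerator < 0L || object@denominator < 0L ||
      object@numerator > object@denominator)
    msg <- c(msg, "need 0 <= numerator <= denominator")
  if (!is.na(object@proportion) &&
      (object@proportion < 0 || object@proportion > 1))
    msg <- c(msg, "'proportion' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

.panelResult <- function(label, numerator, denominator) {
  new("PanelResult", label = label, numerator = as.integer(numerator),
      denominator = as.integer(denominator),
      proportion = if (denominator > 0) numerator / denominator else
        NA_real_,
      flagged = denominator == 0L)
}

setMethod("show", "PanelResult", function(object) {
  if (object@flagged) {
    cat(sprintf("PanelResult [%s]: undefined (0 evaluable)\n", object@label))
  } else {
    cat(sprintf("PanelResult [%s]: %d/%d = %.1f%%\n", object@label,
                object@numerator, object@denominator,
                100 * object@proportion))
  }
})
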