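#' Accessors for qmspanel value objects
#'
#' Small read-only accessors so downstream code never touches slots
#' directly.
#'
#' @param object a qmspanel S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveSlope", function(object) standardGeneric("curveSlope"))
#' @rdname accessors
#' @export
setGeneric("curveIntercept",
           function(object) standardGeneric("curveIntercept"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(object) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setGeneric("failureReason", function(object) standardGeneric("failureReason"))
#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setGeneric("positiveDirection",
           function(object) standardGeneric("positiveDirection"))
#' @rdname accessors
#' @export
setGeneric("cutoffValue", function(object) standardGeneric("cutoffValue"))
#' @rdname accessors
#' @export
setGeneric("youdenJ", function(object) standardGeneric("youdenJ"))
#' @rdname accessors
#' @export
setGeneric("tableCounts", function(object) standardGeneric("tableCounts"))
#' @rdname accessors
#' @export
setGeneric("markerName", function(object) standardGeneric("markerName"))

#' @rdname accessors
#' @export
setMethod("curveSlope", "StandardCurve", function(object) object@slope)
#' @rdname accessors
#' @export
setMethod("curveIntercept", "StandardCurve",
          function(object) object@intercept)
#' @rdname accessors
#' @export
setMethod("rSquared", "StandardCurve", function(object) object@rSquared)
#' @rdname accessors
#' @export
setMethod("isValid", "StandardCurve", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("failureReason", "StandardCurve", function(object) object@reason)
#' @rdname accessors
#' @export
setMethod("markerName", "StandardCurve", function(object) object@gene)

#' @rdname accessors
#' @export
setMethod("rocPoints", "RocCurve", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("positiveDirection", "RocCurve", function(object) object@direction)
#' @rdname accessors
#' @export
setMethod("markerName", "RocCurve", function(object) object@gene)

#' @rdname accessors
#' @export
setMethod("cutoffValue", "MarkerCutoff", function(object) object@value)
#' @rdname accessors
#' @export
setMethod("youdenJ", "MarkerCutoff", function(object) object@youden)
#' @rdname accessors
#' @export
setMethod("positiveDirection", "MarkerCutoff",
          function(object) object@direction)
#' @rdname accessors
#' @export
setMethod("markerName", "MarkerCutoff", function(object) object@gene)

#' @rdname accessors
#' @export
setMethod("tableCounts", "ContingencyTable2x2", function(object)
  object@counts)

#' @rdname accessors
#' @export
setGeneric("panelNumerator",
           function(object) standardGeneric("panelNumerator"))
#' @rdname accessors
#' @export
setGeneric("panelDenominator",
           function(object) standardGeneric("panelDenominator"))
#' @rdname accessors
#' @export
setGeneric("panelProportion",
           function(object) standardGeneric("panelProportion"))

#' @rdname accessors
#' @export
setMethod("panelNumerator", "PanelResult", function(object)
  object@numerator)
#' @rdname accessors
#' @export
setMethod("panelDenominator", "PanelResult", function(object)
  object@denominator)
#' @rdname accessors
#' @export
setMethod("panelProportion", "PanelResult", function(object)
  object@proportion)
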