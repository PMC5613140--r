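#' @name accessors
#' @title Accessors for segcoex classes
#' @description Accessor generics for the core classes. Use these rather
#'   than reaching into slots.
#' @param x an object of the documented class.
#' @param ... further arguments for methods.
NULL

#' @describeIn accessors intensity matrix of an [ExpressionData-class].
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @describeIn accessors declared scale, \code{"linear"} or \code{"log2"}.
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @describeIn accessors ids of background/random probes.
#' @export
setGeneric("backgroundIds", function(x) standardGeneric("backgroundIds"))

#' @describeIn accessors element (row/feature) identifiers.
#' @export
setGeneric("elementIds", function(x) standardGeneric("elementIds"))

#' @describeIn accessors sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @describeIn accessors condition label per sample of a
#'   [SampleDesign-class] (named by sample).
#' @export
setGeneric("conditionOf", function(x, ...) standardGeneric("conditionOf"))

#' @describeIn accessors distinct condition labels.
#' @export
setGeneric("conditionLevels", function(x) standardGeneric("conditionLevels"))

#' @describeIn accessors reference condition of a [SampleDesign-class].
#' @export
setGeneric("referenceCondition",
           function(x) standardGeneric("referenceCondition"))

#' @describeIn accessors element table of a [GenomeLayout-class].
#' @export
setGeneric("layoutElements", function(x) standardGeneric("layoutElements"))

#' @describeIn accessors circular topology flag.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @describeIn accessors edge table of a [CoexpressionNetwork-class].
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @describeIn accessors node ids of a [CoexpressionNetwork-class].
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @describeIn accessors segment table of a [GTSegmentSet-class].
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @describeIn accessors result table of a [DEResult-class].
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @describeIn accessors planted operons of a [SyntheticTruth-class].
#' @export
setGeneric("trueOperons", function(x) standardGeneric("trueOperons"))
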