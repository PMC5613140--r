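#' Construct an ExpressionData object
#'
#' @param values numeric matrix, elements x samples, with row and column
#'   names. Must be complete and finite.
#' @param scale declared scale of the intensities, \code{"linear"} or
#'   \code{"log2"}.
#' @param background character vector of element ids flagged as
#'   background/random probes (must be a subset of the row names).
#' @return an [ExpressionData-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' ExpressionData(m, scale = "log2")
#' @export
ExpressionData <- function(values, scale = c("log2", "linear"),
                           background = character()) {
  scale <- match.arg(scale)
  if (!is.matrix(values))
    values <- as.matrix(values)
  storage.mode(values) <- "double"
  bad <- setdiff(background, rownames(values))
  if (length(bad))
    stop("background ids not in element ids: ", paste(bad, collapse = ", "))
  rd <- S4Vectors::DataFrame(
    background = rownames(values) %in% background,
    row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values), rowData = rd)
  new("ExpressionData", se, scale = scale)
}

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionData", function(x)
  SummarizedExperiment::assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("exprScale", "ExpressionData", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("backgroundIds", "ExpressionData", function(x)
  rownames(x)[SummarizedExperiment::rowData(x)$background])

#' @rdname accessors
#' @export
setMethod("elementIds", "ExpressionData", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionData", function(x) colnames(x))

setMethod("show", "ExpressionData", function(object) {
  cat("ExpressionData:", nrow(object), "elements x", ncol(object),
      "samples\n")
  cat("  scale:", object@scale,
      "| background probes:", length(backgroundIds(object)), "\n")
})

## replace the intensity matrix, keeping ids and background flags
setExprValues <- function(x, values, scale = exprScale(x)) {
  stopifnot(identical(dim(values), dim(exprValues(x))))
  dimnames(values) <- dimnames(exprValues(x))
  ExpressionData(values, scale = scale, background = backgroundIds(x))
}

#' Construct a SampleDesign
#'
#' @param samples character vector of sample ids.
#' @param condition character vector (same length) of condition labels.
#' @param reference the reference condition label.
#' @return a [SampleDesign-class] object.
#' @examples
#' SampleDesign(paste0("s", 1:6), rep(c("glucose", "alginate"), each = 3),
#'              reference = "glucose")
#' @export
SampleDesign <- function(samples, condition, reference) {
  new("SampleDesign", samples = as.character(samples),
      condition = as.character(condition),
      reference = as.character(reference))
}

#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleDesign", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("conditionOf", "SampleDesign", function(x, ...)
  stats::setNames(x@condition, x@samples))

#' @rdname accessors
#' @export
setMethod("conditionLevels", "SampleDesign", function(x) unique(x@condition))

#' @rdname accessors
#' @export
setMethod("referenceCondition", "SampleDesign", function(x) x@reference)

setMethod("show", "SampleDesign", function(object) {
  tab <- table(object@condition)
  cat("SampleDesign:", length(object@samples), "samples,",
      length(tab), "conditions (reference:", object@reference, ")\n")
  print(tab)
})

#' Samples belonging to one condition
#'
#' @param design a [SampleDesign-class].
#' @param condition a condition label present in the design.
#' @return character vector of sample ids.
#' @export
samplesFor <- function(design, condition) {
  stopifnot(is(design, "SampleDesign"))
  if (!condition %in% design@condition)
    stop("unknown condition: ", condition)
  design@samples[design@condition == condition]
}

## check that a design covers a matrix; error otherwise
checkDesign <- function(x, design, min_reps = 2L) {
  missing <- setdiff(sampleIds(x), sampleIds(design))
  if (length(missing))
    stop("samples not mapped in design: ", paste(missing, collapse = ", "))
  tab <- table(design@condition[design@samples %in% sampleIds(x)])
  if (min_reps > 0L && any(tab < min_reps))
    stop("every condition needs >= ", min_reps, " samples; offending: ",
         paste(names(tab)[tab < min_reps], collapse = ", "))
  invisible(TRUE)
}
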