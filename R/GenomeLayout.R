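#' Construct a GenomeLayout
#'
#' Elements are sorted by start position (a notice is emitted when the input
#' needed sorting). Coordinates are 1-based inclusive; on a circular layout
#' the final element may wrap across the origin (start > end).
#'
#' @param id character vector of unique element ids.
#' @param start,end integer-like 1-based inclusive coordinates.
#' @param strand character vector, \code{"+"} or \code{"-"}.
#' @param kind character vector, \code{"gene"} or \code{"intergenic"}
#'   (default all genes).
#' @param circular logical(1), chromosome topology (default \code{TRUE}).
#' @param seqname chromosome name used in interval output.
#' @return a [GenomeLayout-class] object.
#' @examples
#' GenomeLayout(paste0("g", 1:3), c(1, 501, 1001), c(400, 900, 1400),
#'              strand = c("+", "+", "-"))
#' @export
GenomeLayout <- function(id, start, end, strand,
                         kind = rep("gene", length(id)),
                         circular = TRUE, seqname = "chr") {
  el <- S4Vectors::DataFrame(id = as.character(id),
                             start = as.integer(start),
                             end = as.integer(end),
                             strand = as.character(strand),
                             kind = as.character(kind))
  if (is.unsorted(el$start)) {
    message("layout elements were not sorted by start; sorting")
    el <- el[order(el$start), , drop = FALSE]
  }
  rownames(el) <- NULL
  new("GenomeLayout", elements = el, circular = as.logical(circular),
      seqname = as.character(seqname))
}

#' @rdname accessors
#' @export
setMethod("layoutElements", "GenomeLayout", function(x) x@elements)

#' @rdname accessors
#' @export
setMethod("elementIds", "GenomeLayout", function(x) x@elements$id)

#' @rdname accessors
#' @export
setMethod("isCircular", "GenomeLayout", function(x) x@circular)

setMethod("length", "GenomeLayout", function(x) nrow(x@elements))

setMethod("show", "GenomeLayout", function(object) {
  el <- object@elements
  cat("GenomeLayout:", nrow(el), "elements (",
      sum(el$kind == "gene"), "genes ) on",
      if (object@circular) "circular" else "linear",
      "sequence", object@seqname, "\n")
})

#' Gene ids of a layout, in genomic order
#' @param layout a [GenomeLayout-class].
#' @return character vector of ids with \code{kind == "gene"}.
#' @export
geneIds <- function(layout) {
  stopifnot(is(layout, "GenomeLayout"))
  el <- layout@elements
  el$id[el$kind == "gene"]
}

#' Coerce a layout to GRanges
#'
#' Wrap-around elements (start > end on a circular layout) cannot be
#' represented and raise an error.
#'
#' @name GenomeLayout-coercion
#' @examples
#' gl <- GenomeLayout(paste0("g", 1:2), c(1, 501), c(400, 900), c("+", "-"))
#' as(gl, "GRanges")
NULL

setAs("GenomeLayout", "GRanges", function(from) {
  el <- from@elements
  if (any(el$start > el$end))
    stop("wrap-around element cannot be represented as GRanges")
  gr <- GenomicRanges::GRanges(
    seqnames = from@seqname,
    ranges = IRanges::IRanges(el$start, el$end),
    strand = el$strand,
    id = el$id, kind = el$kind)
  names(gr) <- el$id
  GenomeInfoDb::isCircular(GenomeInfoDb::seqinfo(gr)) <- from@circular
  gr
})

#' Construct a reference operon list
#'
#' Validates a reference annotation (e.g. a database of sequence-based
#' operon predictions) against a layout: every operon must have at least two
#' elements, all present and contiguous in the layout.
#'
#' @param operons list of character vectors of element ids.
#' @param layout a [GenomeLayout-class] providing the id space and order.
#' @return the validated list, classed \code{"referenceOperons"}.
#' @export
referenceOperons <- function(operons, layout) {
  stopifnot(is(layout, "GenomeLayout"))
  ids <- elementIds(layout)
  L <- length(ids)
  for (i in seq_along(operons)) {
    op <- as.character(operons[[i]])
    if (length(op) < 2L)
      stop("operon ", i, " has fewer than 2 elements")
    pos <- match(op, ids)
    if (anyNA(pos))
      stop("operon ", i, " references unknown id: ",
           paste(op[is.na(pos)], collapse = ", "))
    step <- diff(pos) %% L
    if (!all(step == 1L) && !all(step == L - 1L))
      stop("operon ", i, " is not contiguous in the layout")
    operons[[i]] <- op
  }
  structure(operons, class = "referenceOperons")
}
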