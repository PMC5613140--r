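#' Construct a GTSegmentSet
#'
#' Usually produced by [enumerateSegments()].
#'
#' @param segments a \code{DataFrame} of segment rows (see
#'   [GTSegmentSet-class]).
#' @param layout_ids the ordered element ids that arc indices refer to.
#' @param circular topology used during enumeration.
#' @return a [GTSegmentSet-class] object.
#' @export
GTSegmentSet <- function(segments, layout_ids, circular) {
  new("GTSegmentSet", segments = segments,
      layout_ids = as.character(layout_ids), circular = as.logical(circular))
}

#' @rdname accessors
#' @export
setMethod("segmentTable", "GTSegmentSet", function(x) x@segments)

setMethod("length", "GTSegmentSet", function(x) nrow(x@segments))

setMethod("show", "GTSegmentSet", function(object) {
  sg <- object@segments
  cat("GTSegmentSet:", nrow(sg), "segments over", length(object@layout_ids),
      "elements (", if (object@circular) "circular" else "linear", ")\n")
  if (nrow(sg)) {
    cat("  lengths:", paste(range(sg$length), collapse = "-"),
        "| density:", sprintf("%.2f-%.2f", min(sg$density), max(sg$density)),
        "| mixed-strand:", sum(sg$strand_class == "mixed"), "\n")
  }
})

setMethod("[", "GTSegmentSet", function(x, i, j, ..., drop = FALSE) {
  GTSegmentSet(x@segments[i, , drop = FALSE], x@layout_ids, x@circular)
})

#' Member id sets of the segments
#' @param x a [GTSegmentSet-class].
#' @return list of character vectors.
#' @export
segmentMembers <- function(x) {
  stopifnot(is(x, "GTSegmentSet"))
  as.list(x@segments$members)
}
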