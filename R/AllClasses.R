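#' ExpressionData: elements x samples intensity matrix
#'
#' Thin extension of \code{SummarizedExperiment} holding one assay
#' (\code{"intensity"}) on a declared scale (\code{"linear"} or
#' \code{"log2"}), with a logical \code{background} column in \code{rowData}
#' flagging background/random probes. Values must be finite and complete:
#' platforms supported here produce full matrices, and rank-based statistics
#' with missingness are not defined by this package.
#'
#' @slot scale character(1), \code{"linear"} or \code{"log2"}.
#' @seealso [ExpressionData()], [exprValues()], [backgroundIds()]
#' @exportClass ExpressionData
setClass("ExpressionData",
  contains = "SummarizedExperiment",
  representation(scale = "character"))

setValidity("ExpressionData", function(object) {
  msg <- NULL
  if (length(object@scale) != 1L || !object@scale %in% c("linear", "log2"))
    msg <- c(msg, "scale must be one of 'linear', 'log2'")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  v <- SummarizedExperiment::assay(object, "intensity")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "element (row) and sample (column) identifiers are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated element id: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample id: %s",
                          colnames(object)[duplicated(colnames(object))][1L]))
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "intensities must be numeric, finite and complete (no NA)")
  if (!"background" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'background' is required")
  if (is.null(msg)) TRUE else msg
})

#' SampleDesign: sample-to-condition mapping
#'
#' Maps every sample of an experiment to its growth condition and names the
#' reference condition that differential contrasts are taken against.
#'
#' @slot samples character, sample identifiers (unique).
#' @slot condition character, condition label per sample.
#' @slot reference character(1), the reference condition label.
#' @exportClass SampleDesign
setClass("SampleDesign",
  representation(samples = "character", condition = "character",
                 reference = "character"))

setValidity("SampleDesign", function(object) {
  msg <- NULL
  if (length(object@samples) != length(object@condition))
    msg <- c(msg, "samples and condition must have equal length")
  if (anyDuplicated(object@samples))
    msg <- c(msg, "duplicated sample id in design")
  if (length(object@reference) != 1L ||
      !object@reference %in% object@condition)
    msg <- c(msg, "reference condition must occur among mapped conditions")
  if (is.null(msg)) TRUE else msg
})

#' GenomeLayout: ordered (optionally circular) sequence of genomic elements
#'
#' Holds the gene order of a chromosome: one row per element with 1-based
#' inclusive coordinates, strand, and kind (\code{gene} or
#' \code{intergenic}). Elements are sorted by start; on a circular layout the
#' final element may wrap across the origin (start > end).
#'
#' @slot elements a \code{DataFrame} with columns \code{id}, \code{start},
#'   \code{end}, \code{strand}, \code{kind}.
#' @slot circular logical(1), chromosome topology.
#' @slot seqname character(1), chromosome name used in interval output.
#' @seealso [readGenomeLayout()], [enumerateSegments()]
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(elements = "DataFrame", circular = "logical",
                 seqname = "character"))

setValidity("GenomeLayout", function(object) {
  el <- object@elements
  msg <- NULL
  need <- c("id", "start", "end", "strand", "kind")
  if (!all(need %in% colnames(el)))
    return(paste("elements must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(el$id))
    msg <- c(msg, sprintf("duplicated element id: %s",
                          el$id[duplicated(el$id)][1L]))
  if (!all(el$strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (!all(el$kind %in% c("gene", "intergenic")))
    msg <- c(msg, "kind must be 'gene' or 'intergenic'")
  n <- nrow(el)
  if (n > 1L && is.unsorted(el$start, strictly = TRUE))
    msg <- c(msg, "elements must be strictly increasing by start")
  wrap <- which(el$start > el$end)
  if (length(wrap) &&
      !(isTRUE(object@circular) && identical(wrap, n)))
    msg <- c(msg,
      "start > end allowed only for the final element of a circular layout")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "circular must be TRUE or FALSE")
  if (is.null(msg)) TRUE else msg
})

#' CoexpressionNetwork: thresholded co-expression graph
#'
#' Undirected graph on expressed elements. An edge is retained when the
#' Spearman correlation, its Bonferroni-adjusted p-value and (optionally)
#' the maximal information coefficient all pass their thresholds. Isolated
#' nodes are kept so that the node set equals the tested element set.
#'
#' @slot nodes character, all element ids entered into pair testing.
#' @slot edges a \code{DataFrame} with columns \code{from}, \code{to},
#'   \code{rho}, \code{p_adj}, \code{mic} (\code{NA} when MIC was not used);
#'   canonical orientation \code{from < to}.
#' @slot params list of thresholds and the Bonferroni family size used.
#' @seealso [buildNetwork()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
  representation(nodes = "character", edges = "DataFrame", params = "list"))

setValidity("CoexpressionNetwork", function(object) {
  ed <- object@edges
  msg <- NULL
  need <- c("from", "to", "rho", "p_adj", "mic")
  if (!all(need %in% colnames(ed)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$from >= ed$to))
      msg <- c(msg, "edges must be canonical: from < to")
    if (!all(c(ed$from, ed$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be network nodes")
    if (anyDuplicated(paste(ed$from, ed$to)))
      msg <- c(msg, "duplicated edge")
  }
  if (is.null(msg)) TRUE else msg
})

#' GTSegmentSet: enumerated or dominant genomic-transcriptomic segments
#'
#' A collection of contiguous arcs of a \linkS4class{GenomeLayout}, each
#' valid (its two extremities are connected by a path internal to the arc in
#' the co-expression network), with its reachable set and density.
#'
#' @slot segments a \code{DataFrame}, one row per segment: \code{start}
#'   (index into the layout's element sequence used for enumeration),
#'   \code{length}, \code{first_id}, \code{last_id}, \code{density},
#'   \code{strand_class}, plus \code{CharacterList} columns \code{members}
#'   and \code{reachable}.
#' @slot layout_ids character, the element sequence the arcs index into.
#' @slot circular logical(1), topology used during enumeration.
#' @seealso [enumerateSegments()], [dominantSegments()]
#' @exportClass GTSegmentSet
setClass("GTSegmentSet",
  representation(segments = "DataFrame", layout_ids = "character",
                 circular = "logical"))

setValidity("GTSegmentSet", function(object) {
  sg <- object@segments
  need <- c("start", "length", "first_id", "last_id", "density",
            "strand_class", "members", "reachable")
  if (!all(need %in% colnames(sg)))
    return(paste("segments must have columns:", paste(need, collapse = ", ")))
  if (nrow(sg)) {
    if (any(sg$length < 2L))
      return("every segment must have at least 2 members")
    k <- lengths(sg$members)
    if (any(k != sg$length))
      return("member list length must equal segment length")
    r <- lengths(sg$reachable)
    if (any(abs(sg$density - r / k) > 1e-12))
      return("density must equal |R(S)|/|S|")
    if (any(r == 0L))
      return("segments must have non-empty reachable sets")
  }
  TRUE
})

#' DEResult: differential expression calls per contrast
#'
#' Per-element moderated-t statistics against the reference condition, with
#' Bonferroni family-wise error control and up/down/none calls at the fold
#' change threshold.
#'
#' @slot table a \code{DataFrame} with columns \code{element},
#'   \code{condition}, \code{log2fc}, \code{t_stat}, \code{df_total},
#'   \code{p_raw}, \code{p_adj}, \code{call}.
#' @slot params list: reference condition, fwer, fc_min, prior df and
#'   variance used.
#' @seealso [runDE()], [deSets()]
#' @exportClass DEResult
setClass("DEResult",
  representation(table = "DataFrame", params = "list"))

setValidity("DEResult", function(object) {
  tb <- object@table
  need <- c("element", "condition", "log2fc", "t_stat", "df_total",
            "p_raw", "p_adj", "call")
  if (!all(need %in% colnames(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb) && !all(tb$call %in% c("up", "down", "none")))
    return("call must be 'up', 'down' or 'none'")
  TRUE
})

#' SyntheticTruth: ground truth of a simulated experiment
#'
#' Records the planted structure of a synthetic expression study: operon
#' memberships, singleton and background ids, the per-condition operon mean
#' profiles, and all generator parameters (including the seed), so that
#' detection output can be scored against truth.
#'
#' @slot operons list of character vectors, each an ordered, contiguous,
#'   same-strand block of gene ids.
#' @slot singletons character, independently expressed gene ids.
#' @slot background character, background/random probe ids.
#' @slot profiles numeric matrix of per-condition means (units x conditions).
#' @slot params list of generator parameters, including \code{seed}.
#' @seealso [simulateExperiment()], [recoveryMetrics()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(operons = "list", singletons = "character",
                 background = "character", profiles = "matrix",
                 params = "list"))

setValidity("SyntheticTruth", function(object) {
  ids <- unlist(object@operons)
  if (anyDuplicated(ids)) return("operons must be disjoint")
  if (any(lengths(object@operons) < 2L))
    return("every operon must have at least 2 genes")
  TRUE
})
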