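#' Construct a CoexpressionNetwork
#'
#' Usually produced by [buildNetwork()]; the constructor canonicalizes edge
#' orientation (\code{from < to}) and drops duplicates.
#'
#' @param nodes character vector of element ids (isolated nodes allowed).
#' @param edges data.frame-like with columns \code{from}, \code{to},
#'   \code{rho}, \code{p_adj} and optionally \code{mic}.
#' @param params list of the parameters used to build the network.
#' @return a [CoexpressionNetwork-class] object.
#' @export
CoexpressionNetwork <- function(nodes, edges = NULL, params = list()) {
  nodes <- as.character(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- S4Vectors::DataFrame(from = character(), to = character(),
                                  rho = numeric(), p_adj = numeric(),
                                  mic = numeric())
  } else {
    edges <- S4Vectors::DataFrame(edges)
    if (!"mic" %in% colnames(edges)) edges$mic <- NA_real_
    a <- pmin(as.character(edges$from), as.character(edges$to))
    b <- pmax(as.character(edges$from), as.character(edges$to))
    edges$from <- a
    edges$to <- b
    edges <- edges[!duplicated(paste(a, b)), , drop = FALSE]
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("CoexpressionNetwork", nodes = nodes,
      edges = edges[, c("from", "to", "rho", "p_adj", "mic"), drop = FALSE],
      params = params)
}

#' @rdname accessors
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  p <- object@params
  if (length(p))
    cat("  thresholds: rho >=", p$rho_min, "| p_adj <=", p$p_max,
        if (isTRUE(p$use_mic)) paste("| mic >=", p$mic_min) else "",
        "\n")
})

## adjacency list over an ordered id vector; integer neighbours, by index
adjacencyIndex <- function(network, ids) {
  idx <- seq_along(ids)
  names(idx) <- ids
  adj <- vector("list", length(ids))
  for (i in idx) adj[[i]] <- integer(0)
  ed <- network@edges
  keep <- ed$from %in% ids & ed$to %in% ids
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed)) {
    a <- idx[ed$from]
    b <- idx[ed$to]
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
  }
  adj
}
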