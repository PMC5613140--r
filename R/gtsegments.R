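## Core segment machinery. A segment is a contiguous arc of the (optionally
## circular) element order; it is valid when its two extremities are
## connected by a path of co-expression edges internal to the arc. R(S) is
## the connected component of the arc-induced subgraph containing both
## extremities (the two literal readings -- component of both extremities
## vs genes reachable from the extremities -- coincide for valid segments,
## and that equivalence is tested).

## BFS component containing `from` within member index set; members flagged
## by stamp in `inarc`. Returns integer indices (sorted).
bfsComponent <- function(from, adj, inarc, stamp, visited) {
  comp <- integer(0)
  frontier <- from
  visited[from] <- TRUE
  while (length(frontier)) {
    comp <- c(comp, frontier)
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (inarc[w] == stamp && !visited[w]) {
          visited[w] <- TRUE
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  sort(comp)
}

#' Reachable set of an arc
#'
#' Members of the arc connected to both extremities by paths internal to
#' the arc in the co-expression network: the connected component of the
#' arc-induced subgraph containing the first and last member. Empty when
#' the extremities are not mutually connected (the arc is not a valid
#' segment).
#'
#' @param members character vector (length >= 2) of consecutive element
#'   ids.
#' @param network a [CoexpressionNetwork-class].
#' @return character vector of member ids (possibly empty).
#' @examples
#' nw <- CoexpressionNetwork(paste0("g", 1:5),
#'   data.frame(from = c("g1", "g3"), to = c("g3", "g5"),
#'              rho = 1, p_adj = 0, mic = 1))
#' reachableSet(paste0("g", 1:5), nw)   # g1 g3 g5
#' @export
reachableSet <- function(members, network) {
  stopifnot(is(network, "CoexpressionNetwork"))
  members <- as.character(members)
  if (length(members) < 2L) stop("an arc needs at least 2 members")
  adj <- adjacencyIndex(network, members)
  inarc <- rep(1L, length(members))
  comp <- bfsComponent(1L, adj, inarc, 1L, logical(length(members)))
  if (!(length(members) %in% comp)) return(character(0))
  members[comp]
}

#' Density of a segment
#'
#' The proportion of arc members that behave co-ordinately:
#' |R(S)| / |S|.
#'
#' @param members arc member ids.
#' @param reachable the reachable set R(S) (non-empty).
#' @return density in (0, 1\].
#' @export
segmentDensity <- function(members, reachable) {
  if (!length(reachable)) stop("invalid segment: empty reachable set")
  length(reachable) / length(members)
}

#' Strand classification of a segment
#'
#' \code{"same_direction"} iff all gene members lie on one strand;
#' intergenic members do not vote.
#'
#' @param members arc member ids.
#' @param layout the [GenomeLayout-class].
#' @return \code{"same_direction"} or \code{"mixed"}.
#' @export
classifyStrandedness <- function(members, layout) {
  stopifnot(is(layout, "GenomeLayout"))
  el <- layoutElements(layout)
  pos <- match(members, el$id)
  if (anyNA(pos))
    stop("unknown id: ", paste(members[is.na(pos)], collapse = ", "))
  strands <- el$strand[pos][el$kind[pos] == "gene"]
  if (length(unique(strands)) <= 1L) "same_direction" else "mixed"
}

#' Enumerate all valid segments
#'
#' Scans every contiguous arc of the element order with
#' \code{min_len <= |S| <= max_len} (wrapping across the origin on circular
#' layouts, with arc length additionally capped at one less than the number
#' of elements to avoid the degenerate whole-genome arc) and keeps exactly
#' the arcs whose extremities are connected inside the arc, attaching the
#' reachable set, density and strand class. Output is deterministic,
#' sorted by (start index, length).
#'
#' @param layout a [GenomeLayout-class].
#' @param network a [CoexpressionNetwork-class].
#' @param min_len,max_len segment size bounds (defaults 2 and 50).
#' @param genes_only when \code{TRUE} (default) arcs run over genes only;
#'   otherwise intergenic elements are interleaved and count toward |S|.
#' @return a [GTSegmentSet-class].
#' @export
enumerateSegments <- function(layout, network, min_len = 2L, max_len = 50L,
                              genes_only = TRUE) {
  stopifnot(is(layout, "GenomeLayout"), is(network, "CoexpressionNetwork"))
  if (min_len < 2L) stop("min_len must be >= 2")
  ids <- if (genes_only) geneIds(layout) else elementIds(layout)
  L <- length(ids)
  circ <- isCircular(layout)
  if (L < 2L)
    return(GTSegmentSet(emptySegmentTable(), ids, circ))
  maxk <- min(max_len, if (circ) L - 1L else L)
  adj <- adjacencyIndex(network, ids)

  inarc <- integer(L)
  stamp <- 0L
  starts <- integer(0); lens <- integer(0)
  mem_l <- list(); reach_l <- list(); dens <- numeric(0)

  n_starts <- if (circ) L else L - min_len + 1L
  for (s in seq_len(n_starts)) {
    upper <- if (circ) maxk else min(maxk, L - s + 1L)
    if (upper < min_len) next
    for (k in seq.int(min_len, upper)) {
      mem <- if (circ) ((s - 1L) + 0L:(k - 1L)) %% L + 1L
             else s:(s + k - 1L)
      stamp <- stamp + 1L
      inarc[mem] <- stamp
      comp <- bfsComponent(mem[1L], adj, inarc, stamp, logical(L))
      if (mem[k] %in% comp) {
        starts <- c(starts, s)
        lens <- c(lens, k)
        mem_l[[length(mem_l) + 1L]] <- ids[mem]
        reach_l[[length(reach_l) + 1L]] <- ids[comp]
        dens <- c(dens, length(comp) / k)
      }
    }
  }
  if (!length(starts))
    return(GTSegmentSet(emptySegmentTable(), ids, circ))
  strand_class <- vapply(mem_l, classifyStrandedness, "", layout = layout)
  sg <- S4Vectors::DataFrame(
    start = starts, length = lens,
    first_id = vapply(mem_l, `[`, "", 1L),
    last_id = vapply(mem_l, function(m) m[length(m)], ""),
    density = dens, strand_class = strand_class,
    members = IRanges::CharacterList(mem_l),
    reachable = IRanges::CharacterList(reach_l))
  ord <- order(sg$start, sg$length)
  sg <- sg[ord, , drop = FALSE]
  rownames(sg) <- NULL
  GTSegmentSet(sg, ids, circ)
}

#' Select dominant segments
#'
#' Segment B dominates A when R(A) is a subset of R(B) and
#' density(A) < density(B) (strict). Dominant segments are those dominated
#' by no other candidate. By default candidacy requires density >=
#' \code{density_min} before dominance is evaluated (candidacy first,
#' selection second); \code{apply_density_filter = FALSE} evaluates
#' dominance over all enumerated segments.
#'
#' @param segments a [GTSegmentSet-class] from one enumeration run.
#' @param density_min candidacy threshold (default 0.6).
#' @param apply_density_filter restrict candidates (and output) to
#'   segments with density >= \code{density_min}.
#' @return a [GTSegmentSet-class] of dominant segments, (start, length)
#'   order preserved.
#' @export
dominantSegments <- function(segments, density_min = 0.6,
                             apply_density_filter = TRUE) {
  stopifnot(is(segments, "GTSegmentSet"))
  sg <- segmentTable(segments)
  if (apply_density_filter)
    sg <- sg[sg$density >= density_min, , drop = FALSE]
  nseg <- nrow(sg)
  if (nseg <= 1L)
    return(GTSegmentSet(sg, segments@layout_ids, segments@circular))
  idx <- seq_along(segments@layout_ids)
  names(idx) <- segments@layout_ids
  rs <- lapply(as.list(sg$reachable), function(r) sort(idx[r]))
  sizes <- lengths(rs)
  dens <- sg$density
  ord <- order(dens, decreasing = TRUE)   # potential dominators first
  keep <- rep(TRUE, nseg)
  for (a in seq_len(nseg)) {
    ra <- rs[[a]]
    for (b in ord) {
      if (dens[b] <= dens[a]) break       # no remaining strict dominator
      if (sizes[b] >= sizes[a] && all(ra %in% rs[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  out <- sg[keep, , drop = FALSE]
  rownames(out) <- NULL
  GTSegmentSet(out, segments@layout_ids, segments@circular)
}

#' Collapse overlapping segments into unique regions
#'
#' Overlapping dominant segments are retained by the dominance rule (they
#' often reflect internal promoters); this utility merges segments that
#' share members, transitively, into unique genomic regions.
#'
#' @param segments a [GTSegmentSet-class].
#' @return list of character vectors, each the union of member ids of one
#'   region, ordered by first appearance.
#' @export
collapseRegions <- function(segments) {
  stopifnot(is(segments, "GTSegmentSet"))
  mems <- segmentMembers(segments)
  if (!length(mems)) return(list())
  parent <- seq_along(mems)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  owner <- list()   # element id -> segment root
  for (i in seq_along(mems)) {
    for (id in mems[[i]]) {
      j <- owner[[id]]
      if (is.null(j)) owner[[id]] <- i
      else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(mems), find, integer(1))
  split_ids <- split(seq_along(mems), roots)
  lapply(unname(split_ids), function(g) unique(unlist(mems[g])))
}

#' Compare segments with a reference operon annotation
#'
#' Classifies every segment against a reference (e.g. sequence-based operon
#' predictions) by member id sets: \code{exact} (equal to some operon),
#' \code{contained_in_operon}, \code{contains_operon}, \code{overlap}
#' (shares members without containment), or \code{none}. Each segment is
#' counted once, at the strongest relation it achieves.
#'
#' @param segments a [GTSegmentSet-class].
#' @param reference list of operons (character id vectors), e.g. from
#'   [readReferenceOperons()].
#' @return list with \code{table} (data.frame, one row per segment:
#'   \code{segment}, \code{category}, \code{operon} index or NA) and
#'   \code{summary} (named counts per category).
#' @export
compareToReference <- function(segments, reference) {
  stopifnot(is(segments, "GTSegmentSet"))
  mems <- segmentMembers(segments)
  unknown <- setdiff(unique(unlist(reference)), segments@layout_ids)
  if (length(unknown))
    stop("reference references unknown id: ",
         paste(unknown, collapse = ", "))
  cats <- c("exact", "contained_in_operon", "contains_operon", "overlap",
            "none")
  cat_of <- character(length(mems))
  op_of <- rep(NA_integer_, length(mems))
  for (i in seq_along(mems)) {
    m <- mems[[i]]
    best <- "none"; bi <- NA_integer_
    for (j in seq_along(reference)) {
      o <- reference[[j]]
      inter <- length(intersect(m, o))
      if (!inter) next
      rel <- if (inter == length(m) && inter == length(o)) "exact"
        else if (inter == length(m)) "contained_in_operon"
        else if (inter == length(o)) "contains_operon"
        else "overlap"
      if (match(rel, cats) < match(best, cats)) { best <- rel; bi <- j }
    }
    cat_of[i] <- best; op_of[i] <- bi
  }
  summary <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
  list(table = data.frame(segment = seq_along(mems), category = cat_of,
                          operon = op_of),
       summary = summary)
}
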