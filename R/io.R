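## File formats: plain TSV (tab-separated, UTF-8, '#' comments ignored) for
## matrices, designs, layouts, networks, segments and reference operons;
## GFF3 (via rtracklayer) for genome layouts. Internal coordinates are
## 1-based inclusive; segment interval output is BED-style 0-based
## half-open.

readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids; first column = element id; numeric
#' body. Duplicated ids and non-numeric cells are hard errors.
#'
#' @param path TSV file.
#' @param scale declared scale of the stored intensities.
#' @param background character vector of background probe ids, or a file
#'   with one id per line.
#' @return an [ExpressionData-class].
#' @export
readExpressionMatrix <- function(path, scale = c("log2", "linear"),
                                 background = character()) {
  scale <- match.arg(scale)
  df <- readTsv(path, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression TSV needs an id column and at least one sample column")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated element id: ", dup[1L])
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(ids, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at element '%s', sample '%s'",
                 ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  if (length(background) == 1L && file.exists(background))
    background <- readLines(background)
  background <- background[nzchar(background)]
  ExpressionData(vals, scale = scale, background = background)
}

#' Write an expression matrix to TSV
#'
#' @param x an [ExpressionData-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(is(x, "ExpressionData"))
  df <- data.frame(element = elementIds(x), exprValues(x),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Two columns: \code{sample}, \code{condition}.
#'
#' @param path TSV file.
#' @param reference reference condition label.
#' @return a [SampleDesign-class].
#' @export
readSampleDesign <- function(path, reference) {
  df <- readTsv(path)
  need <- c("sample", "condition")
  if (!all(need %in% colnames(df)))
    stop("design TSV needs columns: ", paste(need, collapse = ", "))
  SampleDesign(df$sample, df$condition, reference)
}

#' Write a sample design to TSV
#' @param design a [SampleDesign-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSampleDesign <- function(design, path) {
  utils::write.table(
    data.frame(sample = sampleIds(design),
               condition = conditionOf(design)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome layout from GFF3 or TSV
#'
#' GFF3 input is parsed with \code{rtracklayer}; features of
#' \code{feature_types} are kept and element ids taken from the first
#' available of the \code{ID}, \code{locus_tag} or \code{Name} attributes.
#' TSV input needs columns \code{id}, \code{start}, \code{end},
#' \code{strand} and optionally \code{kind}. Rows out of order are sorted
#' with a notice.
#'
#' @param path input file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or
#'   \code{"tsv"}.
#' @param circular chromosome topology flag.
#' @param feature_types GFF3 feature types to keep.
#' @param seqname chromosome name (defaults to the file's, for GFF3).
#' @return a [GenomeLayout-class].
#' @export
readGenomeLayout <- function(path, format = c("auto", "gff3", "tsv"),
                             circular = TRUE, feature_types = "gene",
                             seqname = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% feature_types]
    if (!length(gr)) stop("no features of type ",
                          paste(feature_types, collapse = "/"), " in ", path)
    meta <- S4Vectors::mcols(gr)
    id <- NULL
    for (col in c("ID", "locus_tag", "Name"))
      if (is.null(id) && col %in% colnames(meta)) id <- meta[[col]]
    if (is.null(id)) stop("no ID/locus_tag/Name attribute in GFF3")
    if (is.null(seqname))
      seqname <- as.character(GenomeInfoDb::seqnames(gr)[1L])
    GenomeLayout(as.character(id), GenomicRanges::start(gr),
                 GenomicRanges::end(gr),
                 as.character(GenomicRanges::strand(gr)),
                 circular = circular, seqname = seqname)
  } else {
    df <- readTsv(path)
    need <- c("id", "start", "end", "strand")
    if (!all(need %in% colnames(df)))
      stop("layout TSV needs columns: ", paste(need, collapse = ", "))
    kind <- if ("kind" %in% colnames(df)) df$kind
            else rep("gene", nrow(df))
    GenomeLayout(df$id, df$start, df$end, df$strand, kind = kind,
                 circular = circular,
                 seqname = if (is.null(seqname)) "chr" else seqname)
  }
}

#' Write a genome layout to TSV
#' @param layout a [GenomeLayout-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGenomeLayout <- function(layout, path) {
  stopifnot(is(layout, "GenomeLayout"))
  utils::write.table(as.data.frame(layoutElements(layout)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge list to TSV
#'
#' Columns: \code{node_a}, \code{node_b}, \code{rho}, \code{p_adj},
#' \code{mic}. Isolated nodes are preserved in a \code{## nodes:} header
#' comment so the node set round-trips.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "CoexpressionNetwork"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("## nodes: ",
                    paste(networkNodes(network), collapse = ",")), con)
  ed <- as.data.frame(networkEdges(network))
  colnames(ed)[1:2] <- c("node_a", "node_b")
  utils::write.table(format(ed, digits = 17, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list from TSV
#' @param path file written by [writeNetwork()].
#' @return a [CoexpressionNetwork-class].
#' @export
readNetwork <- function(path) {
  first <- readLines(path, n = 1L)
  nodes <- character()
  if (startsWith(first, "## nodes:"))
    nodes <- strsplit(sub("^## nodes: ?", "", first), ",", fixed = TRUE)[[1L]]
  df <- readTsv(path)
  if (nrow(df)) {
    edges <- S4Vectors::DataFrame(
      from = df$node_a, to = df$node_b,
      rho = as.numeric(df$rho), p_adj = as.numeric(df$p_adj),
      mic = suppressWarnings(as.numeric(df$mic)))
  } else edges <- NULL
  nodes <- union(nodes, c(df$node_a, df$node_b))
  CoexpressionNetwork(nodes, edges)
}

## genomic span of an arc given the layout; BED 0-based half-open.
## wrapping arcs report the span from the first member's start to the
## sequence end unknown -> we report start of first member and end of last
## member; for a wrapping arc end < start would result, so the row carries
## the two sub-intervals joined by the wrap flag.
arcSpan <- function(members, layout) {
  el <- layoutElements(layout)
  pos <- match(members, el$id)
  s <- el$start[pos[1L]]
  e <- el$end[pos[length(pos)]]
  c(start = s, end = e)
}

#' Write segments as a BED-like TSV
#'
#' One row per segment: \code{chrom}, 0-based half-open \code{start} /
#' \code{end} of the spanned region, segment \code{name}, \code{density},
#' \code{strand_class}, comma-separated \code{members} and
#' \code{reachable}. Rows are ordered by (start, length). For arcs wrapping
#' the circular origin the interval runs from the first member's start to
#' the last member's end (end < start flags the wrap).
#'
#' @param segments a [GTSegmentSet-class].
#' @param layout the [GenomeLayout-class] the segments refer to.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSegments <- function(segments, layout, path) {
  stopifnot(is(segments, "GTSegmentSet"), is(layout, "GenomeLayout"))
  sg <- segmentTable(segments)
  ids <- elementIds(layout)
  unknown <- setdiff(unique(unlist(as.list(sg$members))), ids)
  if (length(unknown))
    stop("segment references unknown id: ", paste(unknown, collapse = ", "))
  rows <- data.frame(chrom = character(), start = integer(),
                     end = integer(), name = character(),
                     density = numeric(), strand_class = character(),
                     members = character(), reachable = character())
  if (nrow(sg)) {
    span <- t(vapply(as.list(sg$members), arcSpan, numeric(2),
                     layout = layout))
    rows <- data.frame(
      chrom = layout@seqname,
      start = as.integer(span[, "start"]) - 1L,   # 0-based half-open
      end = as.integer(span[, "end"]),
      name = sprintf("GTS_%05d_%02d", sg$start, sg$length),
      density = sg$density,
      strand_class = sg$strand_class,
      members = vapply(as.list(sg$members), paste, "", collapse = ","),
      reachable = vapply(as.list(sg$reachable), paste, "", collapse = ","))
    rows <- rows[order(rows$start, sg$length), , drop = FALSE]
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read segments from a BED-like TSV written by [writeSegments()]
#'
#' @param path input file.
#' @param layout the [GenomeLayout-class] the file refers to.
#' @return a [GTSegmentSet-class].
#' @export
readSegments <- function(path, layout) {
  df <- readTsv(path)
  ids <- elementIds(layout)
  if (!nrow(df))
    return(GTSegmentSet(emptySegmentTable(), ids, isCircular(layout)))
  members <- strsplit(df$members, ",", fixed = TRUE)
  reach <- strsplit(df$reachable, ",", fixed = TRUE)
  unknown <- setdiff(unique(unlist(members)), ids)
  if (length(unknown))
    stop("segment references unknown id: ", paste(unknown, collapse = ", "))
  start <- vapply(members, function(m) match(m[1L], ids), integer(1))
  sg <- S4Vectors::DataFrame(
    start = start,
    length = lengths(members),
    first_id = vapply(members, `[`, "", 1L),
    last_id = vapply(members, function(m) m[length(m)], ""),
    density = df$density,
    strand_class = df$strand_class,
    members = IRanges::CharacterList(members),
    reachable = IRanges::CharacterList(reach))
  sg <- sg[order(sg$start, sg$length), , drop = FALSE]
  rownames(sg) <- NULL
  GTSegmentSet(sg, ids, isCircular(layout))
}

emptySegmentTable <- function() {
  S4Vectors::DataFrame(
    start = integer(), length = integer(), first_id = character(),
    last_id = character(), density = numeric(), strand_class = character(),
    members = IRanges::CharacterList(), reachable = IRanges::CharacterList())
}

#' Read reference operons (one operon per line, comma-separated ids)
#'
#' @param path input file.
#' @param layout the [GenomeLayout-class] giving the id space.
#' @return a validated list of operons (see [referenceOperons()]).
#' @export
readReferenceOperons <- function(path, layout) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  referenceOperons(strsplit(lines, ",", fixed = TRUE), layout)
}

#' Write reference operons (one operon per line, comma-separated ids)
#' @param operons a list of character vectors.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeReferenceOperons <- function(operons, path) {
  writeLines(vapply(operons, paste, "", collapse = ","), path)
  invisible(path)
}
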