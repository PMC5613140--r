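# Fixture generators and independent oracles. The oracles deliberately use
# different code paths (igraph connectivity, combn-based exhaustive MIC,
# naive all-pairs dominance) from the package implementation.

randomLayout <- function(n, circular = TRUE) {
  start <- (seq_len(n) - 1L) * 1000L + 1L
  GenomeLayout(sprintf("g%02d", seq_len(n)), start, start + 899L,
               strand = sample(c("+", "-"), n, replace = TRUE),
               circular = circular)
}

# Erdos-Renyi network on the layout's ids with edge probability p
randomNetwork <- function(ids, p) {
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- if (any(keep))
    data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
               rho = 0.9, p_adj = 1e-12, mic = 0.9)
  else NULL
  CoexpressionNetwork(ids, edges)
}

networkFromPairs <- function(ids, from, to) {
  edges <- if (length(from))
    data.frame(from = from, to = to, rho = 0.9, p_adj = 1e-12, mic = 0.9)
  else NULL
  CoexpressionNetwork(ids, edges)
}

# igraph object over the full node set
asIgraph <- function(network) {
  ed <- as.data.frame(networkEdges(network))
  igraph::graph_from_data_frame(
    ed[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = networkNodes(network)))
}

# Brute-force enumeration: every arc tested with igraph connectivity.
# Returns data.frame (start, length, reachable as comma-joined ids,
# density), sorted by (start, length).
bruteEnumerate <- function(layout, network, min_len = 2L, max_len = 50L) {
  ids <- geneIds(layout)
  L <- length(ids)
  circ <- isCircular(layout)
  g <- asIgraph(network)
  maxk <- min(max_len, if (circ) L - 1L else L)
  rows <- list()
  n_starts <- if (circ) L else L - min_len + 1L
  for (s in seq_len(n_starts)) {
    upper <- if (circ) maxk else min(maxk, L - s + 1L)
    if (upper < min_len) next
    for (k in min_len:upper) {
      mem <- if (circ) ids[((s - 1L) + 0L:(k - 1L)) %% L + 1L]
             else ids[s:(s + k - 1L)]
      sub <- igraph::induced_subgraph(g, mem)
      comp <- igraph::components(sub)
      c1 <- comp$membership[mem[1L]]
      c2 <- comp$membership[mem[k]]
      if (c1 == c2) {
        r <- sort(names(comp$membership)[comp$membership == c1])
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, length = k,
          reachable = paste(r, collapse = ","),
          density = length(r) / k)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), length = integer(),
                      reachable = character(), density = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$length), , drop = FALSE]
}

# Brute-force dominance: naive all-pairs over the candidate rows
bruteDominants <- function(df, density_min = 0.6, filter = TRUE) {
  if (filter) df <- df[df$density >= density_min, , drop = FALSE]
  n <- nrow(df)
  if (n <= 1L) return(df)
  rs <- strsplit(df$reachable, ",", fixed = TRUE)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b && df$density[a] < df$density[b] &&
        all(rs[[a]] %in% rs[[b]])) {
      keep[a] <- FALSE
      break
    }
  }
  df[keep, , drop = FALSE]
}

# canonical (start, length, reachable, density) table from a GTSegmentSet
segsAsTable <- function(segments) {
  sg <- segmentTable(segments)
  data.frame(start = sg$start, length = sg$length,
             reachable = vapply(as.list(sg$reachable),
                                function(r) paste(sort(r), collapse = ","),
                                ""),
             density = sg$density)
}

expect_same_segments <- function(segments, brute) {
  got <- segsAsTable(segments)
  rownames(got) <- rownames(brute) <- NULL
  got <- got[order(got$start, got$length), , drop = FALSE]
  brute <- brute[order(brute$start, brute$length), , drop = FALSE]
  expect_equal(got$start, brute$start)
  expect_equal(got$length, brute$length)
  expect_equal(got$reachable, brute$reachable)
  expect_equal(got$density, brute$density, tolerance = 1e-12)
}

# Exhaustive MIC in pure R (combn over cut placements), tiny n only
bruteMic <- function(x, y, B) {
  n <- length(x)
  xo <- order(x, seq_len(n))
  yo <- order(y, seq_len(n))
  bins <- function(ord, cuts) {
    b <- integer(n)
    b[ord] <- findInterval(seq_len(n) - 1L, cuts) + 1L
    b
  }
  best <- 0
  for (k in 2:floor(B / 2)) for (l in 2:floor(B / k)) {
    if (l < 2) next
    xcuts <- utils::combn(n - 1L, k - 1L, simplify = FALSE)
    ycuts <- utils::combn(n - 1L, l - 1L, simplify = FALSE)
    for (xc in xcuts) for (yc in ycuts) {
      xb <- bins(xo, xc)
      yb <- bins(yo, yc)
      tab <- table(xb, yb) / n
      px <- rowSums(tab); py <- colSums(tab)
      mi <- 0
      for (a in seq_len(nrow(tab))) for (b in seq_len(ncol(tab)))
        if (tab[a, b] > 0)
          mi <- mi + tab[a, b] * log2(tab[a, b] / (px[a] * py[b]))
      best <- max(best, mi / log2(min(k, l)))
    }
  }
  min(best, 1)
}

# small simulated study for tests that need real-ish data quickly
smallSim <- function(seed = 7, ...) {
  simulateExperiment(n_genes = 60L, n_operons = 8L, seed = seed, ...)
}
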