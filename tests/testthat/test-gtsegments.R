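test_that("reachable sets are the component holding both extremities", {
  ids <- paste0("g", 1:5)
  nw <- networkFromPairs(ids, c("g1", "g3"), c("g3", "g5"))
  expect_identical(reachableSet(ids, nw), c("g1", "g3", "g5"))
  expect_equal(segmentDensity(ids, reachableSet(ids, nw)), 0.6)

  # no edge between a 2-arc's members: invalid
  expect_identical(reachableSet(c("g1", "g2"), nw), character(0))
  expect_error(segmentDensity("g1", character(0)), "invalid")

  # clique: everything reachable
  pr <- t(combn(ids, 2))
  cl <- networkFromPairs(ids, pr[, 1], pr[, 2])
  expect_identical(reachableSet(ids, cl), ids)
  expect_equal(segmentDensity(ids, ids), 1)
  expect_error(reachableSet("g1", nw), "at least 2")
})

test_that("both literal readings of the reachable set coincide for valid
           segments", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    ids <- sprintf("g%02d", 1:n)
    nw <- randomNetwork(ids, runif(1, 0.1, 0.5))
    r1 <- reachableSet(ids, nw)
    # oracle: genes reachable from either extremity within the arc
    g <- asIgraph(nw)
    sub <- igraph::induced_subgraph(g, ids)
    from1 <- names(igraph::subcomponent(sub, ids[1]))
    fromN <- names(igraph::subcomponent(sub, ids[n]))
    if (length(r1)) {
      expect_setequal(r1, union(from1, fromN))
      expect_setequal(r1, intersect(from1, fromN))
    } else {
      expect_false(ids[n] %in% from1)
    }
  }
})

test_that("enumeration returns exactly the valid arcs", {
  gl <- randomLayout(6)
  ids <- elementIds(gl)
  nw <- networkFromPairs(ids, ids[1], ids[2])
  segs <- enumerateSegments(gl, nw)
  expect_identical(length(segs), 1L)
  expect_identical(as.list(segmentTable(segs)$members)[[1]], ids[1:2])

  empty <- enumerateSegments(gl, CoexpressionNetwork(ids))
  expect_identical(length(empty), 0L)

  # complete network on a linear 4-gene layout: every arc, all density 1
  gl4 <- randomLayout(4, circular = FALSE)
  ids4 <- elementIds(gl4)
  pairs <- t(combn(ids4, 2))
  nw4 <- networkFromPairs(ids4, pairs[, 1], pairs[, 2])
  segs4 <- enumerateSegments(gl4, nw4)
  expect_identical(length(segs4), 6L)            # 3 + 2 + 1 arcs
  expect_true(all(segmentTable(segs4)$density == 1))
  expect_setequal(segmentTable(segs4)$length, c(2L, 3L, 4L))

  # circular topology caps arcs below the full circle and wraps
  gl4c <- randomLayout(4, circular = TRUE)
  nw4c <- networkFromPairs(ids4, pairs[, 1], pairs[, 2])
  segs4c <- enumerateSegments(gl4c, nw4c)
  expect_identical(length(segs4c), 8L)           # 4 starts x lengths 2,3
  expect_true(any(vapply(segmentMembers(segs4c), function(m)
    m[1] == ids4[4] && m[2] == ids4[1], logical(1))))
})

test_that("enumeration and dominance match brute force on random
           instances", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    gl <- randomLayout(n, circular = sample(c(TRUE, FALSE), 1))
    nw <- randomNetwork(elementIds(gl), runif(1, 0.05, 0.4))
    segs <- enumerateSegments(gl, nw, max_len = 50)
    brute <- bruteEnumerate(gl, nw, max_len = 50)
    expect_same_segments(segs, brute)
    dom <- dominantSegments(segs)
    bdom <- bruteDominants(brute)
    expect_same_segments(dom, bdom)
  }
})

test_that("dominance keeps non-dominated candidates only", {
  # 6-gene circle; A = [g1..g4] clique component, F = wrapping [g4..g1]
  ids <- paste0("g", 1:6)
  gl <- randomLayout(6)
  el <- S4Vectors::DataFrame(layoutElements(gl))
  el$id <- ids
  gl <- new("GenomeLayout", elements = el, circular = TRUE, seqname = "chr")
  nw <- networkFromPairs(ids,
                         c("g1", "g2", "g3", "g1", "g4"),
                         c("g2", "g3", "g4", "g4", "g1"))
  segs <- enumerateSegments(gl, nw)
  tab <- segsAsTable(segs)
  a_row <- which(tab$start == 1 & tab$length == 4)
  f_row <- which(tab$start == 4 & tab$length == 4)   # g4 g5 g6 g1
  expect_identical(tab$density[a_row], 1)
  expect_identical(tab$density[f_row], 0.5)
  dom <- dominantSegments(segs, density_min = 0.5)
  dtab <- segsAsTable(dom)
  expect_true(any(dtab$start == 1 & dtab$length == 4))
  expect_false(any(dtab$start == 4 & dtab$length == 4))

  # disjoint segments never dominate each other
  nw2 <- networkFromPairs(ids, c("g1", "g4"), c("g2", "g5"))
  dom2 <- dominantSegments(enumerateSegments(gl, nw2))
  expect_identical(length(dom2), 2L)

  # equal densities with nested reachable sets: strictness keeps both
  nw3 <- networkFromPairs(ids, c("g1", "g2", "g1"), c("g2", "g3", "g3"))
  segs3 <- enumerateSegments(gl, nw3)
  dom3 <- segsAsTable(dominantSegments(segs3))
  # [g1,g2] has R nested inside [g1..g3]'s but equal density: both stay
  expect_true(any(dom3$start == 1 & dom3$length == 2))
  expect_true(any(dom3$start == 1 & dom3$length == 3))
  expect_identical(nrow(dom3), 3L)
})

test_that("adding edges never invalidates a previously valid arc", {
  set.seed(31)
  gl <- randomLayout(12)
  ids <- elementIds(gl)
  nw_small <- randomNetwork(ids, 0.15)
  extra <- randomNetwork(ids, 0.15)
  both <- CoexpressionNetwork(ids, rbind(networkEdges(nw_small),
                                         networkEdges(extra)))
  s1 <- segsAsTable(enumerateSegments(gl, nw_small))
  s2 <- segsAsTable(enumerateSegments(gl, both))
  expect_true(all(paste(s1$start, s1$length) %in%
                    paste(s2$start, s2$length)))
})

test_that("strand classification votes over gene members only", {
  gl <- GenomeLayout(c("a", "i1", "b", "c"),
                     start = c(1, 500, 700, 1500),
                     end = c(400, 650, 1400, 1900),
                     strand = c("+", "-", "+", "-"),
                     kind = c("gene", "intergenic", "gene", "gene"),
                     circular = FALSE)
  expect_identical(classifyStrandedness(c("a", "i1", "b"), gl),
                   "same_direction")
  expect_identical(classifyStrandedness(c("a", "b", "c"), gl), "mixed")
  expect_error(classifyStrandedness(c("a", "zz"), gl), "unknown")
})

test_that("segments classify against a reference operon annotation", {
  gl <- randomLayout(10)
  ids <- elementIds(gl)
  pairs <- t(combn(ids, 2))
  nw <- networkFromPairs(ids, pairs[, 1], pairs[, 2])   # clique
  ref <- referenceOperons(list(ids[1:3], ids[5:7]), gl)

  segs <- enumerateSegments(gl, nw, max_len = 8)
  tab <- segmentTable(segs)
  pick <- function(s, k) which(tab$start == s & tab$length == k)
  sel <- segs[c(pick(1, 3),    # exact match of operon 1
                pick(1, 2),    # contained in operon 1
                pick(5, 4),    # contains operon 2 (g5..g8)
                pick(2, 5),    # spans operons 1 and 2 -> overlap
                pick(9, 2))]   # disjoint from both -> none
  cmp <- compareToReference(sel, ref)
  expect_identical(cmp$table$category,
                   c("exact", "contained_in_operon", "contains_operon",
                     "overlap", "none"))
  expect_identical(unname(cmp$summary), rep(1L, 5))
})

test_that("overlapping segments collapse into unique regions", {
  gl <- randomLayout(10)
  ids <- elementIds(gl)
  nw <- networkFromPairs(ids, ids[c(1, 2, 5, 9)], ids[c(2, 3, 6, 10)])
  dom <- dominantSegments(enumerateSegments(gl, nw))
  regions <- collapseRegions(dom)
  expect_identical(length(regions), 3L)
  expect_true(any(vapply(regions, setequal, logical(1), y = ids[1:3])))
})
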