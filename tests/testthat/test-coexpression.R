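test_that("Spearman rho is rank-based, symmetric, and guards constants", {
  x <- 1:5
  expect_equal(spearmanRho(x, x^2), 1)          # monotone invariance
  expect_equal(spearmanRho(c(1, 2, 3, 4, 5), c(5, 6, 7, 8, 7)),
               8 / sqrt(95))                    # tie at average rank 3.5
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_identical(spearmanRho(a, b), spearmanRho(b, a))
  expect_message(r <- spearmanRho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
})

test_that("correlation p-values follow the t approximation", {
  expect_equal(rhoPValue(0, 21), 1)
  # n = 21, rho = 0.8: t = 0.8 sqrt(19/0.36)
  tref <- 0.8 * sqrt(19 / (1 - 0.64))
  expect_equal(tref, 5.8119, tolerance = 1e-4)
  expect_equal(rhoPValue(0.8, 21), 2 * pt(-tref, df = 19),
               tolerance = 1e-12)
  expect_lt(abs(rhoPValue(0.8, 21) - 1.3e-5), 2e-6)
  p1 <- rhoPValue(1, 10)
  expect_true(attr(p1, "boundary"))
  expect_gt(p1, 0)
  # decreasing in |rho| at fixed n
  ps <- vapply(seq(0, 0.95, by = 0.05), rhoPValue, 1, n = 12)
  expect_true(all(diff(ps) < 0))
})

test_that("exact MIC matches an independent exhaustive oracle and its
           boundary behaviour", {
  # perfect monotone dependence: maximal at the admissible grids
  expect_gt(micScore(1:21, (1:21)^3), 0.99)
  expect_equal(micScore(rep(5, 10), 1:10), 0)   # constant -> 0
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(micScore(x, y), micScore(y, x), tolerance = 1e-12)

  # independence keeps MIC low at moderate n
  set.seed(8)
  xs <- sample(30); ys <- sample(30)
  expect_lt(micScore(xs, ys), 0.5)

  # oracle equivalence on tiny instances (independent pure-R search)
  set.seed(21)
  for (i in 1:5) {
    n <- sample(8:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    B <- max(4, floor(n^0.6))
    expect_equal(micScore(x, y), bruteMic(x, y, B), tolerance = 1e-10)
  }
})

test_that("network construction applies the three filters and keeps all
           nodes", {
  set.seed(10)
  n <- 21
  base <- rnorm(n, 8, 1.5)
  m <- rbind(
    dup1 = base,
    dup2 = base,                                  # rho = 1 pair
    matrix(rnorm(8 * n, 8, 1.5), 8, n,
           dimnames = list(paste0("r", 1:8), NULL)))
  colnames(m) <- paste0("s", 1:n)
  x <- ExpressionData(m, "log2")
  nw <- buildNetwork(x, p_max = 0.05, use_mic = FALSE)
  ed <- as.data.frame(networkEdges(nw))
  expect_true(any(ed$from == "dup1" & ed$to == "dup2"))
  expect_setequal(networkNodes(nw), rownames(m))

  # pure-noise matrix: the default p <= 1e-9 cut is unreachable at n = 21
  set.seed(11)
  noise <- matrix(rnorm(60 * 21), 60, 21,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:21)))
  nw0 <- buildNetwork(ExpressionData(noise, "log2"), use_mic = FALSE)
  expect_identical(nrow(networkEdges(nw0)), 0L)

  expect_error(buildNetwork(ExpressionData(noise[, 1:3], "log2")),
               "4 samples")
})

test_that("network thresholds act monotonically and constants are skipped", {
  sim <- smallSim()
  x <- sim$expression
  n1 <- buildNetwork(x, rho_min = 0.8, p_max = 1, use_mic = FALSE)
  n2 <- buildNetwork(x, rho_min = 0.9, p_max = 1, use_mic = FALSE)
  key <- function(nw) with(as.data.frame(networkEdges(nw)),
                           paste(from, to))
  expect_true(all(key(n2) %in% key(n1)))
  n3 <- buildNetwork(x, rho_min = 0.8, p_max = 1e-4, use_mic = FALSE)
  expect_true(all(key(n3) %in% key(n1)))
  # MIC confirmation can only remove edges
  n4 <- buildNetwork(x, rho_min = 0.8, p_max = 1, use_mic = TRUE)
  expect_true(all(key(n4) %in% key(n1)))
  expect_true(all(!is.na(networkEdges(n4)$mic)))
  expect_true(all(networkEdges(n4)$mic >= 0.6))

  # a constant element is skipped and excluded from the Bonferroni family
  v <- exprValues(x)[1:10, ]
  v["GENE_0003", ] <- 7
  xc <- ExpressionData(v, "log2")
  expect_message(nc <- buildNetwork(xc, p_max = 1, use_mic = FALSE),
                 "constant")
  expect_identical(nc@params$m_tested, choose(9, 2))
  expect_identical(nc@params$m_family, choose(9, 2))
  nall <- suppressMessages(
    buildNetwork(xc, p_max = 1, use_mic = FALSE, bonferroni = "all"))
  expect_identical(nall@params$m_family, choose(10, 2))
})

test_that("the network is invariant under monotone per-element transforms", {
  sim <- smallSim(seed = 3)
  x <- sim$expression
  v <- exprValues(x)
  vt <- 2^(v / 4) + 1          # strictly monotone transform, all elements
  xt <- ExpressionData(vt, "log2", background = backgroundIds(x))
  a <- buildNetwork(x, rho_min = 0.8, p_max = 1, use_mic = TRUE)
  b <- buildNetwork(xt, rho_min = 0.8, p_max = 1, use_mic = TRUE)
  ea <- as.data.frame(networkEdges(a))
  eb <- as.data.frame(networkEdges(b))
  expect_equal(ea[c("from", "to")], eb[c("from", "to")])
  expect_equal(ea$rho, eb$rho, tolerance = 1e-12)
  expect_equal(ea$mic, eb$mic, tolerance = 1e-10)
})
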