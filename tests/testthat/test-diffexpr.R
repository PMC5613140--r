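mkStudy <- function(n_genes = 50, n1 = 3, n0 = 3, seed = 1, sd = 0.5) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n0), 8, sd), n_genes, n1 + n0,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              c(paste0("t", seq_len(n1)),
                                paste0("c", seq_len(n0)))))
  x <- ExpressionData(m, "log2")
  design <- SampleDesign(colnames(m),
                         rep(c("treat", "ctrl"), c(n1, n0)), "ctrl")
  list(x = x, design = design)
}

test_that("log2 fold changes are group mean differences", {
  st <- mkStudy()
  v <- exprValues(st$x)
  lfc <- log2FoldChange(st$x, st$design, "treat")
  expect_equal(unname(lfc),
               unname(rowMeans(v[, 1:3]) - rowMeans(v[, 4:6])))
  rev <- log2FoldChange(st$x, st$design, "ctrl", reference = "treat")
  expect_equal(unname(rev), -unname(lfc))
  expect_error(log2FoldChange(st$x, st$design, "nope"), "unknown")
  lin <- ExpressionData(2^exprValues(st$x), "linear")
  expect_error(log2FoldChange(lin, st$design, "treat"), "log2")
})

test_that("moderated t reduces to the ordinary pooled t at d0 = 0", {
  st <- mkStudy(seed = 3)
  tb <- moderatedT(st$x, st$design, "treat", d0 = 0)
  v <- exprValues(st$x)
  for (i in c(1, 17, 50)) {
    tt <- t.test(v[i, 1:3], v[i, 4:6], var.equal = TRUE)
    expect_equal(tb$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tb$p_raw[i], tt$p.value, tolerance = 1e-12)
    expect_equal(tb$df_total[i], 4)
  }
})

test_that("shrinkage is a fixed point when all variances are equal", {
  # equal per-gene pooled variances: posterior variance equals the common
  # value, so every finite d0 yields the d0 = 0 statistics
  set.seed(5)
  gene_row <- function(delta) {
    e <- rnorm(6)
    e[1:3] <- e[1:3] - mean(e[1:3])
    e[4:6] <- e[4:6] - mean(e[4:6])
    e <- e / sqrt(sum(e^2) / 4)          # pooled s^2 = 1 exactly
    8 + e + rep(c(delta, 0), each = 3)
  }
  m <- t(vapply(rnorm(30, 0, 2), gene_row, numeric(6)))
  dimnames(m) <- list(sprintf("g%02d", 1:30),
                      c(paste0("t", 1:3), paste0("c", 1:3)))
  x <- ExpressionData(m, "log2")
  design <- SampleDesign(colnames(m), rep(c("treat", "ctrl"), each = 3),
                         "ctrl")
  for (d0 in c(1, 4, 100)) {
    tb <- moderatedT(x, design, "treat", d0 = d0)
    tb0 <- moderatedT(x, design, "treat", d0 = 0)
    expect_equal(tb$t_stat, tb0$t_stat, tolerance = 1e-9)
  }
})

test_that("prior moment-matching agrees with the limma reference and
           recovers known hyperparameters", {
  skip_if_not_installed("limma")
  # observed variances from the hierarchical model:
  # sigma_g^2 ~ scaled-inv-chi2(d0 = 4, s0^2 = 0.05); s_g^2 ~ sig2 X_d^2/d
  set.seed(11)
  d <- 4
  sig2 <- 0.05 * 4 / rchisq(500, df = 4)
  s2 <- sig2 * rchisq(500, df = d) / d
  prior <- segcoex:::estimatePrior(s2, d)
  fd <- limma::fitFDist(s2, df1 = d)
  expect_equal(prior$d0, fd$df2, tolerance = 1e-6)
  expect_equal(prior$s0_2, fd$scale, tolerance = 1e-6)
  expect_lt(abs(prior$d0 - 4) / 4, 0.5)
  expect_lt(abs(prior$s0_2 - 0.05) / 0.05, 0.2)

  # and across independent simulations the recovery stays in band
  errs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    sig2 <- 0.05 * 4 / rchisq(500, df = 4)
    s2 <- sig2 * rchisq(500, df = d) / d
    pr <- segcoex:::estimatePrior(s2, d)
    c(abs(pr$d0 - 4) / 4, abs(pr$s0_2 - 0.05) / 0.05)
  }, numeric(2))
  expect_true(all(errs[1, ] <= 0.5))
  expect_true(all(errs[2, ] <= 0.2))
})

test_that("moderated t matches limma's eBayes pipeline", {
  skip_if_not_installed("limma")
  st <- mkStudy(n_genes = 120, seed = 21, sd = 0.4)
  v <- exprValues(st$x)
  des <- cbind(Intercept = 1, treat = rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(v, des))
  tb <- moderatedT(st$x, st$design, "treat")
  expect_equal(tb$log2fc, unname(fit$coefficients[, "treat"]),
               tolerance = 1e-10)
  expect_equal(tb$t_stat, unname(fit$t[, "treat"]), tolerance = 1e-8)
  expect_equal(tb$p_raw, unname(fit$p.value[, "treat"]),
               tolerance = 1e-8)
  expect_equal(attr(tb, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("moderated-t p-values are uniform under the null at the true
           prior df", {
  set.seed(33)
  n_genes <- 1500
  d0 <- 4; s0 <- sqrt(0.05)
  sig <- sqrt(d0 * s0^2 / rchisq(n_genes, df = d0))
  m <- matrix(rnorm(n_genes * 6, 0, rep(sig, 6)), n_genes, 6,
              dimnames = list(sprintf("g%04d", 1:n_genes),
                              c(paste0("t", 1:3), paste0("c", 1:3))))
  x <- ExpressionData(m + 8, "log2")
  design <- SampleDesign(colnames(m), rep(c("treat", "ctrl"), each = 3),
                         "ctrl")
  tb <- moderatedT(x, design, "treat", d0 = d0, s0_2 = s0^2)
  ks <- ks.test(tb$p_raw, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("DE calls follow the FWER and fold-change rule", {
  st <- mkStudy(n_genes = 40, seed = 8, sd = 0.3)
  v <- exprValues(st$x)
  v["g001", 1:3] <- v["g001", 1:3] + 5    # strong up
  v["g002", 1:3] <- v["g002", 1:3] - 5    # strong down
  x <- ExpressionData(v, "log2")
  de <- runDE(x, st$design)
  tb <- as.data.frame(deTable(de))
  expect_identical(tb$call[tb$element == "g001"], "up")
  expect_identical(tb$call[tb$element == "g002"], "down")
  expect_equal(tb$p_adj, pmin(1, tb$p_raw * 40), tolerance = 1e-12)

  sets <- deSets(de)
  expect_identical(sets$up$treat, "g001")
  expect_identical(sets$down$treat, "g002")
  expect_identical(sets$summary$n_up, 1L)

  # tightening the FWER never enlarges the sets
  tight <- deSets(de, fwer = 1e-6)
  expect_true(all(tight$up$treat %in% sets$up$treat))
  expect_true(all(tight$down$treat %in% sets$down$treat))

  # an element passing p but not fold change stays uncalled
  v["g003", 1:3] <- v["g003", 1:3] + 1.0
  de2 <- runDE(ExpressionData(v, "log2"), st$design, fc_min = 2)
  tb2 <- as.data.frame(deTable(de2))
  expect_identical(tb2$call[tb2$element == "g003"], "none")
})

test_that("percentage of regulated genes reproduces the printed summary
           arithmetic", {
  expect_identical(percentRegulated(47, 308, 4482), 7.92)
  expect_identical(percentRegulated(63, 128, 4482), 4.26)
  expect_identical(percentRegulated(0, 0, 1000), 0)
})
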