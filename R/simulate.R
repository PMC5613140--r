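#' Simulate a multi-condition expression study with planted operons
#'
#' Emulates a replicated carbon-source profiling design on a circular
#' bacterial chromosome: genes organized in co-expressed operon blocks plus
#' independent singletons, 7 conditions x 3 replicates by default,
#' log2-scale intensities, and background/random probe rows. Each operon o
#' draws condition means mu_{o,c} ~ Normal(mu0, tau^2); gene g of o adds a
#' baseline offset b_g ~ Normal(0, baseline_sd^2); the measured value is
#' mu_{o,c(s)} + b_g + eps with eps ~ Normal(0, sigma^2). Singletons draw
#' their own independent condition means. A fraction \code{de_frac} of
#' units receives a +\code{de_shift} bump in one random non-reference
#' condition. Background rows are Normal(mu0 - 3, sigma^2). Fully
#' reproducible from \code{seed} (one stream, deterministic draw order).
#'
#' @param n_genes number of genes on the chromosome (default 300).
#' @param n_operons number of planted operons (default 40).
#' @param size_prob success probability of the truncated geometric operon
#'   size distribution on \[2, 17\] (default 0.45; mean size ~3.1, typical
#'   of bacterial multi-gene operons).
#' @param n_conditions,n_reps design shape (defaults 7 and 3).
#' @param tau between-condition profile SD (default 1.5, log2 units).
#' @param sigma within-replicate noise SD (default 0.3, log2 units).
#' @param baseline_sd per-gene baseline offset SD (default 0.2).
#' @param background_frac background probe rows as a fraction of
#'   \code{n_genes} (default 0.05).
#' @param de_frac fraction of units shifted in one condition (default
#'   0.05).
#' @param de_shift shift size in log2 units (default 3).
#' @param mu0 grand mean log2 intensity (default 8).
#' @param seed integer seed (required for reproducibility).
#' @return list with \code{expression} ([ExpressionData-class], log2
#'   scale), \code{layout} ([GenomeLayout-class]), \code{design}
#'   ([SampleDesign-class]) and \code{truth} ([SyntheticTruth-class]).
#' @examples
#' sim <- simulateExperiment(n_genes = 60, n_operons = 8, seed = 1)
#' sim$expression
#' @export
simulateExperiment <- function(n_genes = 300L, n_operons = 40L,
                               size_prob = 0.45, n_conditions = 7L,
                               n_reps = 3L, tau = 1.5, sigma = 0.3,
                               baseline_sd = 0.2, background_frac = 0.05,
                               de_frac = 0.05, de_shift = 3, mu0 = 8,
                               seed = 1L) {
  stopifnot(n_genes >= 2L, n_operons >= 0L, n_conditions >= 2L,
            n_reps >= 2L, tau > 0, sigma >= 0, size_prob > 0,
            size_prob < 1)
  set.seed(as.integer(seed))
  sizes <- sample(2:17, n_operons, replace = TRUE,
                  prob = stats::dgeom(0:15, size_prob))
  if (sum(sizes) > n_genes)
    stop("operons require ", sum(sizes), " genes but n_genes = ", n_genes,
         "; reduce n_operons or the size distribution")
  n_sing <- n_genes - sum(sizes)

  conds <- c("glucose", "laminarin", "alginate", "agar", "porphyran",
             "kappa_carrageenan", "iota_carrageenan")
  if (n_conditions <= length(conds)) conds <- conds[seq_len(n_conditions)]
  else conds <- c(conds, paste0("condition_",
                                seq_len(n_conditions - length(conds))))
  design <- SampleDesign(
    samples = paste(rep(conds, each = n_reps),
                    rep(seq_len(n_reps), n_conditions), sep = "_"),
    condition = rep(conds, each = n_reps),
    reference = conds[1L])
  cond_idx <- rep(seq_len(n_conditions), each = n_reps)
  n_samp <- n_conditions * n_reps

  ## interleave operon blocks and singletons in random order on the circle
  unit_kind <- sample(c(rep("op", n_operons), rep("sg", n_sing)))
  op_order <- sample.int(n_operons)
  gene_unit <- integer(0)       # operon index, 0 for singleton
  oi <- 0L
  for (u in unit_kind) {
    if (u == "op") {
      oi <- oi + 1L
      gene_unit <- c(gene_unit, rep(op_order[oi], sizes[op_order[oi]]))
    } else gene_unit <- c(gene_unit, 0L)
  }
  ids <- sprintf("GENE_%04d", seq_len(n_genes))

  ## layout: ~900 bp genes separated by ~100 bp gaps; operon blocks share
  ## a strand
  glen <- 900L; gap <- 100L
  start <- (seq_len(n_genes) - 1L) * (glen + gap) + 1L
  strand <- character(n_genes)
  op_strand <- sample(c("+", "-"), n_operons, replace = TRUE)
  run <- rle(gene_unit)
  pos <- 1L
  for (r in seq_along(run$lengths)) {
    u <- run$values[r]; len <- run$lengths[r]
    if (u > 0L) strand[pos:(pos + len - 1L)] <- op_strand[u]
    else strand[pos:(pos + len - 1L)] <-
        sample(c("+", "-"), len, replace = TRUE)
    pos <- pos + len
  }
  layout <- GenomeLayout(ids, start, start + glen - 1L, strand,
                         circular = TRUE, seqname = "chr")

  ## expression: per-unit condition profiles
  n_units <- n_operons + n_sing
  unit_ids <- c(sprintf("OP_%03d", seq_len(n_operons)),
                sprintf("SG_%03d", seq_len(max(n_sing, 0L))))
  profiles <- matrix(stats::rnorm(n_units * n_conditions, mu0, tau),
                     n_units, n_conditions,
                     dimnames = list(unit_ids[seq_len(n_units)], conds))
  de_units <- which(stats::runif(n_units) < de_frac)
  de_cond <- integer(0)
  if (length(de_units)) {
    de_cond <- sample(2:n_conditions, length(de_units), replace = TRUE)
    for (i in seq_along(de_units))
      profiles[de_units[i], de_cond[i]] <-
        profiles[de_units[i], de_cond[i]] + de_shift
  }

  sing_seen <- 0L
  unit_of_gene <- integer(n_genes)   # row index into profiles
  for (g in seq_len(n_genes)) {
    if (gene_unit[g] > 0L) unit_of_gene[g] <- gene_unit[g]
    else {
      sing_seen <- sing_seen + 1L
      unit_of_gene[g] <- n_operons + sing_seen
    }
  }
  baseline <- stats::rnorm(n_genes, 0, baseline_sd)
  baseline[gene_unit == 0L] <- 0   # offsets matter only within operons
  vals <- profiles[unit_of_gene, cond_idx, drop = FALSE] + baseline +
    matrix(stats::rnorm(n_genes * n_samp, 0, sigma), n_genes, n_samp)

  n_bg <- round(background_frac * n_genes)
  bg_ids <- if (n_bg > 0) sprintf("RANDOM_%03d", seq_len(n_bg))
            else character(0)
  bg_vals <- matrix(stats::rnorm(n_bg * n_samp, mu0 - 3, sigma),
                    n_bg, n_samp)
  mat <- rbind(vals, bg_vals)
  dimnames(mat) <- list(c(ids, bg_ids), sampleIds(design))
  expr <- ExpressionData(mat, scale = "log2", background = bg_ids)

  operons <- lapply(seq_len(n_operons), function(u) ids[gene_unit == u])
  truth <- new("SyntheticTruth",
    operons = operons,
    singletons = ids[gene_unit == 0L],
    background = bg_ids,
    profiles = profiles,
    params = list(n_genes = n_genes, n_operons = n_operons,
                  size_prob = size_prob, n_conditions = n_conditions,
                  n_reps = n_reps, tau = tau, sigma = sigma,
                  baseline_sd = baseline_sd,
                  background_frac = background_frac, de_frac = de_frac,
                  de_shift = de_shift, mu0 = mu0,
                  seed = as.integer(seed),
                  de_units = de_units, de_cond = de_cond))
  list(expression = expr, layout = layout, design = design, truth = truth)
}

#' @rdname accessors
#' @export
setMethod("trueOperons", "SyntheticTruth", function(x) x@operons)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@operons), "operons (sizes",
      paste(range(lengths(object@operons)), collapse = "-"), "),",
      length(object@singletons), "singletons,",
      length(object@background), "background probes; seed",
      object@params$seed, "\n")
})

#' Precision/recall/F1 of detected segments against planted operons
#'
#' A segment matches an operon when their member id sets are equal
#' (\code{mode = "exact"}) or have Jaccard index >= \code{jaccard_min}
#' (\code{mode = "jaccard"}, default 0.5). Precision is the fraction of
#' segments matching some operon; recall the fraction of operons matched
#' by some segment; F1 their harmonic mean. An empty detection has recall
#' 0 and, by convention, precision 1 with \code{empty = TRUE}.
#'
#' @param segments a [GTSegmentSet-class] (typically dominant segments).
#' @param truth a [SyntheticTruth-class].
#' @param mode matching rule.
#' @param jaccard_min Jaccard threshold for \code{mode = "jaccard"}.
#' @return list: \code{precision}, \code{recall}, \code{f1},
#'   \code{n_segments}, \code{n_operons}, \code{empty}.
#' @export
recoveryMetrics <- function(segments, truth, mode = c("jaccard", "exact"),
                            jaccard_min = 0.5) {
  stopifnot(is(segments, "GTSegmentSet"), is(truth, "SyntheticTruth"))
  mode <- match.arg(mode)
  ops <- trueOperons(truth)
  mems <- segmentMembers(segments)
  matches <- function(m, o) {
    if (mode == "exact") setequal(m, o)
    else length(intersect(m, o)) / length(union(m, o)) >= jaccard_min
  }
  if (!length(mems)) {
    return(list(precision = 1, recall = 0, f1 = 0,
                n_segments = 0L, n_operons = length(ops), empty = TRUE))
  }
  seg_hit <- vapply(mems, function(m)
    any(vapply(ops, matches, logical(1), m = m)), logical(1))
  op_hit <- vapply(ops, function(o)
    any(vapply(mems, matches, logical(1), o = o)), logical(1))
  precision <- mean(seg_hit)
  recall <- if (length(ops)) mean(op_hit) else NA_real_
  f1 <- if (is.na(recall) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_segments = length(mems), n_operons = length(ops), empty = FALSE)
}
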