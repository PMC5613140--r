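# segcoex

Detection of operon-like transcription units in bacterial genomes by
combining multi-condition expression data with chromosomal gene order.

## The problem

In prokaryotes, functionally related genes are often transcribed together
as operons. Sequence-based operon predictions (intergenic distances,
promoter/terminator signals) need experimental support: genes that are
truly co-transcribed should be *co-expressed* across perturbations, and
they should be *adjacent* on the chromosome. `segcoex` implements a
segment-based method that fuses these two signals, plus the statistics
that surround such a study: normalization, expression detection against
background probes, moderated-t differential expression with family-wise
error control, Morisita-Horn sample dissimilarity, set intersections and
enrichment tests, and a synthetic benchmark with planted operons. It is
aimed at microbial transcriptomics studies profiling one strain under a
handful of replicated conditions (e.g. growth on different carbon
sources).

## The method

1. **Co-expression network.** For every pair of expressed elements
   (genes, optionally intergenic regions), compute the Spearman
   correlation `rho(g, g')` and its two-sided p-value from the
   t approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Keep an edge when
   `rho >= 0.8` and the Bonferroni-adjusted p-value is at most `1e-9`,
   optionally confirmed by the maximal information coefficient
   (`MIC >= 0.6`, computed exactly by exhaustive grid search — feasible at
   replicated-design sample sizes and deterministic).
2. **Segments.** Model the chromosome as a circular sequence *G* of
   genes. A segment *S* is a contiguous arc of *G* with `2 <= |S| <= 50`
   whose two extremities are connected by a network path lying entirely
   inside *S*. Its reachable set *R(S)* is the connected component of the
   arc-induced subgraph containing both extremities, and its density

       d_g(S) = |R(S)| / |S|

   measures the fraction of the arc behaving co-ordinately; segments with
   `d_g(S) >= 0.6` are candidate transcription units.
3. **Dominance.** Segment *B* dominates *A* when `R(A) ⊆ R(B)` and
   `d_g(A) < d_g(B)`. Dominant segments (those dominated by none) are
   reported; overlapping dominants are retained and can be collapsed into
   unique regions separately.

## Worked example

```r
library(segcoex)

sim <- simulateExperiment(n_genes = 120, n_operons = 15, seed = 42)
sim$expression
#> ExpressionData: 126 elements x 21 samples
#>   scale: log2 | background probes: 6

res <- detectTranscriptionUnits(sim$expression, sim$layout, sim$design,
                                rho_min = 0.8, p_max = 1, use_mic = FALSE)
res$dominant
#> GTSegmentSet: 70 segments over 120 elements ( circular )
#>   lengths: 2-6 | density: 0.67-1.00 | mixed-strand: 1

head(as.data.frame(segmentTable(res$dominant))[,
  c("start", "length", "first_id", "last_id", "density", "strand_class")])
#>   start length  first_id   last_id   density   strand_class
#> 1     1      3 GENE_0001 GENE_0003 0.6666667 same_direction
#> 2     4      2 GENE_0004 GENE_0005 1.0000000 same_direction
#> 3     4      3 GENE_0004 GENE_0006 1.0000000 same_direction
#> 4     5      2 GENE_0005 GENE_0006 1.0000000 same_direction
#> 5    10      2 GENE_0010 GENE_0011 1.0000000 same_direction
#> 6    10      3 GENE_0010 GENE_0012 1.0000000 same_direction

unlist(recoveryMetrics(res$dominant, sim$truth)[c("precision", "recall", "f1")])
#> precision    recall        f1
#> 0.8571429 0.9333333 0.8936170
```

The simulated study plants 15 operon blocks (plus independent singleton
genes and background probes) under a 7-condition x 3-replicate design;
the pipeline recovers 14 of the 15 at Jaccard >= 0.5, and 86% of the
reported dominant segments correspond to a planted operon. Overlapping
dominants with equal density are retained by design — they often delimit
internal transcript boundaries.

The supporting statistics are one call each, e.g.

```r
enrichmentChisq(120, 279, 1429, 4482)$statistic   # 15.90732
tFromR(0.823, 59)$t                               # 11.12874
```

A command-line interface wrapping the same functions is installed at
`inst/scripts/segcoex` (subcommands: `simulate`, `normalize`, `detect`,
`network`, `segments`, `de`, `dissim`, `upset`, `enrich`, `benchmark`).

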