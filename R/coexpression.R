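#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-rank vectors; ties receive average ranks.
#' Returns \code{NA} with a notice for a constant vector (undefined
#' correlation; such pairs are skipped during network construction and do
#' not enter the Bonferroni family).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return rho in \[-1, 1\], or \code{NA} for a constant input.
#' @examples
#' spearmanRho(1:5, (1:5)^2)   # 1: invariant to monotone transforms
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant vector: Spearman correlation undefined, skipping")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Two-sided p-value for a Spearman correlation
#'
#' Uses the t approximation t = rho * sqrt((n - 2) / (1 - rho^2)) with
#' n - 2 degrees of freedom. For |rho| = 1 the statistic is infinite; the
#' smallest representable positive double is returned with attribute
#' \code{boundary = TRUE}.
#'
#' @param rho correlation in \[-1, 1\].
#' @param n number of paired observations (>= 4).
#' @return p in (0, 1\].
#' @examples
#' rhoPValue(0.8, 21)   # ~1.2e-5
#' @export
rhoPValue <- function(rho, n) {
  if (n < 4L) stop("need n >= 4")
  if (abs(rho) > 1) stop("|rho| > 1")
  if (abs(rho) == 1) {
    p <- .Machine$double.xmin
    attr(p, "boundary") <- TRUE
    return(p)
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Maximal information coefficient (exact, small n)
#'
#' Maximal normalized mutual information over axis-aligned grids whose
#' cell-count product is bounded by \code{B = n^b_exponent} (at least 4, so
#' the 2x2 grid is always admissible), normalized by log2 of the smaller
#' grid dimension. Computed by exhaustive search over all cut placements,
#' so the value is exact and deterministic; the search is feasible for the
#' small sample sizes of replicated condition designs (n up to ~40 at the
#' default exponent) and errors beyond that.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param b_exponent grid-size bound exponent (default 0.6).
#' @return mic in \[0, 1\]; 0 for a constant vector.
#' @examples
#' micScore(1:21, (1:21)^3)   # 1: noiseless monotone dependence
#' @export
micScore <- function(x, y, b_exponent = 0.6) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("MIC needs n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  B <- max(4, floor(n^b_exponent))
  .micExhaustive(as.numeric(x), as.numeric(y), B)
}

#' Build the thresholded co-expression network
#'
#' Tests every unordered pair of elements: Spearman rho, two-sided p from
#' the t approximation, Bonferroni adjustment over the number of tested
#' pairs (pairs involving a constant element are skipped and not counted).
#' An edge is retained iff \code{rho >= rho_min} (signed: negative
#' correlations never form edges), \code{p_adj <= p_max}, and, when
#' \code{use_mic}, \code{mic >= mic_min}. MIC is computed only for pairs
#' already passing the correlation and p filters (confirmation step). All
#' input elements remain as nodes, so isolated nodes are retained.
#'
#' @param x an [ExpressionData-class] with >= 4 samples.
#' @param elements optional subset of element ids to test (e.g. the output
#'   of [detectExpressed()]); default: all non-background elements.
#' @param rho_min Spearman threshold (default 0.8).
#' @param p_max adjusted-p threshold (default 1e-9).
#' @param mic_min MIC confirmation threshold (default 0.6).
#' @param use_mic whether to apply the MIC confirmation filter.
#' @param bonferroni family for the Bonferroni multiplier:
#'   \code{"tested"} (default, pairs actually tested) or \code{"all"}
#'   (all element pairs of the matrix).
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(x, elements = NULL, rho_min = 0.8, p_max = 1e-9,
                         mic_min = 0.6, use_mic = TRUE,
                         bonferroni = c("tested", "all")) {
  stopifnot(is(x, "ExpressionData"))
  bonferroni <- match.arg(bonferroni)
  if (ncol(x) < 4L) stop("network construction needs >= 4 samples")
  if (is.null(elements))
    elements <- setdiff(elementIds(x), backgroundIds(x))
  bad <- setdiff(elements, elementIds(x))
  if (length(bad))
    stop("unknown elements: ", paste(bad, collapse = ", "))
  if (length(elements) < 2L) stop("need >= 2 elements")
  v <- exprValues(x)[elements, , drop = FALSE]
  n <- ncol(v)

  const <- apply(v, 1L, function(r) stats::sd(r) == 0)
  if (any(const))
    message(sum(const), " constant element(s) skipped in pair testing")
  ok <- which(!const)
  rho <- stats::cor(t(v[ok, , drop = FALSE]), method = "spearman")

  n_ok <- length(ok)
  m_tested <- n_ok * (n_ok - 1) / 2
  m_family <- if (bonferroni == "all")
    length(elements) * (length(elements) - 1) / 2 else m_tested

  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p_raw <- ifelse(abs(r) >= 1, .Machine$double.xmin,
                  2 * stats::pt(-abs(tstat), df = n - 2))
  p_adj <- pmin(1, p_raw * m_family)

  keep <- which(r >= rho_min & p_adj <= p_max)
  from <- elements[ok][ut[keep, 1L]]
  to <- elements[ok][ut[keep, 2L]]
  mic <- rep(NA_real_, length(keep))
  if (use_mic && length(keep)) {
    B <- max(4, floor(n^0.6))
    for (i in seq_along(keep)) {
      mic[i] <- .micExhaustive(v[from[i], ], v[to[i], ], B)
    }
    conf <- mic >= mic_min
    from <- from[conf]; to <- to[conf]
    r_keep <- r[keep][conf]; p_keep <- p_adj[keep][conf]
    mic <- mic[conf]
  } else {
    r_keep <- r[keep]; p_keep <- p_adj[keep]
  }

  edges <- if (length(from))
    S4Vectors::DataFrame(from = from, to = to, rho = r_keep,
                         p_adj = p_keep, mic = mic)
  else NULL
  CoexpressionNetwork(
    nodes = elements, edges = edges,
    params = list(rho_min = rho_min, p_max = p_max, mic_min = mic_min,
                  use_mic = use_mic, bonferroni = bonferroni,
                  m_family = m_family, m_tested = m_tested,
                  n_samples = n))
}
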