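#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the cross-sample mean of sorted intensity vectors. Ranks within each
#' sample are preserved; tied values receive the mean of the reference
#' values at their tied ranks. Idempotent: a second application is the
#' identity.
#'
#' @param x an [ExpressionData-class] with at least two samples.
#' @return an [ExpressionData-class] with normalized intensities (same
#'   scale flag as the input).
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
#' rownames(m) <- paste0("g", 1:3)
#' exprValues(quantileNormalize(ExpressionData(m, "linear")))
#' @export
quantileNormalize <- function(x) {
  stopifnot(is(x, "ExpressionData"))
  v <- exprValues(x)
  if (ncol(v) < 2L)
    stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(v, 2L, sort))
  cum0 <- c(0, cumsum(ref))           # cum0[r + 1] = sum of ref[1..r]
  out <- v
  for (j in seq_len(ncol(v))) {
    lo <- rank(v[, j], ties.method = "min")
    hi <- rank(v[, j], ties.method = "max")
    out[, j] <- (cum0[hi + 1L] - cum0[lo]) / (hi - lo + 1L)
  }
  setExprValues(x, out)
}

#' Log2 transformation of linear intensities
#'
#' Adds a pseudo-count offset before taking log2 and flips the scale flag.
#'
#' @param x an [ExpressionData-class] on linear scale, values >= 0.
#' @param offset pseudo-count added before the log (default 1).
#' @return an [ExpressionData-class] on log2 scale.
#' @export
log2Transform <- function(x, offset = 1) {
  stopifnot(is(x, "ExpressionData"))
  if (exprScale(x) != "linear")
    stop("log2Transform expects linear-scale input, got ", exprScale(x))
  v <- exprValues(x)
  if (any(v < 0))
    stop("negative intensity encountered; cannot log-transform")
  setExprValues(x, log2(v + offset), scale = "log2")
}

#' Detect significantly expressed elements against background probes
#'
#' An element counts as expressed in a sample when its intensity exceeds
#' the empirical (1 - alpha) quantile (linear-interpolation definition,
#' \code{stats::quantile} type 7) of the background probe intensities in
#' that sample. With \code{mode = "condition"} an element is returned iff
#' it is expressed in all replicate samples of at least one condition; with
#' \code{mode = "sample"} a single expressed sample suffices. Background
#' elements are never returned. \code{alpha >= 1} degenerates to "everything
#' non-background".
#'
#' @param x an [ExpressionData-class] with non-empty background ids.
#' @param design a [SampleDesign-class] covering the samples (required for
#'   \code{mode = "condition"}).
#' @param alpha significance level (default 0.01).
#' @param mode replicate aggregation rule.
#' @return character vector of expressed element ids, in matrix order.
#' @export
detectExpressed <- function(x, design = NULL, alpha = 0.01,
                            mode = c("condition", "sample")) {
  stopifnot(is(x, "ExpressionData"))
  mode <- match.arg(mode)
  bg <- backgroundIds(x)
  if (!length(bg))
    stop("no background ids on this matrix; skip detection instead")
  v <- exprValues(x)
  if (alpha >= 1) {
    thr <- rep(-Inf, ncol(v))
  } else {
    thr <- apply(v[bg, , drop = FALSE], 2L, stats::quantile,
                 probs = 1 - alpha, names = FALSE)
  }
  expressed <- sweep(v, 2L, thr, `>`)
  fg <- setdiff(rownames(v), bg)
  expressed <- expressed[fg, , drop = FALSE]
  if (mode == "sample") {
    hit <- rowSums(expressed) > 0L
  } else {
    if (is.null(design))
      stop("mode = 'condition' requires a design")
    checkDesign(x, design, min_reps = 0L)
    cond <- conditionOf(design)[colnames(v)]
    hit <- rep(FALSE, length(fg))
    for (cc in unique(cond)) {
      cols <- which(cond == cc)
      hit <- hit | rowSums(expressed[, cols, drop = FALSE]) == length(cols)
    }
  }
  fg[hit]
}
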