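#' Log2 fold change of a condition versus the reference
#'
#' Difference of per-element group means on the log2 scale.
#'
#' @param x an [ExpressionData-class] on log2 scale.
#' @param design a [SampleDesign-class].
#' @param condition condition label to contrast.
#' @param reference reference label (default: the design's).
#' @return named numeric vector, one value per element.
#' @export
log2FoldChange <- function(x, design, condition,
                           reference = referenceCondition(design)) {
  stopifnot(is(x, "ExpressionData"), is(design, "SampleDesign"))
  if (exprScale(x) != "log2")
    stop("log2 fold changes need log2-scale input")
  for (cc in c(condition, reference))
    if (!cc %in% conditionLevels(design)) stop("unknown condition: ", cc)
  v <- exprValues(x)
  s1 <- intersect(samplesFor(design, condition), colnames(v))
  s0 <- intersect(samplesFor(design, reference), colnames(v))
  if (length(s1) < 2L || length(s0) < 2L)
    stop("both conditions need >= 2 samples")
  rowMeans(v[, s1, drop = FALSE]) - rowMeans(v[, s0, drop = FALSE])
}

## Newton solve of trigamma(x) = y, vectorized (monotone decreasing).
trigammaInverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

## Moment-matched scaled-inverse-chi-square prior for per-element pooled
## variances: on the log scale, log s^2_g = log s0^2 + log chi-square
## ratios, so E[e_g] and Var[e_g] of e_g = log s^2_g - digamma(d/2) +
## log(d/2) identify (d0, s0^2) through digamma/trigamma moments.
estimatePrior <- function(s2, d, d0 = NULL) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  if (is.null(d0)) {
    evar <- stats::var(e) - trigamma(d / 2)
    d0 <- if (is.na(evar) || evar <= 0) Inf else 2 * trigammaInverse(evar)
  }
  s0_2 <- if (is.infinite(d0)) mean(s2[ok])
          else exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics for one two-group contrast
#'
#' Per-element pooled two-group variance shrunk toward a common prior:
#' the prior (d0, s0^2) is a scaled inverse-chi-square distribution fitted
#' to the observed variances by moment matching on the log scale (or
#' supplied). The posterior variance is
#' \deqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' and t = log2fc / (s_tilde * sqrt(1/n1 + 1/n2)) with d0 + d_g degrees of
#' freedom. With \code{d0 = 0} this reduces exactly to the ordinary pooled
#' two-sample t-test.
#'
#' @param x an [ExpressionData-class] on log2 scale.
#' @param design a [SampleDesign-class].
#' @param condition condition to contrast against \code{reference}.
#' @param reference reference condition (default: the design's).
#' @param d0 prior degrees of freedom, or \code{"estimate"} (default):
#'   both hyperparameters are then moment-matched from the observed
#'   variances. When \code{d0} is supplied without \code{s0_2}, the prior
#'   variance defaults to the mean observed variance (so that identical
#'   per-element variances are an exact fixed point of the shrinkage).
#' @param s0_2 optional prior variance, used with a supplied \code{d0}.
#' @return data.frame with one row per element: \code{element},
#'   \code{log2fc}, \code{t_stat}, \code{df_total}, \code{p_raw}; the
#'   fitted \code{d0} and \code{s0_2} as attributes.
#' @export
moderatedT <- function(x, design, condition,
                       reference = referenceCondition(design),
                       d0 = "estimate", s0_2 = NULL) {
  stopifnot(is(x, "ExpressionData"))
  lfc <- log2FoldChange(x, design, condition, reference)
  v <- exprValues(x)
  s1 <- intersect(samplesFor(design, condition), colnames(v))
  s0 <- intersect(samplesFor(design, reference), colnames(v))
  n1 <- length(s1); n0 <- length(s0)
  d <- n1 + n0 - 2L
  if (d < 1L) stop("zero residual degrees of freedom")
  ss1 <- rowSums((v[, s1, drop = FALSE] -
                    rowMeans(v[, s1, drop = FALSE]))^2)
  ss0 <- rowSums((v[, s0, drop = FALSE] -
                    rowMeans(v[, s0, drop = FALSE]))^2)
  s2 <- (ss1 + ss0) / d
  if (identical(d0, "estimate")) {
    prior <- estimatePrior(s2, d)
  } else {
    d0 <- as.numeric(d0)
    if (d0 < 0) stop("d0 must be >= 0")
    prior <- list(d0 = d0,
                  s0_2 = if (!is.null(s0_2)) s0_2
                         else if (d0 > 0) mean(s2[s2 > 0])
                         else NA_real_)
  }
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_2, length(s2))
    else if (prior$d0 == 0) s2
    else (prior$d0 * prior$s0_2 + d * s2) / (prior$d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  tstat <- lfc / se
  # total df capped at the pooled residual df of the whole matrix: the
  # prior cannot carry more information than the data it was fitted to
  df_total <- min(prior$d0 + d, length(s2) * d)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(element = names(lfc), log2fc = unname(lfc),
                    t_stat = unname(tstat),
                    df_total = rep(df_total, length(lfc)),
                    p_raw = unname(p), row.names = NULL)
  attr(out, "d0") <- prior$d0
  attr(out, "s0_2") <- prior$s0_2
  out
}

#' Differential expression across all non-reference conditions
#'
#' Runs [moderatedT()] per condition against the reference, applies the
#' Bonferroni adjustment (family = elements tested per contrast) and the
#' call rule: up iff p_adj <= fwer and log2fc > fc_min; down iff p_adj <=
#' fwer and log2fc < -fc_min.
#'
#' @param x an [ExpressionData-class] on log2 scale.
#' @param design a [SampleDesign-class].
#' @param conditions conditions to test (default: all non-reference).
#' @param elements optional subset of elements (e.g. detected ones).
#' @param fwer family-wise error bound (default 0.05, non-strict).
#' @param fc_min log2 fold-change threshold (default 2, strict).
#' @param d0 prior df, or \code{"estimate"}.
#' @return a [DEResult-class].
#' @export
runDE <- function(x, design, conditions = NULL, elements = NULL,
                  fwer = 0.05, fc_min = 2, d0 = "estimate") {
  stopifnot(is(x, "ExpressionData"), is(design, "SampleDesign"))
  if (!is.null(elements)) {
    bad <- setdiff(elements, elementIds(x))
    if (length(bad)) stop("unknown elements: ", paste(bad, collapse = ", "))
    x <- x[elements, ]
  }
  ref <- referenceCondition(design)
  if (is.null(conditions))
    conditions <- setdiff(conditionLevels(design), ref)
  m <- nrow(x)
  tabs <- lapply(conditions, function(cc) {
    tb <- moderatedT(x, design, cc, ref, d0 = d0)
    tb$condition <- cc
    tb$p_adj <- pmin(1, tb$p_raw * m)
    tb$call <- ifelse(tb$p_adj <= fwer & tb$log2fc > fc_min, "up",
               ifelse(tb$p_adj <= fwer & tb$log2fc < -fc_min, "down",
                      "none"))
    tb
  })
  tb <- do.call(rbind, tabs)
  new("DEResult",
      table = S4Vectors::DataFrame(
        tb[, c("element", "condition", "log2fc", "t_stat", "df_total",
               "p_raw", "p_adj", "call")]),
      params = list(reference = ref, fwer = fwer, fc_min = fc_min,
                    d0 = d0, m = m))
}

#' @rdname accessors
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

setMethod("show", "DEResult", function(object) {
  tb <- object@table
  cat("DEResult:", length(unique(tb$element)), "elements x",
      length(unique(tb$condition)), "contrasts vs",
      object@params$reference, "\n")
  cat("  calls: up", sum(tb$call == "up"), "| down",
      sum(tb$call == "down"), "\n")
})

#' Up/down sets and per-condition summaries
#'
#' @param de a [DEResult-class].
#' @param fwer,fc_min thresholds; default to those stored in \code{de}.
#' @return list with \code{up} and \code{down} (named lists of element id
#'   vectors per condition) and \code{summary} (data.frame: condition,
#'   n_up, n_down, |log2fc| ranges of the called genes).
#' @export
deSets <- function(de, fwer = de@params$fwer, fc_min = de@params$fc_min) {
  stopifnot(is(de, "DEResult"))
  tb <- as.data.frame(deTable(de))
  up_call <- tb$p_adj <= fwer & tb$log2fc > fc_min
  dn_call <- tb$p_adj <= fwer & tb$log2fc < -fc_min
  conds <- unique(tb$condition)
  up <- lapply(conds, function(cc) tb$element[up_call & tb$condition == cc])
  dn <- lapply(conds, function(cc) tb$element[dn_call & tb$condition == cc])
  names(up) <- names(dn) <- conds
  rng <- function(v) if (length(v)) range(abs(v)) else c(NA_real_, NA_real_)
  summ <- do.call(rbind, lapply(conds, function(cc) {
    u <- up_call & tb$condition == cc
    d <- dn_call & tb$condition == cc
    ur <- rng(tb$log2fc[u]); dr <- rng(tb$log2fc[d])
    data.frame(condition = cc, n_up = sum(u), n_down = sum(d),
               up_fc_min = ur[1], up_fc_max = ur[2],
               down_fc_min = dr[1], down_fc_max = dr[2])
  }))
  list(up = up, down = dn, summary = summ)
}

#' Percentage of regulated genes
#'
#' 100 * (up + down) / total, rounded to two decimals (the convention used
#' for per-substrate regulation summaries).
#'
#' @param up_count,down_count,total_on_chip nonnegative integers,
#'   \code{total_on_chip > 0}.
#' @return numeric percentage, 2 decimals.
#' @examples
#' percentRegulated(47, 308, 4482)   # 7.92
#' @export
percentRegulated <- function(up_count, down_count, total_on_chip) {
  stopifnot(up_count >= 0, down_count >= 0, total_on_chip > 0)
  round(100 * (up_count + down_count) / total_on_chip, 2)
}
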