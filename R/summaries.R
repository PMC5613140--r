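#' Morisita-Horn dissimilarity of two abundance profiles
#'
#' \deqn{1 - \frac{2 \sum x_i y_i}{(\sum x_i^2/X^2 + \sum y_i^2/Y^2) X Y}}
#' with X, Y the profile totals. Symmetric, bounded in \[0, 1\], and
#' scale-invariant (x and c x are equivalent). Not a metric: the triangle
#' inequality can fail.
#'
#' @param x,y nonnegative numeric profiles of equal length with positive
#'   totals.
#' @return dissimilarity in \[0, 1\].
#' @examples
#' morisitaHorn(c(2, 0), c(1, 1))   # 1/3
#' @export
morisitaHorn <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (any(x < 0) || any(y < 0)) stop("profiles must be nonnegative")
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("zero-total profile")
  d <- 1 - (2 * sum(x * y)) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  min(max(d, 0), 1)
}

#' Sample-by-sample Morisita-Horn dissimilarity matrix
#'
#' Pairwise dissimilarities between sample columns, e.g. as input to an
#' external ordination (NMDS). Profiles must be nonnegative, so this is
#' meant for normalized linear-scale intensities.
#'
#' @param x an [ExpressionData-class] with nonnegative values.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
dissimilarityMatrix <- function(x) {
  stopifnot(is(x, "ExpressionData"))
  v <- exprValues(x)
  if (any(v < 0))
    stop("negative values: Morisita-Horn needs nonnegative profiles")
  n <- ncol(v)
  out <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      d <- morisitaHorn(v[, i], v[, j])
      out[i, j] <- d
      out[j, i] <- d
    }
  out
}

#' Exclusive intersection counts of named sets
#'
#' For every non-empty subset P of the set names, counts the elements that
#' belong to exactly the sets in P and no others (the quantities shown by
#' an UpSet plot). Counts over all patterns sum to the size of the union.
#'
#' @param sets named list of vectors.
#' @return data.frame with columns \code{pattern} (set names joined by
#'   \code{"&"}), \code{degree}, \code{count}, sorted by decreasing count;
#'   includes zero-count patterns when there are at most 15 sets.
#' @examples
#' exclusiveIntersections(list(A = c(1, 2), B = c(2, 3)))
#' @export
exclusiveIntersections <- function(sets) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("need a non-empty named list of sets")
  nm <- names(sets)
  uni <- unique(unlist(lapply(sets, as.character)))
  member <- vapply(sets, function(s) uni %in% as.character(s),
                   logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL, nm))
  key <- apply(member, 1L, function(r) paste(nm[r], collapse = "&"))
  counts <- table(key[nzchar(key)])
  if (length(nm) <= 15L) {
    all_patterns <- unlist(lapply(seq_along(nm), function(k)
      utils::combn(nm, k, paste, collapse = "&")))
    full <- stats::setNames(rep(0L, length(all_patterns)), all_patterns)
    full[names(counts)] <- as.integer(counts)
    counts <- full
  }
  out <- data.frame(pattern = names(counts),
                    degree = lengths(strsplit(names(counts), "&",
                                              fixed = TRUE)),
                    count = as.integer(counts), row.names = NULL)
  out[order(-out$count, out$degree, out$pattern), , drop = FALSE]
}

#' One-sample goodness-of-fit enrichment test
#'
#' Tests whether a category is over- or under-represented in a subset
#' relative to the chip-wide proportion: expected in-category count is
#' \code{n_subset * K_total / N_total}, and the chi-squared statistic sums
#' (obs - exp)^2 / exp over the two cells (in-category, not in-category),
#' df = 1.
#'
#' @param k_obs in-category count in the subset.
#' @param n_subset subset size.
#' @param K_total in-category count in the universe.
#' @param N_total universe size.
#' @return list: \code{statistic}, \code{df}, \code{p_value},
#'   \code{expected}, \code{low_expected} (TRUE when an expected cell is
#'   below 1, where the chi-squared approximation is unreliable).
#' @examples
#' enrichmentChisq(120, 279, 1429, 4482)$statistic   # ~15.9
#' @export
enrichmentChisq <- function(k_obs, n_subset, K_total, N_total) {
  stopifnot(k_obs >= 0, k_obs <= n_subset, K_total > 0, K_total < N_total)
  e1 <- n_subset * K_total / N_total
  e2 <- n_subset - e1
  stat <- (k_obs - e1)^2 / e1 + ((n_subset - k_obs) - e2)^2 / e2
  low <- min(e1, e2) < 1
  if (low)
    warning("expected cell below 1; chi-squared approximation unreliable")
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = c(in_category = e1, out_category = e2),
       low_expected = low)
}

#' t statistic for a Pearson correlation
#'
#' t = r sqrt(df) / sqrt(1 - r^2), two-sided p from the t distribution
#' with \code{df} degrees of freedom. Used for cross-platform validation
#' of fold changes (e.g. array vs RT-qPCR).
#'
#' @param r Pearson correlation, |r| < 1.
#' @param df degrees of freedom (n - 2), >= 1.
#' @return list: \code{t}, \code{df}, \code{p_value}.
#' @examples
#' tFromR(0.823, 59)$t   # ~11.13
#' @export
tFromR <- function(r, df) {
  stopifnot(abs(r) < 1, df >= 1)
  tstat <- r * sqrt(df) / sqrt(1 - r^2)
  list(t = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df = df))
}
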