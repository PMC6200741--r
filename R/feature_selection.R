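# Univariate t-test filter feature selection.

#' Rank features by a two-sample t-test between activity classes
#'
#' For every feature, a two-sample t statistic between the ANTI and
#' NON_ANTI groups and its two-sided p-value. Features are ranked by
#' ascending p-value; ties are broken by larger |t|, then by feature name,
#' so the ranking is deterministic. Features whose t statistic is
#' undefined (zero variance in both groups) receive the worst ranks.
#'
#' @param matrix A `descriptor_matrix` (standardization does not change
#'   the ranking: t is invariant to positive affine rescaling).
#' @param labels Optional class vector; defaults to `matrix$labels`.
#' @param variant `"welch"` (unequal variances, default) or `"pooled"`.
#' @return A `feature_ranking` data frame: `feature`, `t`, `p`, `rank`,
#'   sorted by rank.
#' @export
rank_features_ttest <- function(matrix, labels = NULL,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  v <- matrix$values
  if (is.null(labels)) labels <- matrix$labels
  g1 <- labels == "ANTI"
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2)
    stop("each class needs at least 2 observations (got ", n1, " ANTI, ",
         n2, " NON_ANTI)")
  m1 <- colMeans(v[g1, , drop = FALSE])
  m2 <- colMeans(v[!g1, , drop = FALSE])
  v1 <- colSums(sweep(v[g1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(v[!g1, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tt))
  }
  p <- 2 * stats::pt(-abs(tt), df)
  # zero spread in both groups but different means -> infinite separation
  inf_sep <- v1 + v2 == 0 & m1 != m2
  tt[inf_sep] <- sign(m1 - m2)[inf_sep] * Inf
  p[inf_sep] <- 0
  undef <- v1 + v2 == 0 & m1 == m2
  feature <- colnames(v)
  p_order <- ifelse(undef, Inf, p)
  ord <- order(p_order, -abs(tt), feature, na.last = TRUE)
  out <- data.frame(feature = feature[ord], t = unname(tt[ord]),
                    p = unname(p[ord]), rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Keep the k best-ranked features
#'
#' @param ranking A `feature_ranking` from [rank_features_ttest()].
#' @param matrix The `descriptor_matrix` the ranking refers to.
#' @param k Number of features to keep (1 <= k <= p).
#' @return A `descriptor_matrix` restricted to the top k features, columns
#'   ordered by rank (not by original position); provenance retained.
#' @export
select_top_k <- function(ranking, matrix, k) {
  p <- ncol(matrix$values)
  if (k < 1 || k > p)
    stop("k must lie in [1, ", p, "], got ", k)
  .subset_features(matrix, ranking$feature[seq_len(k)])
}

#' Subset-size schedule per descriptor configuration
#'
#' The benchmark's grid of filter subset sizes: (5, 10, 15) for AAC,
#' (25, 50, 75, 100) for DC, (75, 100, 125, 150) for TC and
#' (50, 100, 150, 200) for the merged set.
#'
#' @return Named list of integer vectors.
#' @export
subset_schedule <- function() {
  list(aac = c(5L, 10L, 15L),
       dc = c(25L, 50L, 75L, 100L),
       tc = c(75L, 100L, 125L, 150L),
       merged = c(50L, 100L, 150L, 200L))
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("Feature ranking (", nrow(x), " features, t-test filter)\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}
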