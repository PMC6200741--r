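# Feature-importance reporting from per-fold elastic-net coefficients.

#' Aggregate per-fold elastic-net coefficients
#'
#' Sums each feature's beta over all (repeat, fold) models — a feature
#' absent from a fold model contributes 0 — and records how often the
#' feature carried a nonzero coefficient. Under the package's class
#' encoding (ANTI is the positive class, so the linear predictor increases
#' toward anti-angiogenic), a positive beta sum marks a feature associated
#' with anti-angiogenic activity.
#'
#' @param coefficients Long data frame `repeat`, `fold`, `feature`,
#'   `beta` (as returned by [coef.nested_cv()]).
#' @param provenance Optional named vector feature -> descriptor set.
#' @param statistic `"sum"` (default) or `"mean"` over fold models.
#' @param positive_class The class toward which positive betas point;
#'   fixed to `"ANTI"` by the benchmark but recorded for auditability.
#' @return An `importance_table` data frame: `feature`, `beta_sum`,
#'   `selection_frequency`, `source`, `anti_associated`.
#' @export
aggregate_betas <- function(coefficients, provenance = NULL,
                            statistic = c("sum", "mean"),
                            positive_class = "ANTI") {
  statistic <- match.arg(statistic)
  if (!nrow(coefficients)) stop("empty coefficient table")
  key <- paste(coefficients$`repeat`, coefficients$fold,
               coefficients$feature)
  if (anyDuplicated(key))
    stop("duplicate (repeat, fold, feature) rows in coefficient table")
  n_models <- nrow(unique(coefficients[, c("repeat", "fold")]))
  sums <- tapply(coefficients$beta, coefficients$feature, sum)
  nz <- tapply(coefficients$beta != 0, coefficients$feature, sum)
  feats <- names(sums)
  beta_sum <- as.numeric(sums)
  if (statistic == "mean") beta_sum <- beta_sum / n_models
  src <- if (is.null(provenance)) sub(":.*$", "", feats) else
    unname(provenance[feats])
  anti_pos <- identical(positive_class, "ANTI")
  out <- data.frame(
    feature = feats, beta_sum = beta_sum,
    selection_frequency = as.numeric(nz) / n_models,
    source = src,
    anti_associated = if (anti_pos) beta_sum > 0 else beta_sum < 0,
    stringsAsFactors = FALSE)
  out <- out[order(out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top-k features by absolute aggregated beta
#'
#' Orders features by descending |beta_sum| (both signs are informative:
#' one direction marks anti-angiogenic association, the other its
#' absence), breaking ties by feature name. Features never selected by any
#' fold model (all-zero betas) are excluded by default.
#'
#' @param table An `importance_table`.
#' @param k Number of features to report.
#' @param include_zero Keep never-selected features in the ordering.
#' @return The top-k rows, |beta_sum| non-increasing.
#' @export
top_k_report <- function(table, k, include_zero = FALSE) {
  tab <- table
  if (!include_zero && any(tab$selection_frequency > 0))
    tab <- tab[tab$selection_frequency > 0 | tab$beta_sum != 0, ,
               drop = FALSE]
  if (k > nrow(tab))
    stop("k = ", k, " exceeds the ", nrow(tab), " reportable features")
  ord <- order(-abs(tab$beta_sum), tab$feature)
  out <- tab[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-descriptor composition shares before and after selection
#'
#' For each descriptor set, the percentage of features it contributes to
#' the full matrix and to the selected matrix, and the proportion of its
#' features discarded by selection.
#'
#' @param before,after `descriptor_matrix` objects; `after`'s features
#'   must be a subset of `before`'s.
#' @return Data frame `source`, `n_before`, `n_after`, `share_before`,
#'   `share_after` (percentages summing to 100), `discarded_proportion`.
#' @export
descriptor_composition <- function(before, after) {
  fb <- names(before$provenance); fa <- names(after$provenance)
  if (length(setdiff(fa, fb)))
    stop("selected matrix contains features absent from the full matrix")
  sources <- unique(unname(before$provenance))
  nb <- table(factor(unname(before$provenance), sources))
  na_ <- table(factor(unname(after$provenance), sources))
  data.frame(
    source = sources,
    n_before = as.integer(nb), n_after = as.integer(na_),
    share_before = 100 * as.integer(nb) / sum(nb),
    share_after = 100 * as.integer(na_) / sum(na_),
    discarded_proportion = 1 - as.integer(na_) / as.integer(nb),
    stringsAsFactors = FALSE)
}

#' @export
print.importance_table <- function(x, n = 10, ...) {
  cat("Elastic-net importance table (", nrow(x), " features)\n", sep = "")
  print.data.frame(utils::head(x[order(-abs(x$beta_sum)), ], n),
                   row.names = FALSE)
  invisible(x)
}
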