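# Nested-resampling benchmark: repeated stratified outer k-fold
# cross-validation for performance estimation, with an inner stratified
# 2/3-1/3 holdout used exclusively for hyperparameter tuning.

# Deterministic child seed for a (repeat, fold, learner) cell.
.child_seed <- function(master, r, f = 0L, li = 0L) {
  (((master %% 100000L) * 48271 + r * 16127 + f * 769 + li * 53) %%
     2147483399L) + 1L
}

.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.stratified_holdout <- function(labels, train_frac, seed) {
  set.seed(seed)
  tr <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    tr <- c(tr, sample(idx, max(1L, round(train_frac * length(idx)))))
  }
  sort(tr)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`; tied scores contribute 1/2. ANTI is the positive
#' class.
#'
#' @param scores Numeric scores, higher = more ANTI-like.
#' @param labels Class labels (`ANTI`/`NON_ANTI`).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  pos <- labels == "ANTI"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of exact matches.
#' @export
compute_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("length mismatch: ", length(predicted), " vs ", length(truth))
  if (!length(truth)) stop("empty input")
  mean(predicted == truth)
}

#' Nested cross-validation benchmark of learner families
#'
#' For each of `outer_repeats` repetitions, the data are split into
#' `outer_folds` stratified folds. Per fold and learner, the outer
#' training rows are (optionally) reduced to the top `fs_k` features of a
#' t-test ranking and standardized, then split 2/3-1/3 (stratified) into
#' an inner training and validation set on which every hyperparameter grid
#' point is scored by validation AUC. The best grid point is refitted on
#' the full outer training set and scored (AUC, accuracy) on the held-out
#' fold. Elastic-net coefficient vectors are recorded per fold.
#'
#' In `"fold"` mode both feature ranking and standardization are computed
#' inside each outer training set (leakage-safe). In `"global"` mode they
#' are computed once on the full data before resampling, mirroring the
#' common but optimistic whole-dataset preprocessing workflow; both modes
#' are available so their difference can be quantified.
#'
#' @param matrix A `descriptor_matrix`.
#' @param learners List of `learner_spec` from [make_default_learners()].
#' @param labels Optional label vector; defaults to `matrix$labels`.
#' @param outer_repeats,outer_folds Outer resampling plan (benchmark
#'   defaults 5 x 10).
#' @param inner_train_frac Fraction of outer-training rows used for inner
#'   fitting (rest is the tuning validation set); default 2/3.
#' @param fs_k Optional number of filter-selected features.
#' @param fs_mode,standardize `"fold"` or `"global"` (standardize also
#'   `"none"`).
#' @param seed Master seed; all fold assignments, inner splits and learner
#'   fits derive child seeds from it, so runs are reproducible.
#' @param dataset_label Tag stored in the result rows.
#' @return A `nested_cv` object: `results` (one row per repeat x fold x
#'   learner), `coefficients` (long glmnet beta table), `config`,
#'   `positive_class = "ANTI"`.
#' @export
run_nested_cv <- function(matrix, learners, labels = NULL,
                          outer_repeats = 5L, outer_folds = 10L,
                          inner_train_frac = 2 / 3,
                          fs_k = NULL, fs_mode = c("fold", "global"),
                          standardize = c("fold", "global", "none"),
                          seed = 1L, dataset_label = "data") {
  fs_mode <- match.arg(fs_mode)
  standardize <- match.arg(standardize)
  if (is.null(labels)) labels <- matrix$labels
  v <- matrix$values
  if (!all(is.finite(v))) stop("descriptor matrix contains non-finite values")
  if (min(table(factor(labels, CLASS_LEVELS))) < 2)
    stop("each class needs at least 2 observations")

  global_rank <- NULL
  if (!is.null(fs_k) && fs_mode == "global")
    global_rank <- rank_features_ttest(matrix, labels)
  global_std <- if (standardize == "global") fit_standardizer(matrix) else NULL

  results <- list(); coefs <- list()
  for (r in seq_len(outer_repeats)) {
    fold_of <- .stratified_folds(labels, outer_folds,
                                 .child_seed(seed, r))
    for (f in seq_len(outer_folds)) {
      test_idx <- which(fold_of == f)
      train_idx <- which(fold_of != f)
      if (length(unique(labels[train_idx])) < 2)
        stop("a class is absent from the training fold")

      work <- matrix
      if (!is.null(fs_k)) {
        rk <- if (fs_mode == "global") global_rank else
          rank_features_ttest(.subset_rows(matrix, train_idx))
        work <- select_top_k(rk, work, min(fs_k, nrow(rk)))
      }
      xall <- work$values
      if (standardize == "fold") {
        st <- fit_standardizer(xall, train_idx)
        xall <- predict(st, xall)
      } else if (standardize == "global") {
        xall <- predict(global_std, matrix$values)
        xall <- xall[, colnames(work$values), drop = FALSE]
      }
      xtr <- xall[train_idx, , drop = FALSE]
      ytr <- labels[train_idx]
      xte <- xall[test_idx, , drop = FALSE]
      yte <- labels[test_idx]

      inner_tr <- .stratified_holdout(ytr, inner_train_frac,
                                      .child_seed(seed, r, f))
      for (li in seq_along(learners)) {
        spec <- learners[[li]]
        lseed <- .child_seed(seed, r, f, li)
        tuned <- .tune_learner(spec,
                               xtr[inner_tr, , drop = FALSE],
                               ytr[inner_tr],
                               xtr[-inner_tr, , drop = FALSE],
                               ytr[-inner_tr], lseed)
        fit <- .fit_learner(spec$family, spec$fixed, tuned$params,
                            xtr, ytr, lseed)
        sc <- fit$score(xte)
        # labels from the model's own classification rule where it has
        # one (RF vote, SVM sign); probability scores thresholded at 0.5
        pred <- if (!is.null(fit$classify)) fit$classify(xte) else
          ifelse(sc > 0.5, "ANTI", "NON_ANTI")
        results[[length(results) + 1L]] <- data.frame(
          `repeat` = r, fold = f, learner = spec$family,
          dataset = dataset_label,
          auc = compute_auc(sc, yte),
          accuracy = compute_accuracy(pred, yte),
          params = jsonlite::toJSON(tuned$params, auto_unbox = TRUE,
                                    digits = NA),
          inner_auc = tuned$inner_auc,
          stringsAsFactors = FALSE, check.names = FALSE)
        if (!is.null(fit$coefs) && length(fit$coefs))
          coefs[[length(coefs) + 1L]] <- data.frame(
            `repeat` = r, fold = f, feature = names(fit$coefs),
            beta = unname(fit$coefs),
            stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  structure(list(
    results = do.call(rbind, results),
    coefficients = if (length(coefs)) do.call(rbind, coefs) else NULL,
    config = list(outer_repeats = outer_repeats, outer_folds = outer_folds,
                  inner_train_frac = inner_train_frac, fs_k = fs_k,
                  fs_mode = fs_mode, standardize = standardize,
                  seed = seed, dataset_label = dataset_label,
                  learners = vapply(learners, `[[`, "", "family")),
    positive_class = "ANTI"), class = "nested_cv")
}

.subset_rows <- function(matrix, rows) {
  structure(list(ids = matrix$ids[rows],
                 labels = matrix$labels[rows],
                 values = matrix$values[rows, , drop = FALSE],
                 provenance = matrix$provenance),
            class = "descriptor_matrix")
}

#' Aggregate nested-CV results
#'
#' Per (learner, dataset): the mean AUC/accuracy over the folds of each
#' repeat, then the overall mean of the repeat means, with the spread
#' (standard deviation) of per-fold values.
#'
#' @param object A `nested_cv` object (or its `results` data frame).
#' @return List with `per_repeat` and `overall` data frames.
#' @export
aggregate_results <- function(object) {
  res <- if (inherits(object, "nested_cv")) object$results else object
  cfg <- if (inherits(object, "nested_cv")) object$config else NULL
  if (!is.null(cfg)) {
    expected <- cfg$outer_folds
    cnt <- stats::aggregate(fold ~ learner + dataset + `repeat`, res, length)
    if (any(cnt$fold != expected))
      stop("incomplete fold coverage: expected ", expected,
           " folds per (learner, dataset, repeat)")
  }
  per_repeat <- stats::aggregate(cbind(auc, accuracy) ~
                                   learner + dataset + `repeat`, res, mean)
  overall <- stats::aggregate(cbind(auc, accuracy) ~ learner + dataset,
                              per_repeat, mean)
  spread <- stats::aggregate(cbind(auc_sd = auc, accuracy_sd = accuracy) ~
                               learner + dataset, res, stats::sd)
  overall <- merge(overall, spread, by = c("learner", "dataset"))
  list(per_repeat = per_repeat[order(per_repeat$learner,
                                     per_repeat$dataset,
                                     per_repeat$`repeat`), ],
       overall = overall[order(overall$learner, overall$dataset), ])
}

#' Per-repeat AUC block matrix for model comparison
#'
#' Builds the N x k performance matrix consumed by the statistical
#' comparison cascade: rows are blocks (repeats by default, or individual
#' folds), columns are model configurations, values are AUC (or accuracy).
#'
#' @param ... One or more `nested_cv` objects; column labels are
#'   `learner_dataset`.
#' @param blocks `"repeat"` (N = outer repeats, per-repeat fold means) or
#'   `"fold"` (N = repeats x folds).
#' @param metric `"auc"` or `"accuracy"`.
#' @return Numeric matrix with labelled columns.
#' @export
performance_blocks <- function(..., blocks = c("repeat", "fold"),
                               metric = c("auc", "accuracy")) {
  blocks <- match.arg(blocks)
  metric <- match.arg(metric)
  res <- do.call(rbind, lapply(list(...), function(o)
    if (inherits(o, "nested_cv")) o$results else o))
  res$model <- paste(res$learner, res$dataset, sep = "_")
  if (blocks == "repeat") {
    agg <- stats::aggregate(res[[metric]],
                            list(model = res$model, b = res$`repeat`), mean)
  } else {
    agg <- stats::aggregate(res[[metric]],
                            list(model = res$model,
                                 b = paste(res$`repeat`, res$fold)), mean)
  }
  m <- stats::reshape(agg, idvar = "b", timevar = "model",
                      direction = "wide")
  rn <- m$b
  m <- as.matrix(m[, -1, drop = FALSE])
  colnames(m) <- sub("^x\\.", "", colnames(m))
  rownames(m) <- rn
  if (anyNA(m)) stop("unbalanced results: some model lacks blocks")
  m
}

#' @export
print.nested_cv <- function(x, ...) {
  cfg <- x$config
  cat("Nested cross-validation benchmark\n")
  cat(sprintf("  %d repeats x %d folds, learners: %s\n", cfg$outer_repeats,
              cfg$outer_folds, paste(cfg$learners, collapse = ", ")))
  if (!is.null(cfg$fs_k))
    cat(sprintf("  t-test filter: top %d features (%s mode)\n", cfg$fs_k,
                cfg$fs_mode))
  cat(sprintf("  standardization: %s; positive class: %s\n",
              cfg$standardize, x$positive_class))
  print(aggregate_results(x)$overall, row.names = FALSE)
  invisible(x)
}

#' @export
summary.nested_cv <- function(object, ...) {
  out <- aggregate_results(object)
  class(out) <- "summary.nested_cv"
  out
}

#' @export
print.summary.nested_cv <- function(x, ...) {
  cat("Overall (mean of repeat means):\n")
  print(x$overall, row.names = FALSE)
  cat("\nPer repeat:\n")
  print(x$per_repeat, row.names = FALSE)
  invisible(x)
}

#' @export
coef.nested_cv <- function(object, ...) object$coefficients

#' @export
plot.nested_cv <- function(x, metric = c("auc", "accuracy"), ...) {
  metric <- match.arg(metric)
  graphics::boxplot(x$results[[metric]] ~ x$results$learner,
                    xlab = "learner", ylab = toupper(metric), ...)
  invisible(x)
}
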