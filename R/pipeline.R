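# End-to-end orchestration: generate/load -> featurize -> select ->
# evaluate -> compare -> importance, with every stage artifact written to
# an output directory. A run is fully determined by its config.

#' Build a pipeline configuration
#'
#' @param input Either a `generator_config` (synthetic run) or a list
#'   `list(fasta = path, labels = path)` for real data (`labels` may be
#'   NULL when FASTA headers carry `|ANTI`/`|NON_ANTI` suffixes).
#' @param sets Descriptor sets to compute (merged in this order).
#' @param fs_k Filter subset size (NULL = no selection).
#' @param fs_mode,standardize Resampling scope of selection and
#'   standardization: `"fold"` (leakage-safe, default) or `"global"`.
#' @param learners Learner family names.
#' @param profile Grid profile, `"full"` or `"fast"`.
#' @param outer_repeats,outer_folds Outer resampling plan.
#' @param pseaac_lambda,pseaac_w PseAAC parameters.
#' @param alpha Significance level of the comparison cascade.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, sets = c("aac", "dc", "tc"),
                            fs_k = 200L, fs_mode = "fold",
                            standardize = "fold",
                            learners = c("RF", "KNN_WEIGHTED", "SVM_RBF",
                                         "GLMNET"),
                            profile = "fast",
                            outer_repeats = 5L, outer_folds = 10L,
                            pseaac_lambda = 3L, pseaac_w = 0.05,
                            alpha = 0.05, seed = 1L) {
  known <- c("RF", "KNN_WEIGHTED", "SVM_RBF", "GLMNET")
  bad <- setdiff(learners, known)
  if (length(bad))
    stop("unknown learner(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  if (!profile %in% c("full", "fast")) stop("unknown profile: ", profile)
  structure(list(input = input, sets = sets, fs_k = fs_k,
                 fs_mode = fs_mode, standardize = standardize,
                 learners = learners, profile = profile,
                 outer_repeats = as.integer(outer_repeats),
                 outer_folds = as.integer(outer_folds),
                 pseaac_lambda = pseaac_lambda, pseaac_w = pseaac_w,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Executes every stage and writes its artifacts to `out_dir`:
#' `dataset.fasta`, `labels.csv`, `rejected.csv`, `ranking.csv`,
#' `results.csv`, `coefficients.csv`, `comparison.txt`, `importance.csv`,
#' `composition.csv`, the effective `config.yaml` and a `manifest.txt`.
#' Identical config + seed produces byte-identical CSV artifacts.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory stage objects.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[angiopep] ", ...)
  t0 <- Sys.time()

  say("stage 1/6: dataset")
  if (inherits(config$input, "generator_config")) {
    dataset <- generate_dataset(config$input)
  } else {
    recs <- read_fasta(config$input$fasta)
    labs <- if (!is.null(config$input$labels))
      read_labels(config$input$labels) else NULL
    dataset <- labeled_dataset(recs, labs)
  }
  filtered <- filter_valid(dataset)
  dataset <- filtered$dataset
  labs <- stats::setNames(dataset$label, dataset$id)
  write_fasta(dataset, file.path(out_dir, "dataset.fasta"))
  write_labels(labs, file.path(out_dir, "labels.csv"))
  utils::write.csv(filtered$rejected, file.path(out_dir, "rejected.csv"),
                   row.names = FALSE)

  say("stage 2/6: descriptors (", paste(config$sets, collapse = ", "), ")")
  mat <- featurize_dataset(dataset, config$sets,
                           lambda = config$pseaac_lambda,
                           w = config$pseaac_w)
  full_mat <- mat
  mat <- remove_zero_features(mat)

  say("stage 3/6: t-test feature ranking")
  ranking <- rank_features_ttest(mat)
  utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                   row.names = FALSE)

  say("stage 4/6: nested cross-validation (",
      paste(config$learners, collapse = ", "), ", profile ",
      config$profile, ")")
  learners <- make_default_learners(ncol(mat$values),
                                    profile = config$profile,
                                    families = config$learners)
  cv <- run_nested_cv(mat, learners,
                      outer_repeats = config$outer_repeats,
                      outer_folds = config$outer_folds,
                      fs_k = config$fs_k, fs_mode = config$fs_mode,
                      standardize = config$standardize,
                      seed = config$seed,
                      dataset_label = paste(toupper(config$sets),
                                            collapse = "_"))
  utils::write.csv(cv$results, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  if (!is.null(cv$coefficients))
    utils::write.csv(cv$coefficients,
                     file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)

  say("stage 5/6: statistical comparison")
  comparison <- NULL
  if (length(config$learners) >= 2 && config$outer_repeats >= 2) {
    blocks <- performance_blocks(cv, blocks = "repeat", metric = "auc")
    comparison <- tryCatch(run_cascade(blocks, alpha = config$alpha),
                           error = function(e) e)
    sink(file.path(out_dir, "comparison.txt"))
    if (inherits(comparison, "error"))
      cat("comparison unavailable:", conditionMessage(comparison), "\n")
    else print(comparison)
    sink()
  }

  say("stage 6/6: importance")
  importance <- NULL
  if (!is.null(cv$coefficients)) {
    importance <- aggregate_betas(cv$coefficients,
                                  provenance = mat$provenance)
    utils::write.csv(importance, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
  }
  if (!is.null(config$fs_k)) {
    sel <- select_top_k(ranking, mat, min(config$fs_k,
                                          ncol(mat$values)))
    comp <- descriptor_composition(mat, sel)
    utils::write.csv(comp, file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
  }

  cfg_out <- config
  cfg_out$input <- if (inherits(config$input, "generator_config"))
    list(type = "synthetic", seed = config$input$seed,
         n_pos = config$input$n_pos, n_neg = config$input$n_neg)
  else c(list(type = "files"), config$input)
  yaml::write_yaml(unclass(cfg_out), file.path(out_dir, "config.yaml"))

  artifacts <- c("dataset.fasta", "labels.csv", "rejected.csv",
                 "ranking.csv", "results.csv", "config.yaml")
  if (!is.null(cv$coefficients))
    artifacts <- c(artifacts, "coefficients.csv", "importance.csv")
  if (!is.null(comparison)) artifacts <- c(artifacts, "comparison.txt")
  if (!is.null(config$fs_k)) artifacts <- c(artifacts, "composition.csv")
  writeLines(artifacts, file.path(out_dir, "manifest.txt"))
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))

  invisible(list(dataset = dataset, matrix = mat, full_matrix = full_mat,
                 ranking = ranking, cv = cv, comparison = comparison,
                 importance = importance, out_dir = out_dir))
}
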