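test_that("default grids match the benchmark specification", {
  lrn <- make_default_learners(3058)
  expect_equal(lrn$RF$grid$mtry[lrn$RF$grid$nodesize == 1], 1:55)
  expect_setequal(unique(lrn$RF$grid$nodesize), 1:3)
  expect_equal(lrn$RF$fixed$ntree, 1000L)
  expect_equal(lrn$KNN_WEIGHTED$grid$k, 1:5)
  expect_equal(nrow(lrn$SVM_RBF$grid), 625)
  expect_setequal(unique(lrn$SVM_RBF$grid$C), 2^(-12:12))
  expect_setequal(unique(lrn$SVM_RBF$grid$sigma), 2^(-12:12))
  expect_equal(nrow(lrn$GLMNET$grid), 45)
  expect_setequal(unique(lrn$GLMNET$grid$alpha),
                  c(0.0001, 0.001, 0.01, 0.1, 1))
  expect_setequal(unique(lrn$GLMNET$grid$lambda),
                  c(0, 0.15, 0.25, 0.35, 0.5, 0.65, 0.75, 0.85, 1))
})

test_that("AUC equals normalized Mann-Whitney pair counting", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.1, 0.2),
                           c("ANTI", "ANTI", "NON_ANTI", "NON_ANTI")), 1)
  expect_equal(compute_auc(rep(0.5, 6),
                           rep(c("ANTI", "NON_ANTI"), 3)), 0.5)
  labs <- c("ANTI", "NON_ANTI", "ANTI", "NON_ANTI")
  expect_equal(compute_auc(c(3, 1, 2, 0), labs), 1)
  expect_equal(compute_auc(c(3, 2, 1, 0), labs), 0.75)
  expect_error(compute_auc(1:3, rep("ANTI", 3)), "both classes")
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    scores <- sample(0:5, n, replace = TRUE) + rnorm(n, 0, 0.01)
    labs <- sample(c("ANTI", "NON_ANTI"), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c("ANTI", "NON_ANTI")
    expect_equal(compute_auc(scores, labs), oracle_auc(scores, labs))
  }
})

test_that("accuracy counts exact matches", {
  expect_equal(compute_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(compute_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(compute_accuracy(c("a", "a", "a", "b"),
                                c("a", "a", "a", "a")), 0.75)
  expect_error(compute_accuracy("a", c("a", "b")), "mismatch")
})

test_that("outer folds partition records and stay stratified", {
  labels <- rep(c("ANTI", "NON_ANTI"), c(107, 105))
  fold <- angiopep:::.stratified_folds(labels, 10, seed = 33)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 212)
  global_ratio <- 107 / 212
  for (f in 1:10) {
    in_f <- fold == f
    n_anti <- sum(labels[in_f] == "ANTI")
    # stratification keeps per-fold class counts within 1 of proportional
    expect_lte(abs(n_anti - global_ratio * sum(in_f)), 1)
  }
  # every record in exactly one fold per repeat: fold is a full assignment
  expect_false(anyNA(fold))
})

test_that("inner holdout is stratified and disjoint from outer test rows", {
  labels <- rep(c("ANTI", "NON_ANTI"), c(30, 30))
  tr <- angiopep:::.stratified_holdout(labels, 2 / 3, seed = 5)
  expect_equal(length(tr), 40)
  expect_equal(sum(labels[tr] == "ANTI"), 20)
  expect_true(all(tr %in% seq_along(labels)))
  expect_equal(anyDuplicated(tr), 0)
})

test_that("nested CV is deterministic and records complete fold coverage", {
  ds <- generate_dataset(separable_config(n_pos = 24, n_neg = 24, seed = 6))
  m <- remove_zero_features(featurize_dataset(ds, "aac"))
  lrn <- make_default_learners(20, profile = "fast",
                               families = c("KNN_WEIGHTED", "GLMNET"))
  cv1 <- run_nested_cv(m, lrn, outer_repeats = 2, outer_folds = 3, seed = 17)
  cv2 <- run_nested_cv(m, lrn, outer_repeats = 2, outer_folds = 3, seed = 17)
  expect_identical(cv1$results, cv2$results)
  expect_identical(cv1$coefficients, cv2$coefficients)
  expect_equal(nrow(cv1$results), 2 * 3 * 2)
  cnt <- table(cv1$results$learner, cv1$results$`repeat`)
  expect_true(all(cnt == 3))
})

test_that("aggregation equals brute-force recomputation", {
  ds <- generate_dataset(benchmark_config(seed = 19))
  m <- remove_zero_features(featurize_dataset(ds, "aac"))
  lrn <- make_default_learners(20, profile = "fast", families = "GLMNET")
  cv <- run_nested_cv(m, lrn, outer_repeats = 3, outer_folds = 4, seed = 2)
  agg <- aggregate_results(cv)
  res <- cv$results
  brute_rep <- sapply(1:3, function(r) mean(res$auc[res$`repeat` == r]))
  expect_equal(agg$per_repeat$auc, unname(brute_rep))
  expect_equal(agg$overall$auc, mean(brute_rep))
  # constant-result arithmetic
  fake <- res
  fake$auc <- 0.8; fake$accuracy <- 0.8
  agg2 <- aggregate_results(structure(list(results = fake, config = cv$config),
                                      class = "nested_cv"))
  expect_equal(agg2$overall$auc, 0.8)
  expect_equal(agg2$overall$auc_sd, 0)
  # incomplete coverage is an error
  expect_error(aggregate_results(structure(
    list(results = res[-1, ], config = cv$config), class = "nested_cv")),
    "incomplete fold coverage")
})

test_that("elastic net at lambda=0 approaches unpenalized logistic regression", {
  set.seed(23)
  n <- 200
  x <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- 0.8 * x[, "a"] - 0.5 * x[, "b"]
  y <- ifelse(runif(n) < plogis(eta), "ANTI", "NON_ANTI")
  fit <- angiopep:::.fit_learner("GLMNET", list(),
                                 list(alpha = 0.5, lambda = 0), x, y, 1)
  ref <- glm(I(y == "ANTI") ~ a + b, data = data.frame(x, y = y),
             family = binomial())
  expect_equal(unname(fit$coefs[c("a", "b")]),
               unname(coef(ref)[c("a", "b")]), tolerance = 0.05)
})

test_that("non-finite descriptors and missing classes are rejected", {
  ds <- generate_dataset(separable_config(n_pos = 10, n_neg = 10, seed = 3))
  m <- remove_zero_features(featurize_dataset(ds, "aac"))
  lrn <- make_default_learners(20, profile = "fast", families = "GLMNET")
  bad <- m; bad$values[1, 1] <- NaN
  expect_error(run_nested_cv(bad, lrn), "non-finite")
  expect_error(run_nested_cv(m, lrn, labels = rep("ANTI", 20)),
               "at least 2")
})
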