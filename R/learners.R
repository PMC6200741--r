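# Learner families and their hyperparameter grids. Tuning iterates grids
# in the documented row order (first column varying fastest); ties in the
# inner-validation score keep the first best combination, so selection is
# deterministic.

#' Default learner specifications and hyperparameter grids
#'
#' The four benchmarked families with their tuning grids:
#' \itemize{
#'   \item RF: `mtry` 1..floor(sqrt(p_max)), `nodesize` 1..3, fixed
#'     `ntree` = 1000;
#'   \item distance-weighted k-NN (Minkowski/Euclidean): `k` 1..5;
#'   \item SVM with RBF kernel: `C` and `sigma` over 2^-12 .. 2^12 in
#'     powers of two (625 combinations);
#'   \item elastic-net logistic regression (glmnet): `alpha` in (0.0001,
#'     0.001, 0.01, 0.1, 1), `lambda` in (0, 0.15, 0.25, 0.35, 0.5, 0.65,
#'     0.75, 0.85, 1).
#' }
#' The `"fast"` profile thins the RF/SVM/glmnet grids and reduces the RF
#' forest to 200 trees for quick exploratory runs; grid structure and
#' tuning logic are unchanged.
#'
#' @param p_max Number of features of the largest dataset to be evaluated
#'   (sets the RF `mtry` upper limit).
#' @param profile `"full"` (benchmark grids) or `"fast"`.
#' @param families Subset of `c("RF", "KNN_WEIGHTED", "SVM_RBF",
#'   "GLMNET")`.
#' @return Named list of `learner_spec` objects (`family`, `grid`,
#'   `fixed`).
#' @export
make_default_learners <- function(p_max,
                                  profile = c("full", "fast"),
                                  families = c("RF", "KNN_WEIGHTED",
                                               "SVM_RBF", "GLMNET")) {
  profile <- match.arg(profile)
  stopifnot(p_max >= 1)
  families <- match.arg(families, several.ok = TRUE)
  mtry_max <- max(1L, floor(sqrt(p_max)))
  specs <- list(
    RF = list(
      family = "RF",
      grid = if (profile == "full")
        expand.grid(mtry = seq_len(mtry_max), nodesize = 1:3)
      else
        expand.grid(mtry = unique(c(1L, max(1L, mtry_max %/% 2), mtry_max)),
                    nodesize = c(1L, 3L)),
      fixed = list(ntree = if (profile == "full") 1000L else 200L)),
    KNN_WEIGHTED = list(
      family = "KNN_WEIGHTED",
      grid = expand.grid(k = 1:5),
      fixed = list()),
    SVM_RBF = list(
      family = "SVM_RBF",
      grid = if (profile == "full")
        expand.grid(C = 2^(-12:12), sigma = 2^(-12:12))
      else
        expand.grid(C = 2^seq(-4, 4, 2), sigma = 2^seq(-4, 4, 2)),
      fixed = list()),
    GLMNET = list(
      family = "GLMNET",
      grid = if (profile == "full")
        expand.grid(alpha = c(0.0001, 0.001, 0.01, 0.1, 1),
                    lambda = c(0, 0.15, 0.25, 0.35, 0.5, 0.65, 0.75,
                               0.85, 1))
      else
        expand.grid(alpha = c(0.01, 1),
                    lambda = c(0, 0.25, 0.5, 1)),
      fixed = list()))
  specs <- specs[families]
  lapply(specs, function(s) structure(s, class = "learner_spec"))
}

.as_class_factor <- function(labels) {
  factor(labels, levels = CLASS_LEVELS)  # ANTI is the positive (2nd) level
}

# Distance-weighted k-NN scores: P(ANTI)-like vote with weights 1/d.
.knn_scores <- function(xtr, ytr, xte, k) {
  pos <- ytr == "ANTI"
  apply(xte, 1, function(row) {
    d <- sqrt(colSums((t(xtr) - row)^2))
    ord <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
    w <- 1 / pmax(d[ord], 1e-8)
    sum(w[pos[ord]]) / sum(w)
  })
}

# Fit one learner at fixed hyperparameters; returns a scoring closure
# (higher score = more ANTI-like) plus glmnet coefficients when relevant.
.fit_learner <- function(family, fixed, params, xtr, ytr, seed) {
  yf <- .as_class_factor(ytr)
  set.seed(seed)
  if (family == "RF") {
    m <- randomForest::randomForest(
      x = xtr, y = yf, ntree = fixed$ntree,
      mtry = min(params$mtry, ncol(xtr)), nodesize = params$nodesize)
    list(score = function(x) unname(predict(m, x, type = "prob")[, "ANTI"]),
         classify = function(x) as.character(predict(m, x, type = "response")),
         coefs = NULL)
  } else if (family == "KNN_WEIGHTED") {
    list(score = function(x) .knn_scores(xtr, ytr, x, params$k),
         coefs = NULL)
  } else if (family == "SVM_RBF") {
    m <- kernlab::ksvm(xtr, yf, kernel = "rbfdot",
                       kpar = list(sigma = params$sigma), C = params$C,
                       scaled = FALSE)
    dtr <- predict(m, xtr, type = "decision")[, 1]
    # orient decision values so ANTI scores higher, whatever internal
    # coding ksvm picked for this training set
    flip <- mean(dtr[ytr == "ANTI"]) < mean(dtr[ytr != "ANTI"])
    list(score = function(x) {
      d <- predict(m, x, type = "decision")[, 1]
      if (flip) -d else d
    }, classify = function(x) as.character(predict(m, x, type = "response")),
    coefs = NULL, decision_scores = TRUE)
  } else if (family == "GLMNET") {
    m <- glmnet::glmnet(xtr, yf, family = "binomial",
                        alpha = params$alpha,
                        lambda = .glmnet_lambda_path(params$lambda),
                        maxit = 500000L)
    cf <- as.matrix(stats::coef(m, s = params$lambda, exact = FALSE))[, 1]
    list(score = function(x)
      as.numeric(predict(m, x, type = "response", s = params$lambda)),
      coefs = cf[setdiff(names(cf), "(Intercept)")])
  } else stop("unknown learner family: ", family)
}

# glmnet is fitted along a decreasing path containing the requested
# lambda, which makes coefficient extraction at that lambda exact.
.glmnet_lambda_path <- function(lambda) {
  sort(unique(c(1, 0.85, 0.75, 0.65, 0.5, 0.35, 0.25, 0.15, lambda)),
       decreasing = TRUE)
}

# Grid search on a single inner holdout: returns the first grid row
# achieving the best validation AUC.
.tune_learner <- function(spec, xtr, ytr, xval, yval, seed) {
  grid <- spec$grid
  best <- list(auc = -Inf, row = 1L)
  if (spec$family == "GLMNET") {
    # one path fit per alpha scores every lambda in the grid
    alphas <- unique(grid$alpha)
    lambdas <- unique(grid$lambda)
    yf <- .as_class_factor(ytr)
    aucs <- matrix(NA_real_, nrow(grid), 1)
    for (a in alphas) {
      set.seed(seed)
      m <- glmnet::glmnet(xtr, yf, family = "binomial", alpha = a,
                          lambda = sort(lambdas, decreasing = TRUE))
      pr <- predict(m, xval, type = "response", s = lambdas)
      for (li in seq_along(lambdas)) {
        rows <- which(grid$alpha == a & grid$lambda == lambdas[li])
        aucs[rows, 1] <- compute_auc(pr[, li], yval)
      }
    }
    best_row <- which(aucs[, 1] == max(aucs[, 1]))[1]
    return(list(params = as.list(grid[best_row, , drop = FALSE]),
                inner_auc = aucs[best_row, 1]))
  }
  for (i in seq_len(nrow(grid))) {
    fit <- .fit_learner(spec$family, spec$fixed,
                        as.list(grid[i, , drop = FALSE]), xtr, ytr, seed)
    auc <- compute_auc(fit$score(xval), yval)
    if (auc > best$auc) best <- list(auc = auc, row = i)
  }
  list(params = as.list(grid[best$row, , drop = FALSE]),
       inner_auc = best$auc)
}
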