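# Significance cascade for comparing model performance vectors:
# Shapiro-Wilk and Bartlett gates, Friedman test with the Iman-Davenport
# F extension, and Finner step-down post-hoc adjustment against the
# best-ranked control model.

#' Shapiro-Wilk normality gate
#'
#' @param values Pooled numeric performance values (3 <= n <= 5000).
#' @param alpha Significance level.
#' @return List `W`, `p`, `reject_normality`.
#' @export
gate_normality <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("Shapiro-Wilk needs at least 3 values")
  if (stats::sd(values) == 0) stop("degenerate input: zero variance")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       reject_normality = sw$p.value < alpha)
}

#' Bartlett homoscedasticity gate
#'
#' Bartlett's K-squared across the k model columns with k - 1 degrees of
#' freedom.
#'
#' @param matrix N x k performance block matrix (columns = models).
#' @param alpha Significance level.
#' @return List `K2`, `df`, `p`, `equal_variances_rejected`.
#' @export
gate_homoscedasticity <- function(matrix, alpha = 0.05) {
  if (any(apply(matrix, 2, stats::sd) == 0))
    stop("zero-variance column in performance matrix")
  groups <- lapply(seq_len(ncol(matrix)), function(j) matrix[, j])
  bt <- stats::bartlett.test(groups)
  list(K2 = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value, equal_variances_rejected = bt$p.value < alpha)
}

#' Friedman test with the Iman-Davenport extension
#'
#' Ranks the k models within each of the N blocks (ties get mean ranks)
#' and computes the tie-corrected Friedman chi-square and the
#' Iman-Davenport F statistic
#' `F = (N - 1) chi2 / (N (k - 1) - chi2)` with `(k - 1, (k - 1)(N - 1))`
#' degrees of freedom, a less conservative version of the same null
#' hypothesis that all models perform equally.
#'
#' @param matrix N x k performance block matrix.
#' @return List `chi2`, `F`, `df1`, `df2`, `p`, `avg_ranks` (named, larger
#'   performance = larger rank), `degenerate` (TRUE when all blocks are
#'   perfectly concordant, making the F denominator zero; `p` is then
#'   reported as 0 with this flag set).
#' @export
friedman_iman_davenport <- function(matrix) {
  N <- nrow(matrix); k <- ncol(matrix)
  if (N < 2 || k < 2) stop("need at least 2 blocks and 2 models")
  R <- t(apply(matrix, 1, rank))
  Rbar <- colMeans(R)
  # tie-corrected chi-square (reduces to the classic formula without ties)
  ss_total <- sum((R - (k + 1) / 2)^2)
  chi2 <- if (ss_total == 0) 0 else
    (k - 1) * N * sum((Rbar - (k + 1) / 2)^2) / (ss_total / N)
  den <- N * (k - 1) - chi2
  df1 <- k - 1; df2 <- (k - 1) * (N - 1)
  if (abs(den) < 1e-12) {
    out <- list(chi2 = chi2, F = Inf, df1 = df1, df2 = df2, p = 0,
                avg_ranks = stats::setNames(Rbar, colnames(matrix)),
                degenerate = TRUE)
    return(out)
  }
  Fid <- (N - 1) * chi2 / den
  list(chi2 = chi2, F = Fid, df1 = df1, df2 = df2,
       p = stats::pf(Fid, df1, df2, lower.tail = FALSE),
       avg_ranks = stats::setNames(Rbar, colnames(matrix)),
       degenerate = FALSE)
}

#' Finner post-hoc comparisons against a control model
#'
#' For every non-control model, the rank-difference z statistic
#' `z = (Rbar_i - Rbar_c) / sqrt(k (k + 1) / (6 N))` with a two-sided
#' normal p-value, adjusted by the Finner step-down procedure
#' `APV_(i) = max_(j <= i) min(1, 1 - (1 - p_(j))^((k - 1) / j))`.
#'
#' @param matrix N x k performance block matrix.
#' @param control Column label of the control (reference) model.
#' @param alpha Significance level for the decisions.
#' @return Data frame `model`, `z`, `p_raw`, `p_adjusted`, `rejected`,
#'   ordered by ascending raw p.
#' @export
finner_posthoc <- function(matrix, control, alpha = 0.05) {
  if (!control %in% colnames(matrix))
    stop("control model '", control, "' not found")
  N <- nrow(matrix); k <- ncol(matrix)
  Rbar <- colMeans(t(apply(matrix, 1, rank)))
  se <- sqrt(k * (k + 1) / (6 * N))
  others <- setdiff(colnames(matrix), control)
  z <- (Rbar[others] - Rbar[control]) / se
  p <- 2 * stats::pnorm(-abs(z))
  ord <- order(p, others)
  p_sorted <- p[ord]
  adj <- pmin(1, 1 - (1 - p_sorted)^((k - 1) / seq_along(p_sorted)))
  adj <- cummax(adj)
  out <- data.frame(model = others[ord], z = unname(z[ord]),
                    p_raw = unname(p_sorted), p_adjusted = unname(adj),
                    rejected = unname(adj < alpha),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full model-comparison cascade
#'
#' Checks normality (Shapiro-Wilk on the pooled values) and
#' homoscedasticity (Bartlett); if either parametric condition fails — the
#' expected outcome for bounded AUC data — proceeds nonparametrically with
#' the Friedman / Iman-Davenport test and, when that rejects, Finner
#' post-hoc comparisons against the control model (highest mean
#' performance; ties broken by average rank, then label order). Models
#' whose adjusted p is >= alpha are reported as statistically
#' indistinguishable from the control.
#'
#' @param matrix N x k performance block matrix (e.g. from
#'   [performance_blocks()]).
#' @param alpha Significance level throughout.
#' @return A `comparison_report` list with the gate results, omnibus
#'   statistics, control label, post-hoc table and
#'   `indistinguishable_from_control`.
#' @export
run_cascade <- function(matrix, alpha = 0.05) {
  norm <- gate_normality(as.vector(matrix), alpha)
  hom <- gate_homoscedasticity(matrix, alpha)
  parametric_ok <- !norm$reject_normality && !hom$equal_variances_rejected
  fried <- friedman_iman_davenport(matrix)
  means <- colMeans(matrix)
  best <- max(means)
  cand <- colnames(matrix)[means == best]
  if (length(cand) > 1) {
    rk <- fried$avg_ranks[cand]
    cand <- cand[order(-rk, cand)]
  }
  control <- cand[1]
  post <- NULL
  indist <- setdiff(colnames(matrix), control)
  if (fried$p < alpha) {
    post <- finner_posthoc(matrix, control, alpha)
    indist <- post$model[!post$rejected]
  }
  structure(list(normality = norm, homoscedasticity = hom,
                 parametric_conditions_met = parametric_ok,
                 friedman = fried, control = control, posthoc = post,
                 indistinguishable_from_control = indist,
                 alpha = alpha, positive_direction = "higher is better"),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison cascade (alpha =", x$alpha, ")\n")
  cat(sprintf("  Shapiro-Wilk: W = %.4f, p = %.4g (%s)\n",
              x$normality$W, x$normality$p,
              if (x$normality$reject_normality) "normality rejected"
              else "normality not rejected"))
  cat(sprintf("  Bartlett: K2 = %.4f, df = %d, p = %.4g\n",
              x$homoscedasticity$K2, x$homoscedasticity$df,
              x$homoscedasticity$p))
  cat(sprintf("  Friedman chi2 = %.4f; Iman-Davenport F(%d, %d) = %.4f, p = %.4g%s\n",
              x$friedman$chi2, x$friedman$df1, x$friedman$df2,
              x$friedman$F, x$friedman$p,
              if (x$friedman$degenerate) " [degenerate: perfect concordance]"
              else ""))
  cat("  Control model:", x$control, "\n")
  if (!is.null(x$posthoc)) {
    cat("  Finner post-hoc vs control:\n")
    print(x$posthoc, row.names = FALSE)
  } else {
    cat("  Omnibus test not rejected; no post-hoc comparisons run.\n")
  }
  if (length(x$indistinguishable_from_control))
    cat("  Indistinguishable from control:",
        paste(x$indistinguishable_from_control, collapse = ", "), "\n")
  invisible(x)
}
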