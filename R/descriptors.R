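# Compositional molecular descriptors: amino-acid (AAC), dipeptide (DC)
# and tripeptide (TC) composition, plus parallel- (PC) and series- (SC)
# correlation pseudo-amino-acid composition. All raw compositions are
# fractions that sum to 1 per sequence.

.seq_idx <- function(sequence) {
  idx <- match(strsplit(toupper(sequence), "")[[1]], AA_ALPHABET)
  if (anyNA(idx)) stop("sequence contains non-standard residues")
  idx
}

.DC_NAMES <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
.TC_NAMES <- paste0(rep(AA_ALPHABET, each = 400L),
                    rep(rep(AA_ALPHABET, each = 20L), times = 20L),
                    rep(AA_ALPHABET, times = 400L))

#' Amino-acid composition (AAC)
#'
#' Fraction of each of the 20 residue types in the sequence: component i is
#' the count of residue i divided by the sequence length.
#'
#' @param sequence Valid peptide string, length >= 1.
#' @return Named 20-vector of fractions summing to 1 (order A, C, D, ..., Y).
#' @export
compute_aac <- function(sequence) {
  idx <- .seq_idx(sequence)
  if (!length(idx)) stop("empty sequence")
  stats::setNames(tabulate(idx, 20) / length(idx), AA_ALPHABET)
}

#' Dipeptide composition (DC)
#'
#' Fraction of each of the 400 possible residue pairs among the L - 1
#' overlapping adjacent windows of the sequence.
#'
#' @param sequence Valid peptide string, length >= 2.
#' @return Named 400-vector of fractions summing to 1 (lexicographic order
#'   AA, AC, ..., YY).
#' @export
compute_dc <- function(sequence) {
  idx <- .seq_idx(sequence)
  L <- length(idx)
  if (L < 2) stop("DC requires length >= 2")
  code <- (idx[-L] - 1L) * 20L + idx[-1L]
  stats::setNames(tabulate(code, 400L) / (L - 1L), .DC_NAMES)
}

#' Tripeptide composition (TC)
#'
#' Fraction of each of the 20^3 = 8000 possible residue triples among the
#' L - 2 overlapping adjacent windows of the sequence.
#'
#' @param sequence Valid peptide string, length >= 3.
#' @return Named 8000-vector of fractions summing to 1 (lexicographic
#'   order AAA, AAC, ..., YYY).
#' @export
compute_tc <- function(sequence) {
  idx <- .seq_idx(sequence)
  L <- length(idx)
  if (L < 3) stop("TC requires length >= 3")
  code <- (idx[1:(L - 2)] - 1L) * 400L + (idx[2:(L - 1)] - 1L) * 20L +
    idx[3:L]
  stats::setNames(tabulate(code, 8000L) / (L - 2L), .TC_NAMES)
}

#' Parallel-correlation pseudo-amino-acid composition (type 1)
#'
#' AAC augmented with `lambda` sequence-order correlation factors. The
#' j-th factor is the mean over positions i of
#' Theta(R_i, R_\{i+j\}), where Theta(a, b) averages the squared difference
#' of the three standardized residue properties. Components are normalised
#' so the full vector sums to 1: the first 20 are f_u / (sum f + w sum
#' theta), the last lambda are w theta_j / (sum f + w sum theta).
#'
#' @param sequence Valid peptide string, length > lambda.
#' @param lambda Number of correlation tiers (>= 1).
#' @param w Weight of the sequence-order part (> 0); conventional 0.05.
#' @param props Property matrix from [pseaac_properties()].
#' @return Named (20 + lambda)-vector, nonnegative, summing to 1.
#' @export
compute_pc_pseaac <- function(sequence, lambda = 3L, w = 0.05,
                              props = pseaac_properties()) {
  idx <- .seq_idx(sequence)
  L <- length(idx)
  if (L <= lambda)
    stop("PC-PseAAC requires length > lambda (length ", L,
         ", lambda ", lambda, ")")
  f <- tabulate(idx, 20) / L
  P <- props[idx, , drop = FALSE]
  theta <- vapply(seq_len(lambda), function(j) {
    d <- P[1:(L - j), , drop = FALSE] - P[(1 + j):L, , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  den <- sum(f) + w * sum(theta)
  stats::setNames(c(f, w * theta) / den,
                  c(AA_ALPHABET, sprintf("theta%d", seq_len(lambda))))
}

#' Series-correlation pseudo-amino-acid composition (type 2)
#'
#' AAC augmented with 2 * lambda per-property correlation factors computed
#' separately for hydrophobicity and hydrophilicity:
#' tau_\{2(j-1)+g\} is the mean over positions of H_g(R_i) * H_g(R_\{i+j\}).
#' Normalisation as in the parallel variant (denominator sum f + w sum tau).
#' Because products of standardized properties can be negative, individual
#' pseudo components may be negative; the vector still sums to 1.
#'
#' @inheritParams compute_pc_pseaac
#' @return Named (20 + 2 * lambda)-vector summing to 1.
#' @export
compute_sc_pseaac <- function(sequence, lambda = 3L, w = 0.05,
                              props = pseaac_properties()) {
  idx <- .seq_idx(sequence)
  L <- length(idx)
  if (L <= lambda)
    stop("SC-PseAAC requires length > lambda (length ", L,
         ", lambda ", lambda, ")")
  f <- tabulate(idx, 20) / L
  H <- props[, c("hydrophobicity", "hydrophilicity"), drop = FALSE]
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    for (g in 1:2) {
      tau[2 * (j - 1) + g] <-
        mean(H[idx[1:(L - j)], g] * H[idx[(1 + j):L], g])
    }
  }
  den <- sum(f) + w * sum(tau)
  nm <- c(AA_ALPHABET,
          paste0("tau", rep(seq_len(lambda), each = 2), "_",
                 rep(c("hb", "hl"), lambda)))
  stats::setNames(c(f, w * tau) / den, nm)
}

#' Featurize a labelled dataset into a descriptor matrix
#'
#' Computes the requested descriptor sets for every record and concatenates
#' them column-wise in the requested order, with namespaced feature names
#' (`AAC:`, `DC:`, `TC:`, `PCPSE:`, `SCPSE:`) so the descriptor of origin
#' of every feature is retained.
#'
#' @param dataset A `labeled_dataset`.
#' @param sets Character vector from `c("aac", "dc", "tc", "pcpse",
#'   "scpse")`.
#' @param lambda,w PseAAC parameters (used only when a PseAAC set is
#'   requested).
#' @return A `descriptor_matrix`: list with `ids`, `labels`, `values`
#'   (n x p numeric matrix with namespaced column names) and `provenance`
#'   (named character vector mapping feature -> descriptor set).
#' @export
featurize_dataset <- function(dataset, sets = c("aac", "dc", "tc"),
                              lambda = 3L, w = 0.05) {
  sets <- match.arg(tolower(sets),
                    c("aac", "dc", "tc", "pcpse", "scpse"),
                    several.ok = TRUE)
  props <- pseaac_properties()
  fns <- list(
    aac   = function(s) compute_aac(s),
    dc    = function(s) compute_dc(s),
    tc    = function(s) compute_tc(s),
    pcpse = function(s) compute_pc_pseaac(s, lambda, w, props),
    scpse = function(s) compute_sc_pseaac(s, lambda, w, props))
  prefix <- c(aac = "AAC", dc = "DC", tc = "TC",
              pcpse = "PCPSE", scpse = "SCPSE")
  blocks <- lapply(sets, function(set) {
    rows <- lapply(seq_len(nrow(dataset)), function(i) {
      tryCatch(fns[[set]](dataset$sequence[i]), error = function(e)
        stop("record '", dataset$id[i], "' unusable for descriptor ",
             toupper(set), ": ", conditionMessage(e), call. = FALSE))
    })
    m <- do.call(rbind, rows)
    colnames(m) <- paste0(prefix[[set]], ":", colnames(m))
    m
  })
  values <- do.call(cbind, blocks)
  rownames(values) <- dataset$id
  prov <- rep(prefix[sets], vapply(blocks, ncol, integer(1)))
  names(prov) <- colnames(values)
  structure(list(ids = dataset$id, labels = dataset$label,
                 values = values, provenance = prov),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("Descriptor matrix:", nrow(x$values), "peptides x",
      ncol(x$values), "features\n")
  cat("Sets:", paste(sprintf("%s (%d)", names(table(x$provenance)),
                             table(x$provenance)), collapse = ", "), "\n")
  invisible(x)
}

.subset_features <- function(matrix, keep) {
  structure(list(ids = matrix$ids, labels = matrix$labels,
                 values = matrix$values[, keep, drop = FALSE],
                 provenance = matrix$provenance[keep]),
            class = "descriptor_matrix")
}

#' Drop features that are zero in every observation
#'
#' @param matrix A `descriptor_matrix`.
#' @return The matrix restricted to columns with at least one nonzero
#'   value; column order preserved.
#' @export
remove_zero_features <- function(matrix) {
  keep <- colSums(matrix$values != 0) > 0
  .subset_features(matrix, which(keep))
}

#' Fit a column standardizer on a row subset
#'
#' Learns per-feature mean and standard deviation (sample convention,
#' n - 1 denominator) on the fitting rows only, so the transform can be
#' applied to held-out rows without information leakage. Features with zero
#' spread on the fitting rows are mapped to 0.
#'
#' @param matrix A `descriptor_matrix` (or plain numeric matrix).
#' @param fit_rows Row indices to learn statistics from; default all rows.
#' @return A `standardizer` with `mean` and `sd` vectors.
#' @export
fit_standardizer <- function(matrix, fit_rows = NULL) {
  v <- if (inherits(matrix, "descriptor_matrix")) matrix$values else matrix
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(v))
  if (!length(fit_rows)) stop("fit_rows is empty")
  sub <- v[fit_rows, , drop = FALSE]
  structure(list(mean = colMeans(sub), sd = apply(sub, 2, stats::sd)),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param object A `standardizer`.
#' @param newdata A `descriptor_matrix` or numeric matrix with the same
#'   columns the standardizer was fitted on.
#' @param ... Unused.
#' @return Object of the same kind as `newdata`, standardized.
#' @export
predict.standardizer <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "descriptor_matrix")) newdata$values else newdata
  sd <- ifelse(object$sd == 0, 1, object$sd)
  out <- sweep(sweep(v, 2, object$mean), 2, sd, "/")
  out[, object$sd == 0] <- 0
  if (inherits(newdata, "descriptor_matrix")) {
    newdata$values <- out
    newdata
  } else out
}

#' Serialize a descriptor matrix to CSV
#'
#' First column `id`, optional `label` column, then one column per
#' namespaced feature.
#'
#' @param matrix A `descriptor_matrix`.
#' @param path Output path.
#' @param with_labels Include the label column.
#' @export
write_descriptor_csv <- function(matrix, path, with_labels = TRUE) {
  df <- data.frame(id = matrix$ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (with_labels && !is.null(matrix$labels)) df$label <- matrix$labels
  df <- cbind(df, as.data.frame(matrix$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
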