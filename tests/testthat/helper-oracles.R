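# Independent brute-force oracles used to check the package's formula
# implementations. Each is written as the most direct transcription of
# the definition, with no shared code with the implementation under test.

AA <- angiopep::AA_ALPHABET

random_peptide <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

# -- compositions: count substrings directly ------------------------------

oracle_aac <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  vapply(AA, function(a) sum(chars == a), numeric(1)) / length(chars)
}

oracle_kmer <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  wins <- vapply(seq_len(L - k + 1),
                 function(i) paste(chars[i:(i + k - 1)], collapse = ""),
                 character(1))
  all_kmers <- AA
  for (j in seq_len(k - 1)) all_kmers <- as.vector(outer(all_kmers, AA, paste0))
  counts <- vapply(all_kmers, function(m) sum(wins == m), numeric(1))
  counts / length(wins)
}

# -- PseAAC: literal double-summation transcription -----------------------

oracle_pc_pseaac <- function(seq, lambda, w, props) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- oracle_aac(seq)
  theta <- numeric(lambda)
  for (j in 1:lambda) {
    acc <- 0
    for (i in 1:(L - j)) {
      a <- props[chars[i], ]; b <- props[chars[i + j], ]
      acc <- acc + mean((a - b)^2)
    }
    theta[j] <- acc / (L - j)
  }
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

oracle_sc_pseaac <- function(seq, lambda, w, props) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- oracle_aac(seq)
  tau <- numeric(2 * lambda)
  for (j in 1:lambda) {
    for (g in 1:2) {
      acc <- 0
      for (i in 1:(L - j))
        acc <- acc + props[chars[i], g] * props[chars[i + j], g]
      tau[2 * (j - 1) + g] <- acc / (L - j)
    }
  }
  unname(c(f, w * tau) / (sum(f) + w * sum(tau)))
}

# -- Welch t-test: closed-form formula ------------------------------------

oracle_welch <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- var(x1); v2 <- var(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x1) - mean(x2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# -- AUC: exhaustive pair counting ----------------------------------------

oracle_auc <- function(scores, labels) {
  pos <- which(labels == "ANTI"); neg <- which(labels != "ANTI")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# -- Friedman / Iman-Davenport: column-rank-sum form ----------------------

oracle_friedman <- function(m) {
  N <- nrow(m); k <- ncol(m)
  R <- apply(m, 1, rank)            # k x N
  Rj <- rowSums(R)                  # column rank sums
  num <- (k - 1) * (sum(Rj^2) - N^2 * k * (k + 1)^2 / 4)
  den <- sum(R^2) - N * k * (k + 1)^2 / 4
  chi2 <- if (den == 0) 0 else num / den
  Fid <- (N - 1) * chi2 / (N * (k - 1) - chi2)
  list(chi2 = chi2, F = Fid,
       p = pf(Fid, k - 1, (k - 1) * (N - 1), lower.tail = FALSE))
}

# -- Finner step-down adjustment ------------------------------------------

oracle_finner_adjust <- function(p_sorted, k) {
  adj <- numeric(length(p_sorted))
  run_max <- 0
  for (i in seq_along(p_sorted)) {
    v <- min(1, 1 - (1 - p_sorted[i])^((k - 1) / i))
    run_max <- max(run_max, v)
    adj[i] <- run_max
  }
  adj
}

# -- Needleman-Wunsch identity: explicit DP with traceback ----------------

oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in 1:n) for (j in 1:m) {
    S[i + 1, j + 1] <- max(S[i, j] + (A[i] == B[j]),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  }
  # traceback (prefer diagonal, then up, then left)
  i <- n; j <- m; matches <- 0; alen <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1
  }
  matches / alen
}

# -- small labelled dataset built in code ---------------------------------

toy_dataset <- function() {
  recs <- data.frame(
    id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    sequence = c("ACDEFG", "ACDEFH", "GGGGGG", "SPSPSP", "LSLLSL", "TCTCTC"),
    stringsAsFactors = FALSE)
  labs <- setNames(c("ANTI", "ANTI", "NON_ANTI", "ANTI", "NON_ANTI",
                     "NON_ANTI"), recs$id)
  labeled_dataset(recs, labs)
}
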