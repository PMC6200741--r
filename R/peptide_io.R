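# Reading, validating and writing labelled peptide sequence data.


#' Read peptide sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a data frame of peptide
#' records. Sequences are uppercased and stripped of whitespace; the record
#' id is the first whitespace-delimited token of the header. A header suffix
#' `|ANTI` or `|NON_ANTI` is recognised as an embedded activity label and
#' split off into a `label` column (NA where absent).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence` and `label`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); labels <- character(0)
  cur_id <- NULL; cur_label <- NA_character_; cur_seq <- character(0)
  flush <- function(line_no) {
    seq <- gsub("\\s", "", paste(cur_seq, collapse = ""))
    if (!nzchar(seq))
      stop("FASTA parse error at line ", line_no, ": entry '", cur_id,
           "' has no sequence")
    ids <<- c(ids, cur_id); seqs <<- c(seqs, toupper(seq))
    labels <<- c(labels, cur_label)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      if (!is.null(cur_id)) flush(i)
      header <- trimws(sub("^>", "", line))
      token <- strsplit(header, "\\s+")[[1]][1]
      if (is.na(token) || !nzchar(token))
        stop("FASTA parse error at line ", i, ": empty header")
      cur_label <- NA_character_
      if (grepl("\\|(ANTI|NON_ANTI)$", token)) {
        cur_label <- sub("^.*\\|", "", token)
        token <- sub("\\|(ANTI|NON_ANTI)$", "", token)
      }
      cur_id <- token; cur_seq <- character(0)
    } else {
      if (is.null(cur_id))
        stop("FASTA parse error at line ", i,
             ": sequence data before any header")
      cur_seq <- c(cur_seq, line)
    }
  }
  if (is.null(cur_id)) stop("FASTA parse error: file contains no entries")
  flush(length(lines) + 1L)
  if (anyDuplicated(ids))
    stop("duplicate record ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = seqs, label = labels,
             stringsAsFactors = FALSE)
}

#' Write peptide records to a FASTA file
#'
#' One unwrapped sequence line per record. When `labels` is supplied the
#' header carries the `id|LABEL` convention understood by [read_fasta()].
#'
#' @param records Data frame with columns `id` and `sequence`.
#' @param path Output path.
#' @param labels Optional named character vector (names = ids) of class
#'   labels to embed in headers.
#' @export
write_fasta <- function(records, path, labels = NULL) {
  hdr <- records$id
  if (!is.null(labels)) hdr <- paste0(hdr, "|", labels[records$id])
  writeLines(paste0(">", hdr, "\n", records$sequence), path, sep = "\n")
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path CSV/TSV file with header columns `id` and `label`; labels
#'   must be `ANTI` or `NON_ANTI`.
#' @return Named character vector of labels, names = ids.
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab)))
    stop("label table must have columns 'id' and 'label'")
  bad <- setdiff(unique(tab$label), CLASS_LEVELS)
  if (length(bad))
    stop("invalid label value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label table")
  stats::setNames(tab$label, tab$id)
}

#' Write a label table
#' @param labels Named character vector (names = ids).
#' @param path Output CSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(id = names(labels), label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a labelled peptide dataset
#'
#' Joins records and labels into the pipeline's canonical input container,
#' enforcing a one-to-one correspondence between record ids and label ids.
#'
#' @param records Data frame with columns `id`, `sequence` (a `label`
#'   column, as produced by [read_fasta()] on label-bearing headers, is
#'   used when `labels` is NULL).
#' @param labels Optional named character vector of `ANTI`/`NON_ANTI`.
#' @return A `labeled_dataset`: data frame `id`, `sequence`, `label`.
#' @export
labeled_dataset <- function(records, labels = NULL) {
  if (is.null(labels)) {
    if (!"label" %in% names(records) || anyNA(records$label))
      stop("no labels supplied and FASTA headers do not carry them")
    labels <- stats::setNames(records$label, records$id)
  }
  if (anyDuplicated(records$id)) stop("record ids are not unique")
  missing_lab <- setdiff(records$id, names(labels))
  if (length(missing_lab))
    stop("records without a label: ", paste(missing_lab, collapse = ", "))
  extra <- setdiff(names(labels), records$id)
  if (length(extra))
    stop("labels without a record: ", paste(extra, collapse = ", "))
  bad <- setdiff(unique(unname(labels)), CLASS_LEVELS)
  if (length(bad)) stop("invalid label value(s): ", paste(bad, collapse = ", "))
  out <- data.frame(id = records$id, sequence = toupper(records$sequence),
                    label = unname(labels[records$id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("labeled_dataset", "data.frame")
  out
}

#' Validate a single peptide sequence
#'
#' A record is invalid if its sequence contains any character outside the
#' 20-letter standard alphabet (ambiguity codes such as B, J, O, U, X, Z,
#' gap or stop symbols) or is shorter than 2 residues — the operational
#' reading of "correct nomenclature" used for dataset curation.
#'
#' @param sequence Peptide string (uppercased internally).
#' @return List with `valid` (logical) and `reason` (NA when valid).
#' @export
validate_record <- function(sequence) {
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2)
    return(list(valid = FALSE, reason = "length < 2"))
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    return(list(valid = FALSE,
                reason = sprintf("invalid character '%s' at position %d",
                                 chars[bad[1]], bad[1])))
  list(valid = TRUE, reason = NA_character_)
}

#' Remove invalid records from a labelled dataset
#'
#' Applies [validate_record()] to every record and drops the failures,
#' pruning the label map consistently.
#'
#' @param dataset A `labeled_dataset`.
#' @return List with `dataset` (the retained records) and `rejected`
#'   (data frame `id`, `reason`; zero rows when all records are valid).
#' @export
filter_valid <- function(dataset) {
  verdicts <- lapply(dataset$sequence, validate_record)
  ok <- vapply(verdicts, `[[`, logical(1), "valid")
  if (!any(ok)) stop("all records invalid; dataset unusable")
  rejected <- data.frame(
    id = dataset$id[!ok],
    reason = vapply(verdicts[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  kept <- dataset[ok, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("labeled_dataset", "data.frame")
  list(dataset = kept, rejected = rejected)
}

#' Pairwise sequence identity under global alignment
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a
#' linear gap penalty of -1; identity is the number of identical aligned
#' positions divided by the alignment length (gaps included). Used only for
#' dataset curation checks, not for modelling.
#'
#' @param a,b Peptide sequence strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  # canonical argument order makes the traceback tie-break, and hence the
  # reported identity, symmetric in (a, b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  if (identical(A, B)) return(1)
  n <- length(A); m <- length(B)
  # Needleman-Wunsch score matrix; rows filled with the max-plus prefix
  # trick so the left-gap recurrence is vectorized
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  jj <- 0:m
  for (i in seq_len(n)) {
    cand <- pmax(S[i, 1:m] + (A[i] == B), S[i, 2:(m + 1)] - 1)
    t <- cummax(c(S[i + 1, 1], cand) + jj)
    S[i + 1, ] <- t - jj
  }
  # traceback; among co-optimal moves prefer diagonal, then up, then left
  i <- n; j <- m; matches <- 0L; alen <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1L
  }
  matches / alen
}

#' Report peptide pairs at or above an identity threshold
#'
#' Curation check: a clean benchmark dataset contains no pair of peptides
#' with >= 70 percent pairwise identity. The comparison is inclusive.
#'
#' @param dataset A `labeled_dataset` with at least two records.
#' @param threshold Identity fraction; default 0.70.
#' @return Data frame `id_a`, `id_b`, `identity` (zero rows when the
#'   dataset satisfies the curation property).
#' @export
max_identity_check <- function(dataset, threshold = 0.70) {
  n <- nrow(dataset)
  if (n < 2) stop("need at least 2 records")
  out <- list()
  lens <- nchar(dataset$sequence)
  for (i in seq_len(n - 1)) {
    rest <- seq(i + 1, n)
    # identity <= min(len)/max(len): skip pairs that cannot reach threshold
    feasible <- pmin(lens[i], lens[rest]) / pmax(lens[i], lens[rest]) >=
      threshold
    idy <- rep(0, length(rest))
    idy[feasible] <- vapply(dataset$sequence[rest[feasible]],
                            pairwise_identity, numeric(1),
                            b = dataset$sequence[i], USE.NAMES = FALSE)
    hit <- which(idy >= threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        id_a = dataset$id[i], id_b = dataset$id[rest[hit]],
        identity = idy[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      identity = numeric(0)))
  do.call(rbind, out)
}
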