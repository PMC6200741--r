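test_that("AAC matches direct counting on fixed and random sequences", {
  aac <- compute_aac("ACDA")
  expect_equal(unname(aac[c("A", "C", "D")]), c(0.5, 0.25, 0.25))
  expect_equal(sum(aac), 1)
  expect_equal(unname(compute_aac("GGGG")["G"]), 1)
  expect_length(compute_aac("ACDE"), 20)
  set.seed(1)
  for (i in 1:20) {
    s <- random_peptide(sample(2:40, 1))
    expect_equal(compute_aac(s), oracle_aac(s)[names(compute_aac(s))])
  }
})

test_that("DC uses L-1 adjacent windows and matches counting", {
  dc <- compute_dc("AAAA")
  expect_equal(unname(dc["AA"]), 1)
  dc2 <- compute_dc("ACA")
  expect_equal(unname(dc2[c("AC", "CA")]), c(0.5, 0.5))
  expect_length(dc, 400)
  expect_error(compute_dc("A"), "length")
  set.seed(2)
  for (i in 1:15) {
    s <- random_peptide(sample(2:30, 1))
    impl <- compute_dc(s)
    expect_equal(impl, oracle_kmer(s, 2)[names(impl)])
  }
})

test_that("TC uses L-2 adjacent windows and matches counting", {
  tc <- compute_tc("ACDE")
  expect_equal(unname(tc[c("ACD", "CDE")]), c(0.5, 0.5))
  expect_equal(unname(compute_tc("AAAAA")["AAA"]), 1)
  expect_length(tc, 8000)
  expect_error(compute_tc("AC"), "length")
  set.seed(3)
  for (i in 1:10) {
    s <- random_peptide(sample(3:30, 1))
    impl <- compute_tc(s)
    expect_equal(impl, oracle_kmer(s, 3)[names(impl)])
  }
})

test_that("DC is order-sensitive where AAC is reversal-invariant", {
  s <- "ACDEFG"
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(compute_aac(s), compute_aac(rev_s))
  expect_false(isTRUE(all.equal(compute_dc(s), compute_dc(rev_s))))
})

test_that("property table is standardized over the 20 residues", {
  props <- pseaac_properties()
  expect_equal(dim(props), c(20L, 3L))
  for (j in 1:3) {
    expect_lt(abs(mean(props[, j])), 1e-10)
    expect_equal(sum(props[, j]^2) / 20, 1, tolerance = 1e-10)
  }
})

test_that("PC-PseAAC matches the direct-summation oracle", {
  props <- pseaac_properties()
  # homopolymer: all correlation factors vanish, vector = padded AAC
  v <- compute_pc_pseaac("AAAAA", lambda = 3)
  expect_equal(unname(v), c(unname(compute_aac("AAAAA")), 0, 0, 0))
  expect_length(compute_pc_pseaac("ACACAG", lambda = 4), 24)
  expect_error(compute_pc_pseaac("ACD", lambda = 3), "lambda")
  v2 <- compute_pc_pseaac("ACACA", lambda = 1, w = 0.05)
  expect_equal(unname(v2), oracle_pc_pseaac("ACACA", 1, 0.05, props))
  set.seed(4)
  for (i in 1:15) {
    s <- random_peptide(sample(6:30, 1))
    lam <- sample(1:4, 1)
    impl <- compute_pc_pseaac(s, lam, 0.05)
    expect_equal(unname(impl), oracle_pc_pseaac(s, lam, 0.05, props))
    expect_true(all(impl >= 0))
    expect_equal(sum(impl), 1)
  }
})

test_that("SC-PseAAC matches the direct-summation oracle", {
  props <- pseaac_properties()
  expect_length(compute_sc_pseaac("ACDEFG", lambda = 2), 24)
  expect_error(compute_sc_pseaac("ACD", lambda = 4), "lambda")
  v <- compute_sc_pseaac("ACDEF", lambda = 2, w = 0.05)
  expect_equal(unname(v), oracle_sc_pseaac("ACDEF", 2, 0.05, props))
  set.seed(5)
  for (i in 1:15) {
    s <- random_peptide(sample(6:30, 1))
    lam <- sample(1:4, 1)
    impl <- compute_sc_pseaac(s, lam, 0.05)
    expect_equal(unname(impl), oracle_sc_pseaac(s, lam, 0.05, props))
    expect_equal(sum(impl), 1)
  }
})

test_that("featurize_dataset merges namespaced blocks in order", {
  ds <- toy_dataset()
  m <- featurize_dataset(ds, c("aac", "dc", "tc"))
  expect_equal(dim(m$values), c(6L, 8420L))
  expect_equal(unname(table(m$provenance)[c("AAC", "DC", "TC")]),
               c(20L, 400L, 8000L), ignore_attr = TRUE)
  expect_equal(colnames(m$values)[1], "AAC:A")
  expect_equal(m$ids, ds$id)
  m2 <- featurize_dataset(ds, "aac")
  expect_equal(dim(m2$values), c(6L, 20L))
  # repeated featurization is identical (pure function of the sequences)
  expect_identical(m$values, featurize_dataset(ds, c("aac", "dc", "tc"))$values)
})

test_that("featurize_dataset names the record too short for a set", {
  recs <- data.frame(id = c("ok", "short"), sequence = c("ACDEF", "AC"),
                     stringsAsFactors = FALSE)
  ds <- labeled_dataset(recs, setNames(c("ANTI", "NON_ANTI"), recs$id))
  expect_error(featurize_dataset(ds, "tc"), "short")
})

test_that("remove_zero_features drops exactly the all-zero columns", {
  ds <- toy_dataset()
  m <- featurize_dataset(ds, "tc")
  kept <- remove_zero_features(m)
  observed <- unique(unlist(lapply(ds$sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    vapply(seq_len(length(chars) - 2),
           function(i) paste(chars[i:(i + 2)], collapse = ""), character(1))
  })))
  expect_setequal(sub("^TC:", "", colnames(kept$values)), observed)
  # identity when nothing is all-zero
  aac <- featurize_dataset(ds, "aac")
  aac_kept <- remove_zero_features(aac)
  expect_true(ncol(aac_kept$values) <= 20)
  expect_identical(remove_zero_features(aac_kept)$values, aac_kept$values)
})

test_that("standardizer learns on fit rows only and handles zero spread", {
  x <- cbind(f1 = c(1, 2, 3, 10), f2 = c(5, 5, 5, 5), f3 = c(0, 1, 0, 9))
  st <- fit_standardizer(x, fit_rows = 1:3)
  z <- predict(st, x)
  # sample-sd convention: values (1,2,3) standardize to (-1, 0, 1)
  expect_equal(unname(z[1:3, "f1"]), c(-1, 0, 1))
  expect_equal(unname(z[, "f2"]), rep(0, 4))
  # held-out row uses fit-row statistics (no leakage)
  expect_equal(unname(z[4, "f1"]), (10 - 2) / 1)
  expect_lt(abs(mean(z[1:3, "f1"])), 1e-10)
  expect_error(fit_standardizer(x, integer(0)), "empty")
})
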