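test_that("read_fasta parses entries, normalises case and reads labels", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "ACDE", ">p2", "gg", ">p3|ANTI",
               "AC", "DE"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("p1", "p2", "p3"))
  expect_equal(recs$sequence, c("ACDE", "GG", "ACDE"))
  expect_equal(recs$label, c(NA, NA, "ANTI"))
})

test_that("read_fasta rejects malformed files with a line number", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACDE", ">p1", "GG"), f)
  expect_error(read_fasta(f), "line 1")
  writeLines(c(">p1", ">p2", "GG"), f)
  expect_error(read_fasta(f), "no sequence")
})

test_that("fasta write/read round-trips ids, sequences and labels", {
  ds <- toy_dataset()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ds, f, labels = setNames(ds$label, ds$id))
  back <- read_fasta(f)
  expect_equal(back$id, ds$id)
  expect_equal(back$sequence, ds$sequence)
  expect_equal(back$label, ds$label)
})

test_that("label tables round-trip and are validated", {
  labs <- setNames(c("ANTI", "NON_ANTI"), c("a", "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_labels(labs, f)
  expect_equal(read_labels(f), labs)
  writeLines(c("id,label", "a,MAYBE"), f)
  expect_error(read_labels(f), "invalid label")
})

test_that("validate_record applies the alphabet and length rules", {
  expect_true(validate_record("ACDE")$valid)
  v <- validate_record("ACDEX")
  expect_false(v$valid)
  expect_match(v$reason, "'X' at position 5")
  v2 <- validate_record("A")
  expect_false(v2$valid)
  expect_match(v2$reason, "length")
  expect_false(validate_record("AC-E")$valid)
})

test_that("filter_valid prunes invalid records consistently and is idempotent", {
  recs <- data.frame(id = sprintf("s%d", 1:5),
                     sequence = c("ACDE", "ACXDE", "GG", "B", "MMMM"),
                     stringsAsFactors = FALSE)
  labs <- setNames(c("ANTI", "ANTI", "NON_ANTI", "NON_ANTI", "ANTI"),
                   recs$id)
  ds <- labeled_dataset(recs, labs)
  out <- filter_valid(ds)
  expect_equal(nrow(out$dataset), 3)
  expect_equal(out$rejected$id, c("s2", "s4"))
  expect_setequal(out$dataset$id, setdiff(recs$id, out$rejected$id))
  again <- filter_valid(out$dataset)
  expect_equal(again$dataset, out$dataset)
  expect_equal(nrow(again$rejected), 0)
})

test_that("filter_valid errors when nothing survives", {
  recs <- data.frame(id = c("a", "b"), sequence = c("XX", "ZZ"),
                     stringsAsFactors = FALSE)
  ds <- labeled_dataset(recs, setNames(c("ANTI", "NON_ANTI"), recs$id))
  expect_error(filter_valid(ds), "all records invalid")
})

test_that("labeled_dataset enforces the id/label bijection", {
  recs <- data.frame(id = c("a", "b"), sequence = c("ACDE", "GGGG"),
                     stringsAsFactors = FALSE)
  expect_error(labeled_dataset(recs, c(a = "ANTI")), "without a label")
  expect_error(labeled_dataset(recs, c(a = "ANTI", b = "NON_ANTI",
                                       c = "ANTI")), "without a record")
})

test_that("pairwise identity matches fixed examples and the DP oracle", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  set.seed(42)
  for (i in 1:30) {
    a <- random_peptide(sample(4:12, 1))
    b <- random_peptide(sample(4:12, 1))
    ord <- sort(c(a, b))  # the implementation canonicalises orientation
    expect_equal(pairwise_identity(a, b), oracle_identity(ord[1], ord[2]),
                 tolerance = 1e-12, info = paste(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("max_identity_check reports pairs at or above the threshold", {
  recs <- data.frame(
    id = c("a", "b", "c", "d"),
    sequence = c("ACDEFGHIKL", "ACDEFGHMNP", "WWWWYYYYWW", "ACDEFGHIKL"),
    stringsAsFactors = FALSE)
  ds <- labeled_dataset(recs, setNames(c("ANTI", "ANTI", "NON_ANTI",
                                         "NON_ANTI"), recs$id))
  rep70 <- max_identity_check(ds, threshold = 0.70)
  # a-b share exactly 7/10 positions (inclusive >=); a-d are duplicates
  expect_true(any(rep70$id_a == "a" & rep70$id_b == "b"))
  expect_true(any(rep70$id_a == "a" & rep70$id_b == "d" &
                    rep70$identity == 1))
  expect_false(any(rep70$id_b == "c" | rep70$id_a == "c"))
  dissimilar <- labeled_dataset(
    data.frame(id = c("x", "y"), sequence = c("AAAAA", "CCCCC"),
               stringsAsFactors = FALSE),
    setNames(c("ANTI", "NON_ANTI"), c("x", "y")))
  expect_equal(nrow(max_identity_check(dissimilar, 0.70)), 0)
})
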