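test_that("alphabets preserve order, append the separator, reject duplicates", {
  ab <- build_alphabet(c("a", "b"), separator = "_")
  expect_s3_class(ab, "sls_alphabet")
  expect_identical(ab$symbols, c("a", "b", "_"))
  expect_equal(alphabet_size(ab), 3)

  # explicit separator position is preserved
  ab2 <- build_alphabet(c("x", "_", "y"))
  expect_identical(ab2$symbols, c("x", "_", "y"))

  expect_error(build_alphabet(c("a", "a")), "duplicate.*'a'")
  expect_error(build_alphabet(character(0)), "nonempty")
  expect_error(build_alphabet("ab"), "single character")
})

test_that("the packaged default alphabet has 65 characters and 4225 bi-grams", {
  ab <- default_alphabet()
  expect_equal(alphabet_size(ab), 65)
  expect_identical(ab$symbols[1:26], letters)
  expect_identical(ab$symbols[27], "_")
  expect_equal(sum(duplicated(ab$symbols)), 0)
  expect_equal(length(ngram_names(ab, 2)), 65^2)
  expect_equal(length(ngram_names(ab, 2)), 4225)
})

test_that("clean_text applies the declared normalisation rules", {
  ab <- build_alphabet(c("a", "b"))
  d <- clean_text("Ab  ba", ab)
  expect_identical(d$chars, "ab_ba")
  expect_equal(d$n, 5)

  expect_identical(suppressMessages(clean_text("a9b", ab))$chars, "ab")
  expect_equal(suppressMessages(clean_text("a9b", ab))$n, 2)

  # separator runs left by dropped characters collapse; ends are trimmed
  expect_identical(suppressMessages(clean_text(" a . b ", ab))$chars, "a_b")

  expect_error(suppressMessages(clean_text("x", ab)), "too short")

  # idempotence: cleaning a cleaned document changes nothing
  dirty <- "  Le CHAT; noir 42 chatsé "
  once <- clean_text(dirty, default_alphabet())
  twice <- clean_text(once$chars, default_alphabet())
  expect_identical(once$chars, twice$chars)
})

test_that("bi-gram signatures match hand-enumerated counts and sum to one", {
  ab <- build_alphabet(c("a", "b"))
  sig <- signature_of("abab", ab)
  expect_equal(length(sig), 9)
  expect_equal(unname(sig["a|b"]), 2 / 3)
  expect_equal(unname(sig["b|a"]), 1 / 3)
  expect_equal(sum(sig), 1)
  expect_true(all(sig[setdiff(names(sig), c("a|b", "b|a"))] == 0))

  expect_error(signature_of("a", ab), "too short")
})

test_that("signatures sum to one for random documents of any order k", {
  ab <- build_alphabet(letters[1:5])
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(2:200, 1)
      txt <- paste(sample(ab$symbols, n, replace = TRUE), collapse = "")
      s2 <- signature_of(txt, ab, k = 2)
      expect_equal(sum(s2), 1)
      expect_true(all(s2 >= 0))
      if (n >= 3) {
        s3 <- signature_of(txt, ab, k = 3)
        expect_equal(sum(s3), 1)
        expect_equal(length(s3), alphabet_size(ab)^3)
      }
    }
  })
})

test_that("self-concatenation keeps signatures valid", {
  ab <- build_alphabet(c("a", "b"))
  doc <- clean_text("abba ab", ab)
  dup <- clean_text(paste(doc$chars, doc$chars, sep = "_"), ab)
  sig <- signature_of(dup, ab)
  expect_true(all(sig >= 0))
  expect_equal(sum(sig), 1)
  # no bi-gram of the original disappears in the doubled document
  orig <- signature_of(doc, ab)
  expect_true(all(sig[orig > 0] > 0))
})

test_that("a default-alphabet document yields a 4225-element vector", {
  doc <- clean_text("the quick brown fox jumps over the lazy dog",
                    default_alphabet())
  sig <- signature_of(doc, default_alphabet())
  expect_equal(length(sig), 4225)
  expect_equal(sum(sig), 1)
})

test_that("sls_signatures builds one row per document with n-gram columns", {
  ab <- build_alphabet(c("a", "b"))
  tab <- suppressMessages(sls_signatures(toy_corpus(), ab))
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 1 + 9)
  expect_identical(tab$label, c("doc1", "doc2", "doc3"))
  expect_equal(unname(rowSums(tab[, -1])), rep(1, 3))
})

test_that("signature tables round-trip through dense and sparse writers", {
  ab <- build_alphabet(c("a", "b"))
  tab <- suppressMessages(sls_signatures(toy_corpus(), ab))
  dense <- withr::local_tempfile(fileext = ".tsv")
  sparse <- withr::local_tempfile(fileext = ".tsv")
  write_signatures(tab, dense)
  write_signatures_sparse(tab, sparse)
  back <- read_signatures(dense)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  trip <- readr::read_tsv(sparse, show_col_types = FALSE)
  expect_identical(names(trip), c("label", "ngram", "value"))
  expect_true(all(trip$value > 0))
})

test_that("read_corpus reads text directories and FASTA records", {
  dir <- withr::local_tempdir()
  writeLines("abba", file.path(dir, "one.txt"))
  writeLines(c("ab", "ba"), file.path(dir, "two.txt"))
  corp <- read_corpus(dir)
  expect_identical(corp$label, c("one", "two"))
  expect_identical(corp$text[2], "ab ba")
  expect_error(read_corpus(file.path(dir, "absent")), "no readable")

  skip_if_not_installed("Biostrings")
  fa <- file.path(dir, "seqs.fa")
  writeLines(c(">s1", "ACGT", ">s2", "GGTT"), fa)
  rec <- read_corpus(fa, format = "fasta")
  expect_identical(rec$label, c("s1", "s2"))
  expect_identical(rec$text, c("acgt", "ggtt"))
})
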