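test_that("sliding-window tokenization follows the windowing rule", {
  expect_equal(tokenize_sequence("ACDEF", k = 2), c("AC", "CD", "DE", "EF"))
  expect_equal(tokenize_sequence("", k = 2), character(0))
  expect_equal(tokenize_sequence("MSMS", k = 2), c("MS", "SM", "MS"))
  expect_equal(sum(tokenize_sequence("MSMS", k = 2) == "MS"), 2L)
  # k longer than the sequence is an empty result, not an error
  expect_equal(tokenize_sequence("ACD", k = 5), character(0))
  # stride and block length are configurable
  expect_equal(tokenize_sequence("ACDEFG", k = 2, step = 2),
               c("AC", "DE", "FG"))
  expect_equal(tokenize_sequence("ACDEF", k = 3), c("ACD", "CDE", "DEF"))
})

test_that("tokenization validates input and handles case/alphabet", {
  expect_error(tokenize_sequence("AC1DE", k = 2), "position 3",
               class = "pftp_data_error")
  expect_equal(tokenize_sequence("acdef", k = 2)[1], "AC")
  # 'X' is outside the 20-letter alphabet: dropped by default, kept on demand
  expect_equal(tokenize_sequence("AXC", k = 2), character(0))
  expect_equal(tokenize_sequence("AXC", k = 2, alphabet = NULL),
               c("AX", "XC"))
  # mixed lengths emit all lengths 1..k
  expect_setequal(tokenize_sequence("ACD", k = 2, mixed_lengths = TRUE),
                  c("A", "C", "D", "AC", "CD"))
})

test_that("stride-1 tokenization yields max(0, n - k + 1) blocks", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(0:30, 1)
    s <- paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    k <- sample(1:4, 1)
    expect_length(tokenize_sequence(s, k = k), max(0L, n - k + 1L))
  }
})

test_that("vocabulary construction sorts, prunes and stays deterministic", {
  docs <- list(p1 = c("AC", "AC"), p2 = "CD")
  v1 <- build_vocabulary(docs, min_count = 1)
  expect_equal(v1$blocks, c("AC", "CD"))
  expect_equal(v1$size, 2L)
  v2 <- build_vocabulary(docs, min_count = 2)
  expect_equal(v2$blocks, "AC")
  expect_equal(v2$size, 1L)
  expect_error(build_vocabulary(docs, min_count = 5),
               class = "pftp_config_error")
  # all 2-mers over the 20-letter alphabet give W = 400
  all2 <- as.vector(outer(AA_ALPHABET, AA_ALPHABET, paste0))
  expect_equal(build_vocabulary(list(all2))$size, 400L)
})

test_that("bag-of-words counts raw occurrences over the vocabulary", {
  vocab <- build_vocabulary(list(c("MS", "TS")))
  bow <- build_bow(list(p1 = c("MS", "TS", "MS")), vocab)
  expect_equal(unname(bow$counts[1, ]), c(2L, 1L))
  expect_equal(bow$doc_totals, 3L)
  # out-of-vocabulary blocks are skipped; empty row is valid
  bow0 <- build_bow(list(p1 = c("XX", "YY")), vocab)
  expect_equal(unname(bow0$counts[1, ]), c(0L, 0L))
  expect_equal(bow0$doc_totals, 0L)
  expect_error(build_bow(list(p1 = "MS", p1 = "TS"), vocab),
               class = "pftp_data_error")
})

test_that("disjoint documents give a block-diagonal count pattern", {
  docs <- list(a = c("AA", "AA"), b = c("CC"), c = c("DD", "DD", "DD"))
  vocab <- build_vocabulary(docs)
  bow <- build_bow(docs, vocab)
  expect_equal(unname(bow$counts),
               matrix(c(2L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 3L),
                      3, 3, byrow = TRUE))
})

test_that("bag-of-words is permutation-equivariant and conserves tokens", {
  set.seed(7)
  docs <- lapply(1:5, function(i)
    sample(c("AA", "AC", "CA", "CC"), sample(0:8, 1), replace = TRUE))
  names(docs) <- paste0("p", 1:5)
  vocab <- build_vocabulary(docs[lengths(docs) > 0])
  bow <- build_bow(docs, vocab)
  expect_equal(sum(bow$counts), sum(lengths(docs)))
  perm <- c(3, 1, 5, 2, 4)
  bowp <- build_bow(docs[perm], vocab)
  expect_equal(bowp$counts, bow$counts[perm, ])
})

test_that("bag-of-words text round trip preserves the corpus exactly", {
  docs <- list(p1 = c("MS", "TS", "MS"), p2 = character(0), p3 = "TS")
  vocab <- build_vocabulary(list(c("MS", "TS")))
  bow <- build_bow(docs, vocab)
  cp <- withr::local_tempfile(fileext = ".tsv")
  vp <- withr::local_tempfile(fileext = ".txt")
  write_bow(bow, cp, vp)
  back <- read_bow(cp, vp)
  expect_equal(back$counts, bow$counts)
  expect_equal(back$doc_ids, bow$doc_ids)
  expect_equal(back$vocabulary$blocks, vocab$blocks)
})
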