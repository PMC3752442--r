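# Synthetic lexicon generation: mora inventory, word lexicon, probe sets,
# corpus serialization.

test_that("inventory codes are distinct, deterministic, and capacity-checked", {
  inv <- build_inventory(20, 20, seed = 1)
  expect_length(inv, 20)
  keys <- vapply(inv, function(m) paste(m$features, collapse = ""), "")
  expect_equal(anyDuplicated(keys), 0L)
  # one-hot by default
  expect_true(all(vapply(inv, function(m) sum(m$features), 0) == 1))

  # forced case: two morae on one bit can only be the codes 0 and 1
  inv2 <- build_inventory(2, 1, seed = 1)
  expect_setequal(vapply(inv2, function(m) m$features, 0), c(0, 1))

  # pigeonhole: five morae cannot fit in one bit
  expect_error(build_inventory(5, 1, seed = 1), "cannot code")

  expect_identical(build_inventory(12, 12, seed = 9),
                   build_inventory(12, 12, seed = 9))
})

test_that("lexicon has distinct triples, exact semantic sparsity, capacity errors", {
  inv <- build_inventory(20, 20, seed = 1)
  lex <- build_lexicon(inv, 300, semantic_dim = 50, semantic_sparsity = 0.2,
                       seed = 7)
  expect_length(lex, 300)
  expect_true(all(vapply(lex, function(it) sum(it$semantics), 0) == 10))
  triples <- vapply(lex, function(it) paste(it$morae, collapse = ","), "")
  sems <- vapply(lex, function(it) paste(it$semantics, collapse = ""), "")
  expect_equal(anyDuplicated(triples), 0L)
  expect_equal(anyDuplicated(sems), 0L)

  inv2 <- build_inventory(2, 2, seed = 1)
  expect_error(build_lexicon(inv2, 9, semantic_dim = 10, seed = 1),
               "8 distinct mora triples")

  expect_identical(build_lexicon(inv, 40, seed = 3),
                   build_lexicon(inv, 40, seed = 3))
})

test_that("probe sets have the requested sizes and exclude trained words", {
  inv <- build_inventory(20, 20, seed = 1)
  lex <- build_lexicon(inv, 300, seed = 7)
  ps <- sample_probe_sets(lex, 51, 108, seed = 3)
  expect_length(ps$probe_words, 51)
  expect_length(ps$probe_nonwords, 108)
  lex_keys <- vapply(lex, function(it) paste(it$morae, collapse = ","), "")
  nw_keys <- vapply(ps$probe_nonwords,
                    function(it) paste(it$morae, collapse = ","), "")
  expect_length(intersect(nw_keys, lex_keys), 0)
  expect_equal(anyDuplicated(nw_keys), 0L)
  expect_true(all(vapply(ps$probe_nonwords,
                         function(it) length(it$semantics), 0) == 0))

  empty <- sample_probe_sets(lex, 10, 0, seed = 3)
  expect_length(empty$probe_nonwords, 0)
})

test_that("nonword bigram profile matches the probe-word profile", {
  inv <- build_inventory(20, 20, seed = 1)
  lex <- build_lexicon(inv, 300, seed = 7)
  ps <- sample_probe_sets(lex, 51, 108, seed = 3, tolerance = 0.05)
  # independent counting oracle
  wc <- oracle_bigram_counts(ps$probe_words)
  nc <- oracle_bigram_counts(ps$probe_nonwords)
  expect_lte(bigram_chisq_distance(wc, nc), 0.05)
  # the oracle agrees with the package's internal counts
  internal <- cdanet:::bigram_counts(ps$probe_words)
  expect_equal(sort(wc), sort(internal)[names(sort(wc))])
})

test_that("generated corpora satisfy all distinctness invariants across seeds", {
  for (seed in c(2, 17, 43)) {
    co <- generate_corpus(n_morae = 8, feature_dim = 8, n_words = 40,
                          semantic_dim = 20, n_probe_words = 12,
                          n_probe_nonwords = 24, seed = seed,
                          tolerance = 0.1)
    expect_lte(bigram_chisq_distance(
      oracle_bigram_counts(co$probe_words),
      oracle_bigram_counts(co$probe_nonwords)), 0.1)
    train_keys <- vapply(co$train_words,
                         function(it) paste(it$morae, collapse = ","), "")
    probe_keys <- vapply(co$probe_words,
                         function(it) paste(it$morae, collapse = ","), "")
    nw_keys <- vapply(co$probe_nonwords,
                      function(it) paste(it$morae, collapse = ","), "")
    expect_equal(anyDuplicated(train_keys), 0L)
    expect_true(all(probe_keys %in% train_keys))   # probe words are trained
    expect_length(intersect(nw_keys, train_keys), 0)
    sems <- vapply(co$train_words,
                   function(it) paste(it$semantics, collapse = ""), "")
    expect_equal(anyDuplicated(sems), 0L)
  }
  expect_identical(generate_corpus(n_morae = 8, n_words = 30,
                                   n_probe_words = 10, n_probe_nonwords = 12,
                                   seed = 5),
                   generate_corpus(n_morae = 8, n_words = 30,
                                   n_probe_words = 10, n_probe_nonwords = 12,
                                   seed = 5))
})

test_that("corpus files round-trip exactly and reject malformed input", {
  co <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_equal(back, co)

  # record count matches the lexicon size
  lines <- readLines(path)
  expect_equal(sum(grepl("^WORD\t", lines)),
               length(co$train_words) + length(co$probe_words))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_corpus(empty), "line 1")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cdanet corpus v1", "MORA\t1\tm01\t100000",
               "SECTION\tTRAIN", "WORD\t1,2\t-\taccent0"), bad)
  expect_error(read_corpus(bad), "line 4")
})
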