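test_that("corpus JSONL round trip preserves text, tokens, words and triples", {
  line <- '{"text":"AA bb cc","triple_list":[["AA","habit","cc"]]}'
  f <- withr::local_tempfile(lines = line)
  ex <- read_corpus(f, rx_schema(c("alias", "habit")))
  expect_length(ex, 1L)
  expect_equal(ex[[1]]$tokens, c("AA", "bb", "cc"))
  expect_length(ex[[1]]$triples, 1L)
  tr <- ex[[1]]$triples[[1]]
  expect_span(tr$subject, 0L, 1L)
  expect_span(tr$object, 2L, 3L)
  expect_equal(tr$relation, 2L)  # "habit" in the schema

  # empty file -> empty corpus
  f2 <- withr::local_tempfile(lines = character(0))
  expect_length(read_corpus(f2, rx_schema("habit")), 0L)

  # write-read identity on a generated corpus
  corpus <- generate_corpus(generator_config(n_sentences = 25L, rng_seed = 5L))
  f3 <- withr::local_tempfile()
  write_corpus(corpus, f3)
  back <- read_corpus(f3, attr(corpus, "schema"))
  expect_length(back, length(corpus))
  for (i in seq_along(corpus)) {
    expect_identical(back[[i]]$tokens, corpus[[i]]$tokens)
    expect_identical(lapply(back[[i]]$words, unclass), lapply(corpus[[i]]$words, unclass))
    expect_equal(length(back[[i]]$triples), length(corpus[[i]]$triples))
    for (k in seq_along(corpus[[i]]$triples)) {
      expect_identical(relexr:::triple_key(back[[i]]$triples[[k]]),
                       relexr:::triple_key(corpus[[i]]$triples[[k]]))
    }
  }
  # a second write of the re-read corpus is byte-identical
  f4 <- withr::local_tempfile()
  write_corpus(back, f4, attr(corpus, "schema"))
  expect_identical(readLines(f3), readLines(f4))
})

test_that("read_corpus reports malformed lines and unresolvable mentions", {
  f <- withr::local_tempfile(lines = c('{"text":"a b","triple_list":[]}', "{broken"))
  expect_error(read_corpus(f, rx_schema("r")), "line 2.*malformed JSON")
  f2 <- withr::local_tempfile(
    lines = '{"text":"a b","triple_list":[["zz","r","b"]]}')
  expect_error(read_corpus(f2, rx_schema("r")), "zz.*not found in text")
  expect_error(read_corpus(tempfile(), rx_schema("r")), "not found")
  # duplicate triples are dropped with a warning
  f3 <- withr::local_tempfile(
    lines = '{"text":"a b","triple_list":[["a","r","b"],["a","r","b"]]}')
  expect_warning(ex <- read_corpus(f3, rx_schema("r")), "duplicate")
  expect_length(ex[[1]]$triples, 1L)
})

test_that("build_labels produces the pair matrix, relation vector and BIO rows", {
  # one triple sub=(0,1) obj=(3,5) relation 2, n = 6
  ex <- fixture_example(rel = 2L)
  schema <- fixture_schema(5L)
  lab <- build_labels(ex, schema, negative_relations = 0L)
  expect_equal(which(lab$relation_vector == 1L), 2L)
  expect_equal(sum(lab$pair_matrix), 1L)
  expect_equal(lab$pair_matrix[1L, 4L], 1L)  # 0-based (0,3)
  expect_equal(lab$selected_relations, 2L)
  expect_equal(lab$bio_subject[[1]], c("B", "O", "O", "O", "O", "O"))
  expect_equal(lab$bio_object[[1]], c("O", "O", "O", "B", "I", "O"))

  # no triples: all-zero labels, only negative rows
  empty <- rx_example("a b", c("a", "b"))
  lab0 <- build_labels(empty, schema, negative_relations = 2L, rng_seed = 1L)
  expect_equal(sum(lab0$relation_vector), 0L)
  expect_equal(sum(lab0$pair_matrix), 0L)
  expect_length(lab0$selected_relations, 2L)
  expect_true(all(unlist(lab0$bio_subject) == "O"))

  # shared subject start with two object starts
  ex2 <- rx_example("s f o1 f o2", strsplit("s f o1 f o2", " ")[[1]],
                    triples = list(
                      rx_triple(rx_span(0, 1), 1L, rx_span(2, 3), "s", "o1"),
                      rx_triple(rx_span(0, 1), 3L, rx_span(4, 5), "s", "o2")))
  lab2 <- build_labels(ex2, schema, negative_relations = 0L)
  expect_equal(which(lab2$pair_matrix == 1L, arr.ind = TRUE),
               matrix(c(1L, 1L, 3L, 5L), 2L, dimnames = list(NULL, c("row", "col"))))
  # clamping warning when asking for more negatives than available
  expect_warning(build_labels(ex2, schema, negative_relations = 10L), "clamped")
})

test_that("build_labels then bio_decode recovers the gold spans per relation/role", {
  corpus <- generate_corpus(generator_config(n_sentences = 30L, rng_seed = 8L))
  schema <- attr(corpus, "schema")
  for (ex in corpus) {
    lab <- build_labels(ex, schema, negative_relations = 0L)
    for (k in seq_along(lab$selected_relations)) {
      r <- lab$selected_relations[[k]]
      gold_sub <- unique(vapply(Filter(function(t) t$relation == r, ex$triples),
                                function(t) paste(t$subject$start, t$subject$end), ""))
      dec_sub <- vapply(bio_decode(lab$bio_subject[[k]]),
                        function(s) paste(s$start, s$end), "")
      expect_setequal(dec_sub, gold_sub)
    }
  }
})

test_that("bio_decode agrees with the reference decoder on all 3^5 sequences", {
  tags <- c("B", "I", "O")
  grid <- expand.grid(rep(list(tags), 5L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    seqs <- unlist(grid[i, ], use.names = FALSE)
    got <- lapply(bio_decode(seqs), function(s) c(s$start, s$end))
    expect_identical(got, ref_bio_decode(seqs), label = paste(seqs, collapse = ""))
  }
  # documented examples
  expect_identical(lapply(bio_decode(c("O", "B", "I", "O", "B")), unclass),
                   list(list(start = 1L, end = 3L), list(start = 4L, end = 5L)))
  expect_identical(lapply(bio_decode(c("B", "I", "I")), unclass),
                   list(list(start = 0L, end = 3L)))
  expect_error(bio_decode(c("B", "X")), "B, I, O")
})

test_that("classify_overlap follows the EPO > SOO > SEO > normal precedence", {
  A <- rx_span(0, 1); B <- rx_span(2, 3); C <- rx_span(4, 5)
  t1 <- function(s, r, o) rx_triple(s, r, o)
  expect_equal(classify_overlap(list(t1(A, 1, B))), "normal")
  expect_equal(classify_overlap(list(t1(A, 1, B), t1(A, 2, B))), "epo")
  expect_equal(classify_overlap(list(t1(A, 1, B), t1(A, 2, C))), "seo")
  # subject contained in another triple's object
  wide <- rx_span(0, 2)
  expect_equal(classify_overlap(list(t1(A, 1, wide), t1(C, 2, B))), "soo")
  # soo beats seo: shared subject AND an overlap
  expect_equal(classify_overlap(list(t1(A, 1, wide), t1(A, 2, C))), "soo")
  # epo beats soo
  expect_equal(classify_overlap(list(t1(A, 1, wide), t1(A, 2, wide))), "epo")
  expect_error(classify_overlap(list()), "empty")
})

test_that("classify_overlap is invariant to triple order", {
  set.seed(31)
  corpus <- generate_corpus(generator_config(n_sentences = 40L, rng_seed = 31L))
  for (ex in corpus) {
    if (length(ex$triples) < 2L) next
    base <- classify_overlap(ex$triples)
    for (rep in 1:3) {
      expect_equal(classify_overlap(sample(ex$triples)), base)
    }
  }
})

test_that("span and example validation rejects malformed input", {
  expect_error(rx_span(2, 2), "invalid span")
  expect_error(rx_span(-1, 2), "invalid span")
  expect_error(rx_example("a b", c("a", "b"),
                          words = list(rx_span(0, 1))), "cover")
  expect_error(rx_example("a", "a",
                          triples = list(rx_triple(rx_span(0, 1), 1, rx_span(1, 2)))),
               "exceeds sentence length")
  expect_error(rx_schema(c("a", "a")), "unique")
  expect_length(default_schema(), 13L)
})
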