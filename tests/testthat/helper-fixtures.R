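# Shared fixtures: tiny hand-built examples and a small random model.

# "plantA f01 attrB attrC" with one triple (plantA, rel, attrB attrC)
fixture_example <- function(rel = 2L) {
  tokens <- c("plantA", "f01", "f02", "attrB", "attrC", "f03")
  rx_example(paste(tokens, collapse = " "), tokens,
             triples = list(rx_triple(rx_span(0, 1), rel, rx_span(3, 5),
                                      "plantA", "attrB attrC")))
}

fixture_schema <- function(n = 5L) rx_schema(paste0("rel", seq_len(n)))

# small randomly initialized model over a given corpus
fixture_model <- function(corpus, schema = attr(corpus, "schema"),
                          dim = 8L, n_layers = 1L, seed = 99L) {
  set.seed(seed)
  enc <- encoder_config(build_vocab(corpus), dim = dim, n_layers = n_layers,
                        n_heads = 2L,
                        max_len = max(vapply(corpus, function(e) length(e$tokens), 0L)) + 2L)
  relexr:::init_model(schema, enc)
}

# independent brute-force references ------------------------------------------

# reference BIO decoder: every maximal B I* run, as 0-based half-open pairs;
# an I without an open span is skipped (orphan)
ref_bio_decode <- function(tags) {
  spans <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (tags[i] == "B") {
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == "I") j <- j + 1L
      spans[[length(spans) + 1L]] <- c(i - 1L, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  spans
}

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

ref_softmax_rows <- function(z) {
  t(apply(z, 1L, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

expect_span <- function(span, start, end) {
  expect_equal(span$start, start)
  expect_equal(span$end, end)
}
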