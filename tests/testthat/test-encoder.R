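test_that("embed_tokens sums the three embedding tables elementwise", {
  set.seed(4)
  V <- 7L; d <- 5L; L <- 10L
  tables <- list(E_C = matrix(rnorm(V * d), V), E_S = matrix(rnorm(2 * d), 2),
                 E_P = matrix(rnorm(L * d), L))
  ids <- c(3L, 1L, 6L); segs <- c(1L, 1L, 2L)
  out <- embed_tokens(ids, tables, segs)
  # brute-force three-way sum
  ref <- t(vapply(seq_along(ids), function(t)
    tables$E_C[ids[t], ] + tables$E_S[segs[t], ] + tables$E_P[t, ],
    numeric(d)))
  expect_equal(out, ref, tolerance = 1e-12)
  # zero tables -> zero vectors; zero segment/position -> plain lookup
  z <- list(E_C = tables$E_C * 0, E_S = tables$E_S * 0, E_P = tables$E_P * 0)
  expect_true(all(embed_tokens(ids, z) == 0))
  z2 <- list(E_C = tables$E_C, E_S = tables$E_S * 0, E_P = tables$E_P * 0)
  expect_equal(embed_tokens(ids, z2), tables$E_C[ids, ])
  expect_error(embed_tokens(c(1L, 99L), tables), "out of vocabulary")
})

test_that("whole-word masking acts on whole words with the configured rates", {
  tokens <- c("a1", "a2", "a3", "b1")
  words <- list(rx_span(0, 3), rx_span(3, 4))
  vocab <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", "x", "y", "z")
  # select_rate 0: identity
  out0 <- mask_whole_words(tokens, words, vocab, select_rate = 0)
  expect_identical(out0$tokens, tokens)
  expect_length(out0$targets, 0L)
  # select_rate 1 with mask-only action: every token of every word masked
  out1 <- mask_whole_words(tokens, words, vocab, select_rate = 1,
                           rates = c(1, 0, 0), rng_seed = 1L)
  expect_true(all(out1$tokens == "[MASK]"))
  expect_setequal(out1$targets, 1:4)
  # a word's action never splits: tokens of one word are all masked or none
  for (seed in 1:20) {
    out <- mask_whole_words(tokens, words, vocab, select_rate = 0.5,
                            rates = c(1, 0, 0), rng_seed = seed)
    first_word <- out$tokens[1:3]
    expect_true(all(first_word == "[MASK]") || all(first_word == tokens[1:3]))
  }
  expect_error(mask_whole_words(tokens, words, vocab, rates = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("word selection rate is close to 15 percent over many words", {
  n_words <- 400L
  tokens <- sprintf("w%03d", seq_len(n_words))
  words <- lapply(seq_len(n_words) - 1L, function(i) rx_span(i, i + 1L))
  out <- mask_whole_words(tokens, words, c("[MASK]", "q", "r", "s"),
                          select_rate = 0.15, rates = c(1, 0, 0), rng_seed = 42L)
  frac <- length(out$targets) / n_words
  expect_lt(abs(frac - 0.15), 0.05)
})

test_that("encode_tokens is deterministic, position-sensitive, and reduces to embed at depth 0", {
  corpus <- generate_corpus(generator_config(n_sentences = 5L, rng_seed = 9L))
  vocab <- build_vocab(corpus)
  cfg <- encoder_config(vocab, dim = 8L, n_layers = 2L, n_heads = 2L, max_len = 64L)
  set.seed(11)
  params <- relexr:::init_encoder_params(cfg)
  toks <- corpus[[1]]$tokens
  h1 <- encode_tokens(toks, params, cfg)
  h2 <- encode_tokens(toks, params, cfg)
  expect_identical(h1, h2)
  expect_equal(dim(h1), c(length(toks) + 2L, 8L))

  # depth 0: encode == embed of [CLS] tokens [SEP]
  cfg0 <- encoder_config(vocab, dim = 8L, n_layers = 0L, n_heads = 2L, max_len = 64L)
  h0 <- encode_tokens(toks, params, cfg0)
  ids <- relexr:::token_ids(c("[CLS]", toks, "[SEP]"), vocab)
  emb <- relexr:::ad_value(embed_tokens(ids, params[c("E_C", "E_S", "E_P")]))
  expect_equal(h0, emb, tolerance = 1e-12)

  # permuting two tokens changes the output (position embeddings active)
  toks2 <- toks
  toks2[c(2L, 4L)] <- toks2[c(4L, 2L)]
  expect_false(isTRUE(all.equal(encode_tokens(toks2, params, cfg), h1)))

  # overlength input truncates with a warning
  cfg_small <- encoder_config(vocab, dim = 8L, n_layers = 0L, n_heads = 2L, max_len = 6L)
  expect_warning(h_tr <- encode_tokens(corpus[[1]]$tokens, params, cfg_small), "truncated")
  expect_equal(nrow(h_tr), 6L)
})

test_that("fgm_delta rescales the gradient onto the epsilon sphere", {
  d <- fgm_delta(matrix(c(3, 4), 1L), epsilon = 0.005)
  expect_equal(d$delta, matrix(c(0.003, 0.004), 1L), tolerance = 1e-12)
  expect_equal(fgm_delta(matrix(0, 2, 2))$delta, matrix(0, 2, 2))
  set.seed(2)
  for (i in 1:25) {
    g <- matrix(rnorm(12, sd = 10^runif(1, -6, 3)), 3L)
    dd <- fgm_delta(g, epsilon = 0.005)
    expect_equal(sqrt(sum(dd$delta^2)), 0.005, tolerance = 1e-9)
  }
  expect_error(fgm_delta(matrix(c(1, NA), 1L)), "non-finite")
})

test_that("with_perturbation applies the delta inside and restores bit-for-bit", {
  set.seed(3)
  tab <- relexr:::ad_param(matrix(rnorm(20), 5L))
  orig <- tab$value
  pert <- fgm_delta(matrix(rnorm(20), 5L), 0.01)
  inside <- with_perturbation(tab, pert, function() tab$value)
  expect_equal(inside, orig + pert$delta, tolerance = 1e-15)
  expect_identical(tab$value, orig)
  # restores on error too
  expect_error(with_perturbation(tab, pert, function() stop("boom")), "boom")
  expect_identical(tab$value, orig)
  # nesting refused
  expect_error(
    with_perturbation(tab, pert, function()
      with_perturbation(tab, pert, function() NULL)),
    "already active")
  # zero delta: no observable change while inside
  zero <- fgm_delta(matrix(0, 5L, 4L), 0.01)
  expect_identical(with_perturbation(tab, zero, function() tab$value), orig)
  # embed output inside the handle differs by exactly the delta rows
  ids <- c(2L, 4L)
  tabs <- list(E_C = tab, E_S = relexr:::ad_const(matrix(0, 2, 4)),
               E_P = relexr:::ad_const(matrix(0, 9, 4)))
  clean <- embed_tokens(ids, tabs)$value
  pert_out <- with_perturbation(tab, pert, function() embed_tokens(ids, tabs)$value)
  expect_equal(pert_out - clean, pert$delta[ids, ], tolerance = 1e-12)
})
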