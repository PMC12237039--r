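# independent formula references used throughout: plain-loop recomputations

ref_pool_words <- function(e, words) {
  chunks <- t(vapply(words, function(w)
    colMeans(e[(w$start + 1):w$end, , drop = FALSE]), numeric(ncol(e))))
  matrix(colMeans(chunks), 1L)
}

ref_pool_windows <- function(e, window) {
  n <- nrow(e)
  starts <- seq(1L, n, by = window)
  chunks <- t(vapply(starts, function(s)
    colMeans(e[s:min(s + window - 1L, n), , drop = FALSE]), numeric(ncol(e))))
  matrix(colMeans(chunks), 1L)
}

test_that("pooling operations match slice-and-mean references", {
  set.seed(10)
  # documented small cases
  expect_equal(pool_global(rbind(c(1, 0), c(0, 1))), matrix(c(0.5, 0.5), 1L))
  e_const <- matrix(2.5, 4L, 3L)
  expect_equal(pool_global(e_const), matrix(2.5, 1L, 3L))
  expect_equal(pool_words(rbind(c(2, 0), c(0, 2)), list(rx_span(0, 2))),
               matrix(c(1, 1), 1L))
  expect_equal(pool_words(e_const, list(rx_span(0, 1), rx_span(1, 4))),
               matrix(2.5, 1L, 3L))
  # padding: masked mean equals mean after removing padded rows
  e <- matrix(rnorm(6 * 4), 6L)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(pool_global(e, mask),
               matrix(colMeans(e[1:4, ]), 1L), tolerance = 1e-12)
  expect_error(pool_global(e, rep(FALSE, 6)), "all-padding")

  # single-token words make word pooling equal global pooling
  words1 <- lapply(0:5, function(i) rx_span(i, i + 1L))
  expect_equal(pool_words(e, words1), pool_global(e), tolerance = 1e-12)

  # window boundaries: n=6, window=4 -> chunks (0,4), (4,6)
  expect_equal(pool_windows(e, 4L),
               matrix(colMeans(rbind(colMeans(e[1:4, ]), colMeans(e[5:6, ]))), 1L),
               tolerance = 1e-12)
  # window >= n reduces to global pooling
  expect_equal(pool_windows(e, 10L), pool_global(e), tolerance = 1e-12)

  # randomized agreement with brute-force references
  for (i in 1:25) {
    n <- sample(2:9, 1L); d <- sample(2:6, 1L)
    e <- matrix(rnorm(n * d), n)
    cuts <- sort(sample(seq_len(n - 1L), sample(0:(n - 1L), 1L)))
    bounds <- cbind(c(0L, cuts), c(cuts, n))
    words <- lapply(seq_len(nrow(bounds)), function(k) rx_span(bounds[k, 1], bounds[k, 2]))
    expect_equal(pool_words(e, words), ref_pool_words(e, words), tolerance = 1e-10)
    w <- sample(1:5, 1L)
    expect_equal(pool_windows(e, w), ref_pool_windows(e, w), tolerance = 1e-10)
  }
})

test_that("classify_relations implements the fused sigmoid formula", {
  set.seed(20)
  n <- 6L; d <- 4L; n_r <- 5L
  e <- matrix(rnorm(n * d), n)
  words <- list(rx_span(0, 2), rx_span(2, 3), rx_span(3, 6))
  params <- relation_head_params(d, n_r, window = 4L)
  # zero weights -> sigmoid(0) = 0.5 everywhere
  p0 <- params; p0$w_r <- matrix(0, d, n_r); p0$b_r <- matrix(0, 1L, n_r)
  expect_equal(as.numeric(classify_relations(e, words, p0)), rep(0.5, n_r))
  # alpha=1, beta=gamma=0 reduces to a mean-pooled linear-sigmoid classifier
  p1 <- params; p1$alpha <- 1; p1$beta <- 0; p1$gamma <- 0
  w_r <- relexr:::ad_value(params$w_r); b_r <- relexr:::ad_value(params$b_r)
  expect_equal(as.numeric(classify_relations(e, words, p1)),
               as.numeric(ref_sigmoid(pool_global(e) %*% w_r + b_r)),
               tolerance = 1e-10)
  # full formula oracle
  fused <- (pool_global(e) + ref_pool_words(e, words) + ref_pool_windows(e, 4L)) / 3
  expect_equal(as.numeric(classify_relations(e, words, params)),
               as.numeric(ref_sigmoid(fused %*% w_r + b_r)), tolerance = 1e-10)
  # padding invariance: appending padded rows never changes p_rel
  e_pad <- rbind(e, matrix(rnorm(2 * d), 2L))
  mask <- c(rep(TRUE, n), FALSE, FALSE)
  expect_equal(classify_relations(e_pad, words, params, mask = mask),
               classify_relations(e, words, params), tolerance = 1e-10)
})

test_that("pair_matrix matches a double-loop recomputation and honors the mask", {
  set.seed(21)
  n <- 3L; d <- 4L
  h <- matrix(rnorm(n * d), n)
  params <- pair_matrix_params(d)
  P <- pair_matrix(h, params)
  W_sub <- relexr:::ad_value(params$W_sub); W_obj <- relexr:::ad_value(params$W_obj)
  w1 <- relexr:::ad_value(params$w_g_sub); w2 <- relexr:::ad_value(params$w_g_obj)
  bg <- as.numeric(relexr:::ad_value(params$b_g))
  ref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    hi <- h[i, ] %*% W_sub; hj <- h[j, ] %*% W_obj
    ref[i, j] <- ref_sigmoid(as.numeric(hi %*% w1) + as.numeric(hj %*% w2) + bg)
  }
  expect_equal(P, ref, tolerance = 1e-10)
  # zero weights -> all 0.5
  p0 <- pair_matrix_params(d, project = FALSE)
  p0$w_g_sub <- matrix(0, d, 1L); p0$w_g_obj <- matrix(0, d, 1L)
  expect_true(all(pair_matrix(h, p0) == 0.5))
  # padded position k zeroes row and column k
  mask <- c(TRUE, TRUE, FALSE)
  Pm <- pair_matrix(h, params, mask = mask)
  expect_true(all(Pm[3, ] == 0) && all(Pm[, 3] == 0))
  expect_equal(Pm[1:2, 1:2], P[1:2, 1:2], tolerance = 1e-12)
  # generically asymmetric: (i,j) independent of (j,i)
  expect_false(isTRUE(all.equal(P, t(P))))
})

test_that("self_attention equals a step-by-step manual computation", {
  set.seed(22)
  n <- 3L; dx <- 5L; dv <- 4L
  X <- matrix(rnorm(n * dx), n)
  params <- list(W_Q = matrix(rnorm(dx * dv), dx), W_K = matrix(rnorm(dx * dv), dx),
                 W_V = matrix(rnorm(dx * dv), dx), d_k = dv)
  H <- self_attention(X, params)
  Q <- X %*% params$W_Q; K <- X %*% params$W_K; V <- X %*% params$W_V
  A <- ref_softmax_rows(Q %*% t(K) / sqrt(dv))
  expect_equal(H, A %*% V, tolerance = 1e-10)
  expect_equal(rowSums(A), rep(1, n), tolerance = 1e-12)
  # n = 1: output is that token's value vector
  X1 <- X[1, , drop = FALSE]
  expect_equal(self_attention(X1, params), X1 %*% params$W_V, tolerance = 1e-12)
  # W_K = 0: uniform attention -> every row is the mean value vector
  p0 <- params; p0$W_K <- params$W_K * 0
  H0 <- self_attention(X, p0)
  expect_equal(H0, matrix(colMeans(V), n, dv, byrow = TRUE), tolerance = 1e-10)
})

test_that("tag_for_relation conditions on the relation and yields distributions", {
  set.seed(23)
  n <- 2L; d <- 4L; n_r <- 5L
  h <- matrix(rnorm(n * d), n)
  params <- tagger_params(d, n_r)
  out <- tag_for_relation(h, 3L, params)
  expect_equal(rowSums(out$p_sub), rep(1, n), tolerance = 1e-6)
  expect_equal(rowSums(out$p_obj), rep(1, n), tolerance = 1e-6)
  # manual pipeline recomputation
  r3 <- relexr:::ad_value(params$r_emb)[3L, ]
  X <- cbind(h, matrix(r3, n, length(r3), byrow = TRUE))
  H <- self_attention(X, list(W_Q = relexr:::ad_value(params$W_Q),
                              W_K = relexr:::ad_value(params$W_K),
                              W_V = relexr:::ad_value(params$W_V), d_k = params$d_k))
  ref_sub <- ref_softmax_rows(sweep(H %*% relexr:::ad_value(params$W_sub), 2L,
                                    as.numeric(relexr:::ad_value(params$b_sub)), "+"))
  expect_equal(unname(out$p_sub), unname(ref_sub), tolerance = 1e-10)
  # different relations produce different tag distributions (generic params)
  out2 <- tag_for_relation(h, 4L, params)
  expect_false(isTRUE(all.equal(out$p_sub, out2$p_sub)))
  # zero output head -> uniform distributions
  pz <- params; pz$W_sub <- relexr:::ad_param(matrix(0, d, 3L))
  outz <- tag_for_relation(h, 1L, pz)
  expect_true(all(abs(outz$p_sub - 1 / 3) < 1e-12))
  expect_error(tag_for_relation(h, 99L, params), "out of range")
})

test_that("fusion degeneracy: constant embeddings make all three pools coincide", {
  e <- matrix(1.7, 5L, 3L)
  words <- list(rx_span(0, 2), rx_span(2, 5))
  expect_equal(pool_global(e), pool_words(e, words), tolerance = 1e-12)
  expect_equal(pool_global(e), pool_windows(e, 4L), tolerance = 1e-12)
})
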