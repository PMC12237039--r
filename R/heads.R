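# The three prediction heads.
#
# 1. Relation classification: multi-level fusion of three average-pooled
#    sentence vectors (global, word-level, fixed-window) through a linear
#    map and sigmoid -> multi-label relation probabilities.
# 2. Global correspondence matrix: sigmoid(w_g [h_i^sub ; h_j^obj] + b_g)
#    over all token pairs, scoring "a subject starts at i and an object
#    starts at j". Rows index subject starts, columns object starts.
#    h^sub and h^obj are separate linear views of the encoder states.
# 3. Relation-conditioned tagger: concatenate each token vector with the
#    relation embedding, run scaled dot-product self-attention, and emit
#    per-token B/I/O distributions for the subject and object roles.
#
# Every operation accepts either plain numeric matrices (returning plain
# results) or `ad_node`s (returning graph nodes), so the training graph and
# the user-facing API share one implementation.

BIO_LEVELS <- c("B", "I", "O")

wrap_head <- function(plain, node) if (plain) node$value else node

#' Average-pool token vectors into a sentence vector
#'
#' @param e n x dim token vectors (matrix or `ad_node`).
#' @param mask logical vector marking real (non-padding) tokens;
#'   `NULL` means all real. At least one token must be real.
#' @return 1 x dim sentence vector.
#' @export
pool_global <- function(e, mask = NULL) {
  plain <- !is_ad_node(e)
  e <- as_ad(e)
  rows <- if (is.null(mask)) seq_len(nrow(e$value)) else which(mask)
  if (length(rows) == 0L) stop("cannot pool an all-padding sequence")
  wrap_head(plain, ad_mean_rows(e, rows))
}

#' Word-level pooled sentence vector
#'
#' Each word's token vectors are averaged into one chunk vector; the chunk
#' vectors are then average-pooled into the sentence vector.
#'
#' @param e n x dim token vectors (matrix or `ad_node`).
#' @param word_boundaries list of `rx_span` partitioning the (unpadded)
#'   token range.
#' @return 1 x dim sentence vector.
#' @export
pool_words <- function(e, word_boundaries) {
  plain <- !is_ad_node(e)
  e <- as_ad(e)
  n <- nrow(e$value)
  groups <- lapply(word_boundaries, function(w) {
    if (w$end > n) stop("word boundary [", w$start, ", ", w$end, ") outside sequence of length ", n)
    (w$start + 1L):w$end
  })
  chunks <- ad_group_means(e, groups)
  wrap_head(plain, ad_mean_rows(chunks, seq_along(groups)))
}

#' Fixed-window pooled sentence vector
#'
#' Contiguous chunks of `window` tokens are averaged (the final chunk over
#' its true, possibly shorter, length), then the chunk vectors are averaged.
#'
#' @param e n x dim token vectors (matrix or `ad_node`).
#' @param window chunk size in tokens (default 4).
#' @param n_real number of real tokens to pool over (default all rows).
#' @return 1 x dim sentence vector.
#' @export
pool_windows <- function(e, window = 4L, n_real = NULL) {
  plain <- !is_ad_node(e)
  e <- as_ad(e)
  if (window < 1L) stop("window must be >= 1")
  n <- if (is.null(n_real)) nrow(e$value) else n_real
  starts <- seq(1L, n, by = window)
  groups <- lapply(starts, function(s) s:min(s + window - 1L, n))
  chunks <- ad_group_means(e, groups)
  wrap_head(plain, ad_mean_rows(chunks, seq_along(groups)))
}

#' Default relation-head parameters
#'
#' @param dim encoder dimension; @param n_r number of relations.
#' @param alpha,beta,gamma fusion weights of the global / word-level /
#'   window-level sentence vectors (default 1/3 each).
#' @param window window size for the third pooling level (default 4).
#' @param lambda relation decision threshold in (0,1) (default 0.5).
#' @return Parameter list (`w_r`, `b_r` as `ad_param` nodes).
#' @export
relation_head_params <- function(dim, n_r, alpha = 1/3, beta = 1/3, gamma = 1/3,
                                 window = 4L, lambda = 0.5) {
  if (window < 1L) stop("window must be >= 1")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  list(w_r = ad_param(rnorm_mat(dim, n_r)), b_r = ad_param(matrix(0, 1L, n_r)),
       alpha = alpha, beta = beta, gamma = gamma, window = as.integer(window),
       lambda = lambda)
}

# fused sentence representation + relation logits (graph form)
relation_logits <- function(e, word_boundaries, params, mask = NULL) {
  e <- as_ad(e)
  n_real <- if (is.null(mask)) nrow(e$value) else sum(mask)
  e1 <- pool_global(e, mask)
  e2 <- pool_words(e, word_boundaries)
  e3 <- pool_windows(e, params$window, n_real)
  wgt <- function(ei, w) if (is_ad_node(w)) ad_scalar_mul(ei, w) else ad_scale(ei, w)
  fused <- ad_add(ad_add(wgt(e1, params$alpha), wgt(e2, params$beta)),
                  wgt(e3, params$gamma))
  ad_add(ad_matmul(fused, params$w_r), params$b_r)
}

#' Multi-level-fusion relation classifier
#'
#' `p_rel = sigmoid(w_r (alpha e1avg + beta e2avg + gamma e3avg) + b_r)`
#' where the three sentence vectors come from [pool_global()],
#' [pool_words()] and [pool_windows()].
#'
#' @param e n x dim token vectors (matrix or `ad_node`).
#' @param word_boundaries list of `rx_span` word units.
#' @param params from [relation_head_params()].
#' @param mask optional logical real-token mask.
#' @return Length-`n_r` probability vector (1 x n_r matrix).
#' @export
classify_relations <- function(e, word_boundaries, params, mask = NULL) {
  plain <- !is_ad_node(e)
  out <- ad_sigmoid(relation_logits(e, word_boundaries, params, mask))
  wrap_head(plain, out)
}

#' Default pair-matrix head parameters
#'
#' @param dim encoder dimension.
#' @param project if `TRUE` (default) the subject and object views are
#'   separate linear projections of the encoder states.
#' @return Parameter list (`w_g` split as `w_g_sub`/`w_g_obj`, `b_g`).
#' @export
pair_matrix_params <- function(dim, project = TRUE) {
  p <- list(w_g_sub = ad_param(rnorm_mat(dim, 1L)),
            w_g_obj = ad_param(rnorm_mat(dim, 1L)),
            b_g = ad_param(matrix(0, 1L, 1L)))
  if (project) {
    p$W_sub <- ad_param(rnorm_mat(dim, dim))
    p$W_obj <- ad_param(rnorm_mat(dim, dim))
  }
  p
}

pair_matrix_logits <- function(h, params) {
  h <- as_ad(h)
  hs <- if (!is.null(params$W_sub)) ad_matmul(h, params$W_sub) else h
  ho <- if (!is.null(params$W_obj)) ad_matmul(h, params$W_obj) else h
  # w_g [h_i^sub ; h_j^obj] + b_g  ==  (h_i^sub . w1) + (h_j^obj . w2) + b_g
  u <- ad_matmul(hs, params$w_g_sub)
  v <- ad_matmul(ho, params$w_g_obj)
  ad_add(ad_outer_sum(u, v), params$b_g)
}

#' Global correspondence matrix
#'
#' Entry (i, j) is `sigmoid(w_g [h_i^sub ; h_j^obj] + b_g)`: the confidence
#' that a subject mention starts at token i and an object mention starts at
#' token j. Padded positions are masked to zero.
#'
#' @param h n x dim encoder states (matrix or `ad_node`).
#' @param params from [pair_matrix_params()].
#' @param mask optional logical real-token mask; padded rows and columns
#'   are forced to 0.
#' @return n x n probability matrix.
#' @export
pair_matrix <- function(h, params, mask = NULL) {
  plain <- !is_ad_node(h)
  out <- ad_sigmoid(pair_matrix_logits(h, params))
  if (!is.null(mask)) {
    keep <- outer(mask, mask, "&") * 1
    out <- ad_mulconst(out, keep)
  }
  wrap_head(plain, out)
}

#' Scaled dot-product self-attention
#'
#' `H = softmax(Q K^T / sqrt(d_k)) V` with `Q = X W_Q`, `K = X W_K`,
#' `V = X W_V`. Attention rows sum to 1; padded key positions are excluded
#' before the softmax.
#'
#' @param X n x d input (matrix or `ad_node`).
#' @param params list with `W_Q`, `W_K`, `W_V` and `d_k`.
#' @param keep optional logical key mask (`FALSE` = padded key).
#' @return n x d_v output.
#' @export
self_attention <- function(X, params, keep = NULL) {
  plain <- !is_ad_node(X)
  X <- as_ad(X)
  if (params$d_k <= 0) stop("d_k must be positive")
  Q <- ad_matmul(X, params$W_Q)
  K <- ad_matmul(X, params$W_K)
  V <- ad_matmul(X, params$W_V)
  A <- ad_softmax_rows(ad_scale(ad_tcrossprod(Q, K), 1 / sqrt(params$d_k)),
                       keep = keep)
  wrap_head(plain, ad_matmul(A, V))
}

#' Default tagger parameters
#'
#' @param dim encoder dimension; @param n_r number of relations.
#' @param rel_dim relation-embedding dimension (default `dim`).
#' @param d_v attention value dimension (default `dim`).
#' @return Parameter list: relation embedding table `r_emb` plus attention
#'   and output projections.
#' @export
tagger_params <- function(dim, n_r, rel_dim = dim, d_v = dim) {
  dx <- dim + rel_dim
  # W_Q and W_K start as the same matrix: Q_i . K_i = |W' X_i|^2 > 0, so
  # attention opens near-diagonal and each token initially reads mostly its
  # own state — sequence tagging needs token identity preserved. Both
  # matrices train independently afterwards.
  W_qk <- rnorm_mat(dx, d_v, sd = 0.15)
  list(r_emb = ad_param(rnorm_mat(n_r, rel_dim)),
       W_Q = ad_param(W_qk),
       W_K = ad_param(W_qk),
       W_V = ad_param(rnorm_mat(dx, d_v)),
       d_k = d_v,
       W_sub = ad_param(rnorm_mat(d_v, 3L)), b_sub = ad_param(matrix(0, 1L, 3L)),
       W_obj = ad_param(rnorm_mat(d_v, 3L)), b_obj = ad_param(matrix(0, 1L, 3L)))
}

tagger_logits <- function(h, relation, params) {
  h <- as_ad(h)
  n <- nrow(h$value)
  rj <- ad_repeat_row(ad_rows(params$r_emb, relation), n)
  X <- ad_cbind(h, rj)
  H <- self_attention(X, params)
  list(sub = ad_add(ad_matmul(H, params$W_sub), params$b_sub),
       obj = ad_add(ad_matmul(H, params$W_obj), params$b_obj))
}

#' Relation-conditioned BIO tagger
#'
#' Concatenates each token vector with the relation embedding, applies
#' [self_attention()] and maps the output to per-token distributions over
#' the tags B/I/O for the subject and object roles.
#'
#' @param h n x dim encoder states (matrix or `ad_node`).
#' @param relation 1-based relation id.
#' @param params from [tagger_params()].
#' @return List with `p_sub` and `p_obj`, each n x 3 (columns B, I, O; rows
#'   sum to 1).
#' @export
tag_for_relation <- function(h, relation, params) {
  plain <- !is_ad_node(h)
  if (relation < 1L || relation > nrow(ad_value(params$r_emb)))
    stop("relation id out of range")
  lg <- tagger_logits(h, relation, params)
  p_sub <- ad_softmax_rows(lg$sub)
  p_obj <- ad_softmax_rows(lg$obj)
  if (plain) {
    ps <- p_sub$value; po <- p_obj$value
    colnames(ps) <- colnames(po) <- BIO_LEVELS
    list(p_sub = ps, p_obj = po)
  } else {
    list(p_sub = p_sub, p_obj = p_obj)
  }
}
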