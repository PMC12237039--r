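# Token representation: summed word/segment/position embeddings, a small
# bidirectional transformer encoder, the whole-word-masking collator, and
# the fast-gradient-method (FGM) perturbation machinery.
#
# The encoder runs in "tiny" mode: a from-scratch post-layer-norm
# transformer (default 2 layers, 2 heads, dimension 32) trained jointly with
# the heads. Layer normalization after each sublayer keeps the token states
# at unit scale, which the prediction heads rely on for usable gradients.

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Build a vocabulary from a corpus
#'
#' @param examples list of `rx_example`.
#' @return Character vector: the special tokens `[PAD]`, `[UNK]`, `[CLS]`,
#'   `[SEP]`, `[MASK]` followed by the sorted unique corpus tokens.
#' @export
build_vocab <- function(examples) {
  toks <- sort(unique(unlist(lapply(examples, function(e) e$tokens))))
  c(SPECIAL_TOKENS, setdiff(toks, SPECIAL_TOKENS))
}

token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- match("[UNK]", vocab)
  ids
}

#' Encoder configuration
#'
#' @param vocab character vector from [build_vocab()].
#' @param dim embedding/hidden dimension.
#' @param n_layers,n_heads transformer depth and heads (tiny mode).
#' @param max_len maximum sequence length including `[CLS]`/`[SEP]`;
#'   longer sentences are truncated with a warning.
#' @param ffn_mult width multiplier of the feed-forward sublayer.
#' @return A list of class `rx_encoder_config`.
#' @export
encoder_config <- function(vocab, dim = 32L, n_layers = 2L, n_heads = 2L,
                           max_len = 128L, ffn_mult = 2L) {
  if (dim %% n_heads != 0L) stop("dim must be divisible by n_heads")
  structure(list(vocab = vocab, vocab_size = length(vocab), dim = as.integer(dim),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 max_len = as.integer(max_len), ffn_mult = as.integer(ffn_mult)),
            class = "rx_encoder_config")
}

#' Sum word, segment and position embeddings
#'
#' The per-token representation is `E_C[id] + E_S[segment] + E_P[position]`.
#' All inputs here are single sentences, so segment ids default to 1.
#'
#' @param token_ids integer vector of 1-based vocabulary indices.
#' @param tables list with matrices `E_C` (vocab x dim), `E_S` (2 x dim),
#'   `E_P` (max_len x dim); `ad_node` parameters are also accepted.
#' @param segment_ids integer vector, same length as `token_ids`.
#' @return n x dim numeric matrix (or `ad_node` when tables are nodes).
#' @export
embed_tokens <- function(token_ids, tables, segment_ids = rep(1L, length(token_ids))) {
  stopifnot(length(token_ids) == length(segment_ids))
  is_graph <- is_ad_node(tables$E_C)
  EC <- as_ad(tables$E_C); ES <- as_ad(tables$E_S); EP <- as_ad(tables$E_P)
  if (any(token_ids < 1L) || any(token_ids > nrow(EC$value)))
    stop("token id out of vocabulary range")
  n <- length(token_ids)
  if (n > nrow(EP$value)) stop("sequence longer than the position table")
  out <- ad_add(ad_add(ad_rows(EC, token_ids), ad_rows(ES, segment_ids)),
                ad_rows(EP, seq_len(n)))
  if (is_graph) out else out$value
}

#' Whole-word masking collator
#'
#' Selects masking units at the word level: every token of a selected word
#' receives the same action, so a multi-token mention is masked as a block.
#' Each word is selected independently with probability `select_rate`; a
#' selected word is replaced by `[MASK]` / by random vocabulary tokens /
#' kept unchanged with probabilities `rates`.
#'
#' @param tokens character vector.
#' @param word_boundaries list of `rx_span` partitioning the tokens.
#' @param vocab vocabulary for random replacement.
#' @param select_rate per-word selection probability (default 0.15).
#' @param rates length-3 action probabilities (mask, random, keep);
#'   must sum to 1.
#' @param rng_seed optional seed.
#' @return List with `tokens` (masked sequence) and `targets` (1-based
#'   positions of all tokens of selected words).
#' @export
mask_whole_words <- function(tokens, word_boundaries, vocab,
                             select_rate = 0.15, rates = c(0.8, 0.1, 0.1),
                             rng_seed = NULL) {
  if (abs(sum(rates) - 1) > 1e-9) stop("masking action rates must sum to 1")
  validate_word_partition(word_boundaries, length(tokens))
  run <- function() {
    out <- tokens
    targets <- integer(0)
    for (w in word_boundaries) {
      if (stats::runif(1) >= select_rate) next
      idx <- (w$start + 1L):w$end
      targets <- c(targets, idx)
      action <- sample(c("mask", "random", "keep"), 1L, prob = rates)
      if (action == "mask") {
        out[idx] <- "[MASK]"
      } else if (action == "random") {
        out[idx] <- sample(setdiff(vocab, SPECIAL_TOKENS), length(idx), replace = TRUE)
      }
    }
    list(tokens = out, targets = targets)
  }
  if (!is.null(rng_seed)) with_seed(rng_seed, run()) else run()
}

# ---- encoder parameters and forward pass -----------------------------------

rnorm_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_encoder_params <- function(cfg) {
  d <- cfg$dim
  p <- list(E_C = ad_param(rnorm_mat(cfg$vocab_size, d)),
            E_S = ad_param(rnorm_mat(2L, d)),
            E_P = ad_param(rnorm_mat(cfg$max_len, d)))
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("L", l, ".Wq")]] <- ad_param(rnorm_mat(d, d))
    p[[paste0("L", l, ".Wk")]] <- ad_param(rnorm_mat(d, d))
    p[[paste0("L", l, ".Wv")]] <- ad_param(rnorm_mat(d, d))
    p[[paste0("L", l, ".Wo")]] <- ad_param(rnorm_mat(d, d))
    p[[paste0("L", l, ".W1")]] <- ad_param(rnorm_mat(d, d * cfg$ffn_mult))
    p[[paste0("L", l, ".b1")]] <- ad_param(matrix(0, 1L, d * cfg$ffn_mult))
    p[[paste0("L", l, ".W2")]] <- ad_param(rnorm_mat(d * cfg$ffn_mult, d))
    p[[paste0("L", l, ".b2")]] <- ad_param(matrix(0, 1L, d))
    p[[paste0("L", l, ".g1")]] <- ad_param(matrix(1, 1L, d))
    p[[paste0("L", l, ".n1")]] <- ad_param(matrix(0, 1L, d))
    p[[paste0("L", l, ".g2")]] <- ad_param(matrix(1, 1L, d))
    p[[paste0("L", l, ".n2")]] <- ad_param(matrix(0, 1L, d))
  }
  p
}

# one post-LN transformer block: attention + residual + LN, FFN + residual + LN
encoder_layer <- function(X, params, layer, cfg, dropout = 0) {
  d <- cfg$dim; nh <- cfg$n_heads; dh <- d %/% nh
  Wq <- params[[paste0("L", layer, ".Wq")]]
  Wk <- params[[paste0("L", layer, ".Wk")]]
  Wv <- params[[paste0("L", layer, ".Wv")]]
  Wo <- params[[paste0("L", layer, ".Wo")]]
  Q <- ad_matmul(X, Wq); K <- ad_matmul(X, Wk); V <- ad_matmul(X, Wv)
  heads <- NULL
  for (h in seq_len(nh)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ad_cols(Q, cols); Kh <- ad_cols(K, cols); Vh <- ad_cols(V, cols)
    A <- ad_softmax_rows(ad_scale(ad_tcrossprod(Qh, Kh), 1 / sqrt(dh)))
    Hh <- ad_matmul(A, Vh)
    heads <- if (is.null(heads)) Hh else ad_cbind(heads, Hh)
  }
  X <- ad_layernorm(ad_add(X, ad_dropout(ad_matmul(heads, Wo), dropout)),
                    params[[paste0("L", layer, ".g1")]],
                    params[[paste0("L", layer, ".n1")]])
  W1 <- params[[paste0("L", layer, ".W1")]]; b1 <- params[[paste0("L", layer, ".b1")]]
  W2 <- params[[paste0("L", layer, ".W2")]]; b2 <- params[[paste0("L", layer, ".b2")]]
  ff <- ad_dropout(ad_matmul(ad_relu(ad_add(ad_matmul(X, W1), b1)), W2), dropout)
  ad_layernorm(ad_add(X, ad_add(ff, b2)),
               params[[paste0("L", layer, ".g2")]],
               params[[paste0("L", layer, ".n2")]])
}

#' Encode a token sequence into contextual vectors
#'
#' Wraps the sentence in `[CLS]`/`[SEP]`, sums the three embedding tables
#' and applies the transformer layers. With `n_layers = 0` encoding reduces
#' to the embedding sum. Deterministic given parameters and input.
#'
#' @param tokens character vector (without special tokens).
#' @param params encoder parameter list from the fitted model (or
#'   [init_encoder_params()]).
#' @param cfg an `rx_encoder_config`.
#' @param graph if `TRUE` return the `ad_node` (gradient flows to the
#'   embedding tables); otherwise a plain numeric matrix.
#' @param dropout dropout rate applied to the embedding sum and inside each
#'   layer; use only during training (0 at inference).
#' @return (n + 2) x dim contextual vectors including the `[CLS]`/`[SEP]`
#'   rows.
#' @export
encode_tokens <- function(tokens, params, cfg, graph = FALSE, dropout = 0) {
  if (length(tokens) + 2L > cfg$max_len) {
    warning("sentence truncated from ", length(tokens), " to ", cfg$max_len - 2L, " tokens")
    tokens <- tokens[seq_len(cfg$max_len - 2L)]
  }
  ids <- token_ids(c("[CLS]", tokens, "[SEP]"), cfg$vocab)
  X <- embed_tokens(ids, params[c("E_C", "E_S", "E_P")])
  X <- ad_dropout(as_ad(X), dropout)
  if (cfg$n_layers > 0L) {
    for (l in seq_len(cfg$n_layers)) X <- encoder_layer(X, params, l, cfg, dropout)
  }
  if (graph) X else X$value
}

# ---- FGM perturbation ------------------------------------------------------

#' Fast-gradient-method perturbation of the word-embedding table
#'
#' Computes `delta = epsilon * g / ||g||_2` where `g` is the loss gradient
#' at the word-embedding table and the norm is the Frobenius norm over the
#' whole table (the perturbation is shared by all samples). A zero gradient
#' yields a zero perturbation.
#'
#' @param g gradient matrix at the word embeddings (finite).
#' @param epsilon perturbation scale (default 0.005).
#' @return List with `delta` (matrix like `g`) and `epsilon`, class
#'   `rx_perturbation`.
#' @export
fgm_delta <- function(g, epsilon = 0.005) {
  if (!all(is.finite(g))) stop("non-finite gradient passed to fgm_delta")
  nrm <- sqrt(sum(g * g))
  delta <- if (nrm == 0) g * 0 else epsilon * g / nrm
  structure(list(delta = delta, epsilon = epsilon), class = "rx_perturbation")
}

#' Apply a perturbation to an embedding table, run code, restore
#'
#' Adds `perturbation$delta` to the table held by the parameter node, runs
#' `fn()`, and restores the original table bit-for-bit on exit (also on
#' error). Nesting is refused: only one perturbation may be active.
#'
#' @param table_node an `ad_node` parameter (the word-embedding table).
#' @param perturbation an `rx_perturbation` from [fgm_delta()].
#' @param fn zero-argument function evaluated while the table is perturbed.
#' @return The value of `fn()`.
#' @export
with_perturbation <- function(table_node, perturbation, fn) {
  stopifnot(is_ad_node(table_node), inherits(perturbation, "rx_perturbation"))
  if (isTRUE(table_node$perturbed)) stop("a perturbation is already active on this table")
  if (!identical(dim(table_node$value), dim(perturbation$delta)))
    stop("perturbation shape does not match the embedding table")
  original <- table_node$value
  table_node$perturbed <- TRUE
  table_node$value <- original + perturbation$delta
  on.exit({ table_node$value <- original; table_node$perturbed <- FALSE })
  fn()
}
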