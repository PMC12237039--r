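# Model assembly, the two-pass adversarial training step, and the `relexr()`
# fitting function with its S3 methods.

#' Training control parameters
#'
#' @param lr Adam learning rate (default 1e-4, the standard fine-tuning
#'   rate for this architecture family; from-scratch tiny encoders want
#'   around 3e-3).
#' @param weight_decay decoupled (AdamW-style) weight decay (default 0.01).
#' @param dropout encoder dropout rate during training (default 0.1).
#' @param batch_size sentences per optimizer step (default 8).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs without improvement of
#'   the dev exact-triple micro F1 (default 30).
#' @param epsilon FGM perturbation scale at the word-embedding table
#'   (default 0.005); 0 disables the perturbation but keeps the two-pass
#'   schedule.
#' @param loss_weights length-3 weights of the relation / matrix / tagging
#'   losses, default equal proportions.
#' @param negative_relations non-gold relations given all-O tag rows per
#'   example (default 2).
#' @param lambda relation decision threshold (default 0.5).
#' @param lambda_g pair-matrix filter threshold (default 0.5).
#' @param lr_decay if `TRUE` (default) the learning rate follows a cosine
#'   schedule from `lr` down to `lr/10` across `max_epochs`.
#' @param mask_rate whole-word masking rate applied to training inputs as
#   denoising augmentation (labels unchanged); default 0 (off): masking a
#   short object mention deletes the only evidence for its relation while
#   the label still demands it, which at small corpus sizes adds more label
#   noise than regularization.
#' @param seed integer seed covering initialization, batching and negative
#'   sampling.
#' @return A list of class `rx_train_control`.
#' @export
train_control <- function(lr = 1e-4, batch_size = 8L, max_epochs = 200L,
                          patience = 30L, epsilon = 0.005,
                          loss_weights = c(1, 1, 1), negative_relations = 2L,
                          lambda = 0.5, lambda_g = 0.5, weight_decay = 0.01,
                          dropout = 0.1, lr_decay = TRUE, mask_rate = 0,
                          seed = 1L) {
  if (lr <= 0) stop("learning rate must be positive")
  if (patience < 1L) stop("patience must be >= 1")
  structure(list(lr = lr, weight_decay = weight_decay, dropout = dropout,
                 lr_decay = lr_decay, mask_rate = mask_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 epsilon = epsilon, loss_weights = loss_weights,
                 negative_relations = as.integer(negative_relations),
                 lambda = lambda, lambda_g = lambda_g, seed = as.integer(seed)),
            class = "rx_train_control")
}

init_model <- function(schema, enc_cfg, alpha = 1/3, beta = 1/3, gamma = 1/3,
                       window = 4L, lambda = 0.5, lambda_g = 0.5,
                       rel_dim = enc_cfg$dim, trainable_fusion = FALSE) {
  n_r <- length(schema)
  d <- enc_cfg$dim
  rel <- relation_head_params(d, n_r, alpha, beta, gamma, window, lambda)
  if (trainable_fusion) {
    rel$alpha <- ad_param(matrix(alpha, 1L, 1L))
    rel$beta <- ad_param(matrix(beta, 1L, 1L))
    rel$gamma <- ad_param(matrix(gamma, 1L, 1L))
  }
  model <- structure(list(
    schema = schema,
    enc_cfg = enc_cfg,
    encoder = init_encoder_params(enc_cfg),
    rel_head = rel,
    pair_head = pair_matrix_params(d),
    tagger = tagger_params(d, n_r, rel_dim),
    lambda = lambda, lambda_g = lambda_g,
    history = NULL, best_epoch = NA_integer_
  ), class = "relexr")
  model
}

# flat list of every trainable parameter node
model_params <- function(model) {
  is_par <- function(x) is_ad_node(x) && x$requires
  c(Filter(is_par, model$encoder), Filter(is_par, model$rel_head),
    Filter(is_par, model$pair_head), Filter(is_par, model$tagger))
}

# joint loss graph for one example; labels from build_labels()
example_loss_graph <- function(model, example, labels, weights = c(1, 1, 1),
                               dropout = 0) {
  n <- length(example$tokens)
  h_full <- encode_tokens(example$tokens, model$encoder, model$enc_cfg, graph = TRUE,
                          dropout = dropout)
  h <- ad_rows(h_full, 1L + seq_len(n))  # drop [CLS]/[SEP]
  loss1 <- ad_sigmoid_bce(relation_logits(h, example$words, model$rel_head),
                          matrix(labels$relation_vector, 1L))
  loss2 <- ad_sigmoid_bce(pair_matrix_logits(h, model$pair_head), labels$pair_matrix)
  sel <- labels$selected_relations
  n_pot <- length(sel)
  loss3 <- ad_const(matrix(0, 1L, 1L))
  if (n_pot > 0L) {
    norm3 <- 2 * n * n_pot
    for (k in seq_along(sel)) {
      lg <- tagger_logits(h, sel[[k]], model$tagger)
      ts <- match(labels$bio_subject[[k]], BIO_LEVELS)
      to <- match(labels$bio_object[[k]], BIO_LEVELS)
      loss3 <- ad_add(loss3, ad_add(ad_softmax_ce_rows(lg$sub, ts, norm = norm3),
                                    ad_softmax_ce_rows(lg$obj, to, norm = norm3)))
    }
  }
  total <- ad_add(ad_add(ad_scale(loss1, weights[1]), ad_scale(loss2, weights[2])),
                  ad_scale(loss3, weights[3]))
  list(total = total,
       loss1 = as.numeric(loss1$value), loss2 = as.numeric(loss2$value),
       loss3 = as.numeric(loss3$value))
}

batch_loss_graph <- function(model, batch, labels, weights, dropout = 0) {
  acc <- NULL
  b1 <- b2 <- b3 <- 0
  for (i in seq_along(batch)) {
    g <- example_loss_graph(model, batch[[i]], labels[[i]], weights, dropout)
    scaled <- ad_scale(g$total, 1 / length(batch))
    acc <- if (is.null(acc)) scaled else ad_add(acc, scaled)
    b1 <- b1 + g$loss1; b2 <- b2 + g$loss2; b3 <- b3 + g$loss3
  }
  nb <- length(batch)
  list(total = acc, breakdown = loss_breakdown(b1 / nb, b2 / nb, b3 / nb, weights))
}

#' One adversarial (two-pass FGM) optimization step
#'
#' Pass 1 computes the joint loss on the clean batch and backpropagates,
#' retaining gradients without updating. The FGM perturbation
#' `delta = epsilon g / ||g||_2` is formed from the word-embedding gradient
#' and added to the shared embedding table; pass 2 backpropagates the
#' perturbed loss on top of the retained gradients. The table is restored
#' bit-for-bit before a single Adam update applies the summed gradients.
#'
#' @param model a `relexr` model (parameters are updated in place).
#' @param batch list of `rx_example`.
#' @param labels list of label sets from [build_labels()], one per example.
#' @param opt Adam state from [adam_init()].
#' @param epsilon FGM scale.
#' @param weights length-3 loss weights.
#' @param dropout encoder dropout rate for both passes of this step.
#' @return List with `breakdown` (clean-pass `rx_loss_breakdown`) and the
#'   updated `opt`.
#' @export
adversarial_step <- function(model, batch, labels, opt, epsilon = 0.005,
                             weights = c(1, 1, 1), dropout = 0) {
  plist <- model_params(model)
  ad_zero_grad(plist)
  pass1 <- batch_loss_graph(model, batch, labels, weights, dropout)
  if (!is.finite(as.numeric(pass1$total$value)))
    stop("non-finite loss; aborting step")
  ad_backward(pass1$total)
  g <- model$encoder$E_C$grad
  if (is.null(g)) g <- model$encoder$E_C$value * 0
  delta <- fgm_delta(g, epsilon)
  with_perturbation(model$encoder$E_C, delta, function() {
    pass2 <- batch_loss_graph(model, batch, labels, weights, dropout)
    if (!is.finite(as.numeric(pass2$total$value)))
      stop("non-finite loss in perturbed pass; aborting step")
    ad_backward(pass2$total)
  })
  opt <- adam_step(opt, plist)
  list(breakdown = pass1$breakdown, opt = opt)
}

#' Fit the joint triple-extraction model
#'
#' Trains the three-stage extractor (relation classifier, global
#' correspondence matrix, relation-conditioned BIO taggers over a shared
#' tiny transformer encoder) with the two-pass FGM schedule and equal-weight
#' joint loss. Early stopping monitors exact-triple micro F1 on `dev`;
#' the best-scoring parameters are retained.
#'
#' @param x training corpus: list of `rx_example` (e.g. from
#'   [generate_corpus()] or [read_corpus()]).
#' @param dev held-out corpus for early stopping; `NULL` monitors training
#'   F1 instead.
#' @param schema an `rx_schema`; defaults to the corpus attribute.
#' @param dim,n_layers,n_heads tiny-encoder size (defaults 32/2/2).
#' @param alpha,beta,gamma fusion weights (default 1/3 each).
#' @param window window size of the third pooling level (default 4).
#' @param trainable_fusion make the fusion weights trainable scalars.
#' @param control an `rx_train_control`.
#' @param verbose print per-epoch progress.
#' @return An object of class `relexr` with the fitted parameters, the
#'   vocabulary, and a `history` data frame (per-epoch losses and dev F1).
#' @export
relexr <- function(x, dev = NULL, schema = attr(x, "schema"),
                   dim = 32L, n_layers = 2L, n_heads = 2L,
                   alpha = 1/3, beta = 1/3, gamma = 1/3, window = 4L,
                   trainable_fusion = FALSE,
                   control = train_control(), verbose = FALSE) {
  if (length(x) == 0L) stop("training corpus is empty")
  if (is.null(schema)) stop("a relation schema is required")
  set.seed(control$seed)
  vocab <- build_vocab(c(x, dev))
  max_len <- max(vapply(c(x, dev), function(e) length(e$tokens), 0L)) + 2L
  enc_cfg <- encoder_config(vocab, dim = dim, n_layers = n_layers,
                            n_heads = n_heads, max_len = max(max_len, 16L))
  model <- init_model(schema, enc_cfg, alpha, beta, gamma, window,
                      control$lambda, control$lambda_g,
                      trainable_fusion = trainable_fusion)
  plist <- model_params(model)
  opt <- adam_init(plist, lr = control$lr, weight_decay = control$weight_decay)
  monitor <- if (is.null(dev)) x else dev
  dcfg <- decode_config(control$lambda, control$lambda_g)

  best_f1 <- -Inf; best_values <- NULL; best_epoch <- 0L; stale <- 0L
  history <- data.frame()
  n_ex <- length(x)
  for (epoch in seq_len(control$max_epochs)) {
    if (isTRUE(control$lr_decay)) {
      frac <- (epoch - 1) / max(1L, control$max_epochs - 1L)
      opt$lr <- control$lr * (0.1 + 0.9 * (1 + cos(pi * frac)) / 2)
    }
    ord <- sample.int(n_ex)
    labels <- lapply(x, build_labels, schema = schema,
                     negative_relations = control$negative_relations)
    ep <- c(loss1 = 0, loss2 = 0, loss3 = 0, total = 0)
    nb <- 0L
    step_res <- NULL
    ok <- TRUE
    for (s in seq(1L, n_ex, by = control$batch_size)) {
      idx <- ord[s:min(s + control$batch_size - 1L, n_ex)]
      batch <- x[idx]
      if (control$mask_rate > 0) {
        batch <- lapply(batch, function(ex) {
          masked <- mask_whole_words(ex$tokens, ex$words, vocab,
                                     select_rate = control$mask_rate)
          ex$tokens <- masked$tokens
          ex
        })
      }
      step_res <- tryCatch(
        adversarial_step(model, batch, labels[idx], opt,
                         epsilon = control$epsilon, weights = control$loss_weights,
                         dropout = control$dropout),
        error = function(e) e)
      if (inherits(step_res, "error")) {
        warning("training aborted at epoch ", epoch, ": ", conditionMessage(step_res),
                "; keeping last good checkpoint")
        ok <- FALSE
        break
      }
      opt <- step_res$opt
      bd <- step_res$breakdown
      ep <- ep + c(bd$loss1, bd$loss2, bd$loss3, bd$total)
      nb <- nb + 1L
    }
    if (!ok) break
    ep <- ep / nb
    preds <- lapply(monitor, extract_triples, model = model, config = dcfg)
    f1 <- corpus_f1(monitor, preds)
    history <- rbind(history, data.frame(epoch = epoch, loss1 = ep[["loss1"]],
                                         loss2 = ep[["loss2"]], loss3 = ep[["loss3"]],
                                         total = ep[["total"]], dev_f1 = f1))
    if (verbose) message(sprintf("epoch %3d  loss %.4f  dev F1 %.3f", epoch,
                                 ep[["total"]], f1))
    if (f1 > best_f1) {
      best_f1 <- f1; best_epoch <- epoch; stale <- 0L
      best_values <- lapply(plist, function(p) p$value)
    } else {
      stale <- stale + 1L
      if (stale >= control$patience) break
    }
    if (f1 >= 1) break  # cannot improve further
  }
  if (!is.null(best_values)) {
    for (i in seq_along(plist)) plist[[i]]$value <- best_values[[i]]
  }
  model$history <- history
  model$best_epoch <- best_epoch
  model$best_f1 <- best_f1
  model$control <- control
  model
}

corpus_f1 <- function(corpus, predictions) {
  counts <- list(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(corpus)) {
    m <- match_triples(predictions[[i]], corpus[[i]]$triples)
    counts$tp <- counts$tp + m$tp; counts$fp <- counts$fp + m$fp
    counts$fn <- counts$fn + m$fn
  }
  micro_prf(counts)[["f1"]]
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.relexr <- function(x, ...) {
  cat("Joint relational triple extractor (relexr)\n")
  cat(sprintf("  schema: %d relations; encoder: dim %d, %d layers, %d heads\n",
              length(x$schema), x$enc_cfg$dim, x$enc_cfg$n_layers, x$enc_cfg$n_heads))
  cat(sprintf("  vocabulary: %d tokens\n", x$enc_cfg$vocab_size))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat(sprintf("  trained %d epochs; best dev F1 %.3f at epoch %d\n",
                nrow(x$history), x$best_f1, x$best_epoch))
  } else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.relexr <- function(object, ...) {
  ps <- model_params(object)
  n_par <- sum(vapply(ps, function(p) length(p$value), 0))
  out <- list(n_relations = length(object$schema), n_parameters = n_par,
              dim = object$enc_cfg$dim, n_layers = object$enc_cfg$n_layers,
              history = object$history, best_epoch = object$best_epoch,
              best_f1 = object$best_f1)
  class(out) <- "summary.relexr"
  out
}

#' @export
print.summary.relexr <- function(x, ...) {
  cat(sprintf("relexr model: %d relations, %d trainable parameters (dim %d, %d layers)\n",
              x$n_relations, x$n_parameters, x$dim, x$n_layers))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    h <- x$history
    cat(sprintf("training: %d epochs, final joint loss %.4f, best dev F1 %.3f (epoch %d)\n",
                nrow(h), h$total[nrow(h)], x$best_f1, x$best_epoch))
  }
  invisible(x)
}

#' @export
coef.relexr <- function(object, ...) {
  flat <- model_params(object)
  lapply(flat, function(p) p$value)
}

#' Extract triples from new sentences
#'
#' @param object fitted `relexr` model.
#' @param newdata list of `rx_example` (gold triples, if present, are
#'   ignored).
#' @param lambda,lambda_g decode thresholds; default those of the fit.
#' @param ... unused.
#' @return List (one element per sentence) of lists of `rx_triple`.
#' @export
predict.relexr <- function(object, newdata, lambda = object$lambda,
                           lambda_g = object$lambda_g, ...) {
  cfg <- decode_config(lambda, lambda_g)
  lapply(newdata, extract_triples, model = object, config = cfg)
}

#' @export
plot.relexr <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch", ylab = "joint loss",
                 main = "training loss")
  graphics::lines(h$epoch, h$loss1, lty = 2)
  graphics::lines(h$epoch, h$loss2, lty = 3)
  graphics::lines(h$epoch, h$loss3, lty = 4)
  graphics::legend("topright", c("total", "relation", "matrix", "tagging"),
                   lty = 1:4, bty = "n", cex = 0.8)
  graphics::plot(h$epoch, h$dev_f1, type = "l", xlab = "epoch", ylab = "micro F1",
                 ylim = c(0, 1), main = "validation F1")
  invisible(x)
}

# ---- checkpointing ---------------------------------------------------------

#' Save a fitted model to disk
#'
#' Serializes parameter values, configuration, schema and history into a
#' single file readable by [load_model()].
#'
#' @param model fitted `relexr`.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  plist <- model_params(model)
  snap <- list(values = lapply(plist, function(p) p$value),
               names = names(plist),
               schema = unclass(model$schema),
               enc_cfg = model$enc_cfg,
               rel_meta = model$rel_head[c("alpha", "beta", "gamma", "window", "lambda")],
               trainable_fusion = is_ad_node(model$rel_head$alpha),
               lambda = model$lambda, lambda_g = model$lambda_g,
               history = model$history, best_epoch = model$best_epoch,
               best_f1 = model$best_f1,
               rel_dim = ncol(ad_value(model$tagger$r_emb)))
  if (snap$trainable_fusion) {
    snap$rel_meta$alpha <- as.numeric(ad_value(model$rel_head$alpha))
    snap$rel_meta$beta <- as.numeric(ad_value(model$rel_head$beta))
    snap$rel_meta$gamma <- as.numeric(ad_value(model$rel_head$gamma))
  }
  saveRDS(snap, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path checkpoint file.
#' @return A `relexr` model.
#' @export
load_model <- function(path) {
  snap <- readRDS(path)
  enc_cfg <- snap$enc_cfg
  model <- init_model(rx_schema(snap$schema), enc_cfg,
                      alpha = snap$rel_meta$alpha, beta = snap$rel_meta$beta,
                      gamma = snap$rel_meta$gamma, window = snap$rel_meta$window,
                      lambda = snap$lambda, lambda_g = snap$lambda_g,
                      rel_dim = snap$rel_dim,
                      trainable_fusion = isTRUE(snap$trainable_fusion))
  plist <- model_params(model)
  stopifnot(identical(names(plist), snap$names))
  for (i in seq_along(plist)) plist[[i]]$value <- snap$values[[i]]
  model$history <- snap$history
  model$best_epoch <- snap$best_epoch
  model$best_f1 <- snap$best_f1
  model
}
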