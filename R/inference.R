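# Decoding model outputs into triples: threshold the relation probabilities,
# tag subjects/objects per selected relation, decode BIO rows into spans,
# take the Cartesian product of spans, and keep pairs whose start positions
# score at least lambda_g in the global correspondence matrix.

#' Decode configuration
#'
#' @param lambda relation decision threshold (strict `>`); default 0.5.
#' @param lambda_g global-matrix filter threshold (`>=`); default 0.5.
#' @param max_spans optional cap on spans per role per relation
#'   (`Inf` = unlimited).
#' @return A list of class `rx_decode_config`.
#' @export
decode_config <- function(lambda = 0.5, lambda_g = 0.5, max_spans = Inf) {
  if (lambda <= 0 || lambda >= 1 || lambda_g <= 0 || lambda_g >= 1)
    stop("thresholds must lie in (0, 1)")
  structure(list(lambda = lambda, lambda_g = lambda_g, max_spans = max_spans),
            class = "rx_decode_config")
}

#' Select relations above the decision threshold
#'
#' @param p_rel probability vector.
#' @param lambda threshold; a relation is selected iff `p_rel > lambda`
#'   (strict).
#' @return Ascending integer ids.
#' @export
select_relations <- function(p_rel, lambda = 0.5) {
  which(as.numeric(p_rel) > lambda)
}

#' Pair subject and object spans and filter by matrix confidence
#'
#' Forms the Cartesian product of the decoded subject and object spans and
#' keeps a pair iff `matrix[sub$start, obj$start] >= lambda_g` (start
#' positions index the global correspondence matrix). Output is ordered by
#' (subject start, object start).
#'
#' @param sub_spans,obj_spans lists of `rx_span`.
#' @param matrix n x n global correspondence matrix.
#' @param lambda_g filter threshold.
#' @return List of `list(sub = , obj = )` span pairs.
#' @export
pair_and_filter <- function(sub_spans, obj_spans, matrix, lambda_g = 0.5) {
  out <- list()
  for (ss in sub_spans) for (os in obj_spans) {
    if (ss$start + 1L > nrow(matrix) || os$start + 1L > ncol(matrix))
      stop("span start outside the matrix range")
    if (matrix[ss$start + 1L, os$start + 1L] >= lambda_g)
      out[[length(out) + 1L]] <- list(sub = ss, obj = os)
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(p) p$sub$start * 1e6 + p$obj$start, 0)
    out <- out[order(key)]
  }
  out
}

# raw model outputs for one example; dispatch point for the oracle stub
model_outputs <- function(model, example) UseMethod("model_outputs")

#' @export
model_outputs.relexr <- function(model, example) {
  n <- length(example$tokens)
  h_full <- encode_tokens(example$tokens, model$encoder, model$enc_cfg)
  h <- h_full[1L + seq_len(n), , drop = FALSE]
  list(p_rel = as.numeric(classify_relations(h, example$words, model$rel_head)),
       pair = pair_matrix(h, model$pair_head),
       tag = function(r) tag_for_relation(h, r, model$tagger))
}

#' Perfect-prediction oracle stub
#'
#' A drop-in stand-in for a fitted model whose outputs are the gold labels
#' turned into hard probabilities (1 for gold relations, pairs and tags;
#' 0 elsewhere). Running the full decoding pipeline over it must recover
#' the gold triples exactly; used for pipeline-identity checks.
#'
#' @param schema an `rx_schema`.
#' @return An object usable as the `model` argument of [extract_triples()].
#' @export
perfect_oracle <- function(schema) {
  structure(list(schema = schema, lambda = 0.5, lambda_g = 0.5),
            class = c("relexr_oracle"))
}

#' @export
model_outputs.relexr_oracle <- function(model, example) {
  lab <- build_labels(example, model$schema, negative_relations = 0L)
  n <- length(example$tokens)
  tag_rows <- function(role, r) {
    k <- match(r, lab$selected_relations)
    probs <- matrix(0, n, 3L, dimnames = list(NULL, BIO_LEVELS))
    if (is.na(k)) { probs[, "O"] <- 1; return(probs) }
    tags <- if (role == "sub") lab$bio_subject[[k]] else lab$bio_object[[k]]
    probs[cbind(seq_len(n), match(tags, BIO_LEVELS))] <- 1
    probs
  }
  list(p_rel = as.numeric(lab$relation_vector),
       pair = lab$pair_matrix * 1,
       tag = function(r) list(p_sub = tag_rows("sub", r), p_obj = tag_rows("obj", r)))
}

#' Extract relational triples from one sentence
#'
#' Runs the three-stage decode: relations with probability above `lambda`
#' are selected; for each, the relation-conditioned tagger proposes subject
#' and object spans via [bio_decode()]; span pairs surviving the global
#' matrix filter are emitted as triples. Duplicates (same spans and
#' relation) are removed; output order is deterministic.
#'
#' @param example an `rx_example`.
#' @param model a fitted `relexr` or a [perfect_oracle()] stub.
#' @param config an `rx_decode_config`.
#' @return List of `rx_triple`.
#' @export
extract_triples <- function(example, model, config = decode_config(
                              model$lambda %||% 0.5, model$lambda_g %||% 0.5)) {
  out <- model_outputs(model, example)
  rels <- select_relations(out$p_rel, config$lambda)
  triples <- list()
  seen <- character(0)
  for (r in rels) {
    tg <- out$tag(r)
    sub_spans <- bio_decode(BIO_LEVELS[max.col(tg$p_sub, ties.method = "first")])
    obj_spans <- bio_decode(BIO_LEVELS[max.col(tg$p_obj, ties.method = "first")])
    if (is.finite(config$max_spans)) {
      sub_spans <- utils::head(sub_spans, config$max_spans)
      obj_spans <- utils::head(obj_spans, config$max_spans)
    }
    pairs <- pair_and_filter(sub_spans, obj_spans, out$pair, config$lambda_g)
    for (p in pairs) {
      tr <- rx_triple(p$sub, r, p$obj,
                      span_text(example, p$sub), span_text(example, p$obj))
      k <- triple_key(tr)
      if (!(k %in% seen)) {
        seen <- c(seen, k)
        triples[[length(triples) + 1L]] <- tr
      }
    }
  }
  triples
}

`%||%` <- function(a, b) if (is.null(a)) b else a
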