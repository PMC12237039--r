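# Template-based synthetic corpus generator.
#
# Emulates the statistical structure of plant-attribute text: sentences with
# 1-5+ triples, an overlap-pattern mix dominated by SEO (shared plant-name
# heads carrying several attributes), disjoint per-relation attribute
# vocabularies, and filler tokens between entity mentions so that span
# boundaries must actually be learned. Surface realism is not a goal.

#' Configuration for the synthetic corpus generator
#'
#' @param n_sentences number of sentences to generate.
#' @param pattern_mix named probabilities over the overlap patterns; the
#'   default (normal 10\%, seo 83\%, epo 2\%, soo 5\%) mirrors the
#'   composition observed in plant-attribute corpora, where most plants
#'   carry several attributes sharing the head entity.
#' @param triple_count_distribution probabilities over 1..5 triples per
#'   sentence; the 5th slot is the "5 or more" bucket, realized uniformly
#'   over 5-7. Default uniform.
#' @param schema an `rx_schema`; default the 13-category plant schema.
#' @param n_subjects size of the shared plant-name vocabulary.
#' @param objects_per_relation size of each relation's disjoint attribute
#'   vocabulary.
#' @param n_fillers size of the filler-token vocabulary.
#' @param rng_seed integer seed; generation is deterministic given the seed.
#' @return A list of class `rx_generator_config`.
#' @export
generator_config <- function(n_sentences = 100L,
                             pattern_mix = c(normal = 0.10, seo = 0.83,
                                             epo = 0.02, soo = 0.05),
                             triple_count_distribution = rep(0.2, 5L),
                             schema = default_schema(),
                             n_subjects = 24L,
                             objects_per_relation = 8L,
                             n_fillers = 10L,
                             rng_seed = 1L) {
  pats <- c("normal", "seo", "epo", "soo")
  if (!all(pats %in% names(pattern_mix)))
    stop("pattern_mix must name all of ", paste(pats, collapse = ", "))
  pattern_mix <- pattern_mix[pats]
  if (abs(sum(pattern_mix) - 1) > 1e-9) stop("pattern_mix must sum to 1")
  if (abs(sum(triple_count_distribution) - 1) > 1e-9)
    stop("triple_count_distribution must sum to 1")
  if (length(triple_count_distribution) != 5L)
    stop("triple_count_distribution has 5 slots: counts 1..4 and the 5+ bucket")
  structure(list(n_sentences = as.integer(n_sentences),
                 pattern_mix = pattern_mix,
                 triple_count_distribution = triple_count_distribution,
                 schema = schema,
                 n_subjects = as.integer(n_subjects),
                 objects_per_relation = as.integer(objects_per_relation),
                 n_fillers = as.integer(n_fillers),
                 rng_seed = as.integer(rng_seed)),
            class = "rx_generator_config")
}

gen_vocab <- function(config) {
  n_r <- length(config$schema)
  subjects <- sprintf("plant%02d", seq_len(config$n_subjects))
  objects <- lapply(seq_len(n_r), function(r)
    sprintf("%s_v%02d", config$schema[[r]], seq_len(config$objects_per_relation)))
  fillers <- sprintf("f%02d", seq_len(config$n_fillers))
  list(subjects = subjects, objects = objects, fillers = fillers)
}

# draw a subject mention: 1-2 tokens from the plant-name vocabulary.
# `used` holds tokens already spent in this sentence: mentions never share
# tokens, so first-occurrence span resolution on re-read is unambiguous.
draw_subject <- function(vocab, used) {
  repeat {
    k <- if (stats::runif(1) < 0.4) 2L else 1L
    toks <- sample(vocab$subjects, k)
    if (!any(toks %in% used)) return(toks)
  }
}

# draw an object mention for relation r: 1-2 tokens from its disjoint vocab
draw_object <- function(vocab, r, used) {
  pool <- vocab$objects[[r]]
  repeat {
    k <- if (stats::runif(1) < 0.35) 2L else 1L
    toks <- sample(pool, min(k, length(pool)))
    if (!any(toks %in% used)) return(toks)
  }
}

#' Generate one synthetic sentence
#'
#' Assembles entity mentions for the requested overlap pattern with filler
#' tokens interleaved so mentions are non-adjacent, and records gold spans.
#' Patterns are realized so that [classify_overlap()] on the gold triples
#' returns exactly the requested pattern: a shared subject for `seo`,
#' identical entity pairs under distinct relations for `epo`, an object
#' span containing the subject mention for `soo`.
#'
#' @param pattern one of `"normal"`, `"seo"`, `"epo"`, `"soo"`.
#' @param n_triples number of triples (incompatible requests are upgraded,
#'   e.g. `epo`/`seo` with 1 triple becomes 2).
#' @param config an `rx_generator_config` (supplies schema and vocabulary).
#' @param vocab internal vocabulary tables; built from `config` if omitted.
#' @return An `rx_example` carrying gold triples.
#' @export
generate_sentence <- function(pattern, n_triples, config = generator_config(),
                              vocab = gen_vocab(config)) {
  pattern <- match.arg(pattern, c("normal", "seo", "epo", "soo"))
  n_triples <- as.integer(n_triples)
  if (pattern %in% c("seo", "epo") && n_triples < 2L) n_triples <- 2L
  n_r <- length(config$schema)
  used <- character(0)
  fill <- function() sample(vocab$fillers, 1L)

  # a "mention plan": list of segments, each seg = list(tokens, role)
  # roles: "sub:<k>" / "obj:<k>" tie segments to triple slots, "fill" = noise
  segs <- list()
  push <- function(tokens, role) segs[[length(segs) + 1L]] <<- list(tokens = tokens, role = role)

  if (pattern == "seo") {
    rels <- sample(n_r, min(n_triples, n_r))
    if (length(rels) < n_triples) rels <- c(rels, sample(n_r, n_triples - length(rels), replace = TRUE))
    sub <- draw_subject(vocab, used); used <- c(used, sub)
    push(fill(), "fill"); push(sub, "sub:shared")
    for (k in seq_len(n_triples)) {
      obj <- draw_object(vocab, rels[[k]], used); used <- c(used, obj)
      push(fill(), "fill"); push(obj, paste0("obj:", k))
    }
    plan <- lapply(seq_len(n_triples), function(k)
      list(sub = "sub:shared", rel = rels[[k]], obj = paste0("obj:", k)))
  } else if (pattern == "epo") {
    # triples 1 and 2 share the entity pair under two distinct relations;
    # any remaining triples reuse the same shared subject (EPO precedence).
    rels <- sample(n_r, max(2L, min(n_triples, n_r)))
    sub <- draw_subject(vocab, used); used <- c(used, sub)
    obj <- draw_object(vocab, rels[[1L]], used); used <- c(used, obj)
    push(fill(), "fill"); push(sub, "sub:shared"); push(fill(), "fill"); push(obj, "obj:pair")
    plan <- list(list(sub = "sub:shared", rel = rels[[1L]], obj = "obj:pair"),
                 list(sub = "sub:shared", rel = rels[[2L]], obj = "obj:pair"))
    if (n_triples > 2L) for (k in 3L:n_triples) {
      r <- if (k <= length(rels)) rels[[k]] else sample(n_r, 1L)
      obj2 <- draw_object(vocab, r, used); used <- c(used, obj2)
      push(fill(), "fill"); push(obj2, paste0("obj:", k))
      plan[[k]] <- list(sub = "sub:shared", rel = r, obj = paste0("obj:", k))
    }
  } else if (pattern == "soo") {
    # triple 1's object span covers the subject mention plus an attribute
    # token: a contiguous "SUB ATTR" mention containing the subject.
    rels <- sample(n_r, min(max(n_triples, 1L), n_r))
    if (length(rels) < n_triples) rels <- c(rels, sample(n_r, n_triples - length(rels), replace = TRUE))
    sub <- draw_subject(vocab, used); used <- c(used, sub)
    attr_tok <- sample(vocab$objects[[rels[[1L]]]], 1L); used <- c(used, attr_tok)
    push(fill(), "fill"); push(c(sub, attr_tok), "soo:pair")
    plan <- list(list(sub = "soo:sub", rel = rels[[1L]], obj = "soo:obj"))
    if (n_triples > 1L) for (k in 2L:n_triples) {
      obj <- draw_object(vocab, rels[[k]], used); used <- c(used, obj)
      push(fill(), "fill"); push(obj, paste0("obj:", k))
      plan[[k]] <- list(sub = "soo:sub", rel = rels[[k]], obj = paste0("obj:", k))
    }
  } else { # normal: fully disjoint subject/object per triple
    rels <- sample(n_r, min(n_triples, n_r))
    if (length(rels) < n_triples) rels <- c(rels, sample(n_r, n_triples - length(rels), replace = TRUE))
    plan <- vector("list", n_triples)
    for (k in seq_len(n_triples)) {
      sub <- draw_subject(vocab, used); used <- c(used, sub)
      obj <- draw_object(vocab, rels[[k]], used); used <- c(used, obj)
      push(fill(), "fill"); push(sub, paste0("sub:", k))
      push(fill(), "fill"); push(obj, paste0("obj:", k))
      plan[[k]] <- list(sub = paste0("sub:", k), rel = rels[[k]], obj = paste0("obj:", k))
    }
  }
  push(fill(), "fill")

  # realize segments into tokens + word boundaries + role span lookup
  tokens <- character(0)
  words <- list()
  role_span <- list()
  for (seg in segs) {
    s <- length(tokens)
    tokens <- c(tokens, seg$tokens)
    e <- length(tokens)
    if (seg$role == "soo:pair") {
      # subject = all but last token; object = whole segment
      role_span[["soo:sub"]] <- rx_span(s, e - 1L)
      role_span[["soo:obj"]] <- rx_span(s, e)
      words[[length(words) + 1L]] <- rx_span(s, e - 1L)
      words[[length(words) + 1L]] <- rx_span(e - 1L, e)
    } else {
      if (seg$role != "fill") role_span[[seg$role]] <- rx_span(s, e)
      words[[length(words) + 1L]] <- rx_span(s, e)
    }
  }
  triples <- lapply(plan, function(p) {
    ss <- role_span[[p$sub]]; os <- role_span[[p$obj]]
    rx_triple(ss, p$rel, os,
              paste(tokens[(ss$start + 1L):ss$end], collapse = " "),
              paste(tokens[(os$start + 1L):os$end], collapse = " "))
  })
  # drop duplicate triples (can arise when relations repeat under seo)
  keys <- vapply(triples, triple_key, "")
  triples <- triples[!duplicated(keys)]
  rx_example(paste(tokens, collapse = " "), tokens, words, triples)
}

#' Generate a synthetic corpus
#'
#' Draws an overlap pattern and a triple count per sentence from the
#' configured distributions and realizes each with [generate_sentence()].
#' Deterministic given `config$rng_seed`; the generated pattern of every
#' sentence agrees with [classify_overlap()] on its gold triples.
#'
#' @param config an `rx_generator_config`.
#' @return List of `rx_example` with attributes `"schema"` and
#'   `"patterns"` (the requested pattern per sentence).
#' @export
generate_corpus <- function(config = generator_config()) {
  with_seed(config$rng_seed, {
    vocab <- gen_vocab(config)
    pats <- c("normal", "seo", "epo", "soo")
    examples <- vector("list", config$n_sentences)
    patterns <- character(config$n_sentences)
    for (i in seq_len(config$n_sentences)) {
      pattern <- sample(pats, 1L, prob = config$pattern_mix)
      slot <- sample.int(5L, 1L, prob = config$triple_count_distribution)
      n_triples <- if (slot == 5L) sample(5:7, 1L) else slot
      examples[[i]] <- generate_sentence(pattern, n_triples, config, vocab)
      patterns[[i]] <- pattern
    }
    attr(examples, "schema") <- config$schema
    attr(examples, "patterns") <- patterns
    examples
  })
}
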