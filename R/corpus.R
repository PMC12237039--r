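# Domain types and corpus I/O.
#
# Spans are token-indexed, 0-based, half-open [start, end): `start` is the
# index of the first token of the mention, `end` one past the last. Relation
# ids are 1-based indices into the schema (idiomatic R). The on-disk corpus
# is JSON-lines, one object per line:
#   {"text": str, "triple_list": [[subject, predicate, object], ...],
#    "words": [[start, end], ...]}   # "words" optional

#' Construct a token span
#'
#' @param start 0-based index of the first token (inclusive).
#' @param end 0-based index one past the last token (exclusive).
#' @return A list with elements `start` and `end`, class `rx_span`.
#' @export
rx_span <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid span [", start, ", ", end, ")")
  structure(list(start = start, end = end), class = "rx_span")
}

span_eq <- function(a, b) a$start == b$start && a$end == b$end

span_overlaps <- function(a, b) a$start < b$end && b$start < a$end

#' Construct a relational triple
#'
#' @param subject,object `rx_span` objects locating the mentions.
#' @param relation 1-based relation id into the schema.
#' @param subject_text,object_text surface strings of the mentions.
#' @return A list of class `rx_triple`.
#' @export
rx_triple <- function(subject, relation, object, subject_text = NULL,
                      object_text = NULL) {
  stopifnot(inherits(subject, "rx_span"), inherits(object, "rx_span"))
  relation <- as.integer(relation)
  if (is.na(relation) || relation < 1L) stop("relation id must be a positive integer")
  structure(list(subject = subject, relation = relation, object = object,
                 subject_text = subject_text, object_text = object_text),
            class = "rx_triple")
}

triple_key <- function(tr) {
  paste(tr$subject$start, tr$subject$end, tr$relation,
        tr$object$start, tr$object$end, sep = ":")
}

#' Construct a sentence example
#'
#' @param text raw sentence string.
#' @param tokens character vector of tokens.
#' @param words list of `rx_span` partitioning `[0, length(tokens))` into
#'   word units (whole-word masking and word-level pooling operate on these);
#'   defaults to one word per token.
#' @param triples list of `rx_triple`.
#' @return A list of class `rx_example`.
#' @export
rx_example <- function(text, tokens, words = NULL, triples = list()) {
  n <- length(tokens)
  if (is.null(words)) words <- lapply(seq_len(n) - 1L, function(i) rx_span(i, i + 1L))
  validate_word_partition(words, n)
  for (tr in triples) {
    if (tr$subject$end > n || tr$object$end > n)
      stop("triple span exceeds sentence length ", n)
  }
  structure(list(text = text, tokens = tokens, words = words, triples = triples),
            class = "rx_example")
}

validate_word_partition <- function(words, n) {
  pos <- 0L
  for (w in words) {
    if (w$start != pos) stop("word boundaries must partition [0, n) in order; gap at ", pos)
    pos <- w$end
  }
  if (pos != n) stop("word boundaries cover [0, ", pos, ") but sentence has ", n, " tokens")
  invisible(TRUE)
}

#' Construct a relation schema
#'
#' @param names ordered character vector of unique relation-category names.
#' @return Character vector of class `rx_schema`.
#' @export
rx_schema <- function(names) {
  names <- as.character(names)
  if (length(names) == 0L || anyDuplicated(names) || any(!nzchar(names)))
    stop("schema names must be unique and non-empty")
  structure(names, class = "rx_schema")
}

#' The default 13-category plant-attribute relation schema
#'
#' Relation categories for plant-attribute text: alias, family, morphology,
#' habit, habitat, distribution, flowering period, fruit period, flower
#' color, leaf shape, propagation, usage, cultural symbolism.
#'
#' @return An `rx_schema` of length 13.
#' @export
default_schema <- function() {
  rx_schema(c("alias", "family", "morphology", "habit", "habitat",
              "distribution", "flowering_period", "fruit_period",
              "flower_color", "leaf_shape", "propagation", "usage",
              "cultural_symbolism"))
}

# ---- tokenization ----------------------------------------------------------

#' Tokenize a sentence
#'
#' @param text input string.
#' @param mode `"whitespace"` (split on blanks; Latin/synthetic text) or
#'   `"character"` (one token per character, blanks dropped; Chinese text).
#' @return Character vector of tokens.
#' @export
tokenize <- function(text, mode = c("whitespace", "character")) {
  mode <- match.arg(mode)
  if (mode == "whitespace") {
    toks <- strsplit(trimws(text), "\\s+")[[1L]]
    toks[nzchar(toks)]
  } else {
    toks <- strsplit(text, "")[[1L]]
    toks[toks != " "]
  }
}

# locate the first occurrence of token subsequence `needle` in `haystack`;
# returns an rx_span or NULL
find_subsequence <- function(haystack, needle) {
  n <- length(haystack); m <- length(needle)
  if (m == 0L || m > n) return(NULL)
  for (i in seq_len(n - m + 1L)) {
    if (all(haystack[i:(i + m - 1L)] == needle)) return(rx_span(i - 1L, i - 1L + m))
  }
  NULL
}

# ---- corpus I/O ------------------------------------------------------------

#' Read a JSON-lines corpus
#'
#' Each line holds one sentence object with `"text"` and `"triple_list"`
#' (list of `[subject, predicate, object]` string records) and optionally
#' `"words"` (list of `[start, end)` token spans marking word units).
#' Mention spans are resolved against the tokenized text by first-occurrence
#' subsequence match. Duplicate triples are dropped with a warning.
#'
#' @param path file path.
#' @param schema an `rx_schema`; `NULL` infers one from the predicates seen
#'   (sorted order).
#' @param tokenizer `"whitespace"` or `"character"`, see [tokenize()].
#' @return List of `rx_example`, in input order, with attribute `"schema"`.
#' @export
read_corpus <- function(path, schema = NULL, tokenizer = "whitespace") {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stop("line ", i, ": malformed JSON: ", conditionMessage(e),
                               call. = FALSE))
    if (is.null(rec$text) || is.null(rec$triple_list))
      stop("line ", i, ": missing \"text\" or \"triple_list\"", call. = FALSE)
    records[[i]] <- rec
  }
  if (is.null(schema)) {
    preds <- unique(unlist(lapply(records, function(r)
      vapply(r$triple_list, function(t) as.character(t[[2L]]), ""))))
    schema <- rx_schema(sort(preds))
  }
  examples <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    tokens <- tokenize(rec$text, tokenizer)
    words <- NULL
    if (!is.null(rec$words)) {
      words <- lapply(rec$words, function(w) rx_span(w[[1L]], w[[2L]]))
    }
    triples <- list()
    seen <- character(0)
    for (t in rec$triple_list) {
      sub_s <- as.character(t[[1L]]); rel_s <- as.character(t[[2L]]); obj_s <- as.character(t[[3L]])
      rel <- match(rel_s, schema)
      if (is.na(rel)) stop("line ", i, ": predicate \"", rel_s, "\" not in schema", call. = FALSE)
      sub_span <- find_subsequence(tokens, tokenize(sub_s, tokenizer))
      obj_span <- find_subsequence(tokens, tokenize(obj_s, tokenizer))
      if (is.null(sub_span) || is.null(obj_span))
        stop("line ", i, ": triple (", sub_s, ", ", rel_s, ", ", obj_s,
             ") has a mention not found in text", call. = FALSE)
      tr <- rx_triple(sub_span, rel, obj_span, sub_s, obj_s)
      k <- triple_key(tr)
      if (k %in% seen) {
        warning("line ", i, ": duplicate triple (", sub_s, ", ", rel_s, ", ",
                obj_s, ") dropped", call. = FALSE)
        next
      }
      seen <- c(seen, k)
      triples[[length(triples) + 1L]] <- tr
    }
    examples[[i]] <- rx_example(rec$text, tokens, words, triples)
  }
  attr(examples, "schema") <- schema
  examples
}

#' Write a corpus as JSON-lines
#'
#' @param examples list of `rx_example`.
#' @param path output file path.
#' @param schema `rx_schema` used to name predicates; defaults to the
#'   corpus's `"schema"` attribute.
#' @export
write_corpus <- function(examples, path, schema = attr(examples, "schema")) {
  if (is.null(schema)) stop("a schema is required to name predicates")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (ex in examples) {
    rec <- list(
      text = ex$text,
      triple_list = lapply(ex$triples, function(tr) {
        list(span_text(ex, tr$subject), schema[[tr$relation]], span_text(ex, tr$object))
      }),
      words = lapply(ex$words, function(w) c(w$start, w$end))
    )
    line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(NULL)
}

span_text <- function(ex, span) {
  paste(ex$tokens[(span$start + 1L):span$end], collapse = " ")
}

# ---- supervision labels ----------------------------------------------------

#' Build supervision labels for one example
#'
#' Produces the three label structures the joint model is trained against:
#' a multi-hot relation vector, an n-by-n subject/object start-pair matrix,
#' and per-relation BIO tag rows for the subject and object roles. Tag rows
#' are built for every gold relation plus `negative_relations` sampled
#' non-gold relations whose rows are all `O`.
#'
#' @param example an `rx_example`.
#' @param schema an `rx_schema`.
#' @param negative_relations how many non-gold relations receive all-`O` tag
#'   rows (clamped to the number available, with a warning).
#' @param rng_seed optional integer seed for the negative sampling.
#' @return A list with `relation_vector` (length `n_r` 0/1),
#'   `pair_matrix` (n-by-n 0/1), `selected_relations` (integer ids),
#'   `bio_subject` and `bio_object` (each a list, indexed like
#'   `selected_relations`, of length-n character vectors over B/I/O).
#' @export
build_labels <- function(example, schema, negative_relations = 2L, rng_seed = NULL) {
  n <- length(example$tokens)
  n_r <- length(schema)
  for (tr in example$triples) {
    if (tr$relation > n_r) stop("triple relation id ", tr$relation, " outside schema")
  }
  relation_vector <- integer(n_r)
  pair_matrix <- matrix(0L, n, n)
  gold <- sort(unique(vapply(example$triples, function(tr) tr$relation, 0L)))
  relation_vector[gold] <- 1L
  for (tr in example$triples) {
    pair_matrix[tr$subject$start + 1L, tr$object$start + 1L] <- 1L
  }
  avail <- setdiff(seq_len(n_r), gold)
  k <- negative_relations
  if (k > length(avail)) {
    warning("negative_relations clamped from ", k, " to ", length(avail))
    k <- length(avail)
  }
  negs <- integer(0)
  if (k > 0L) {
    if (!is.null(rng_seed)) {
      negs <- with_seed(rng_seed, sample(avail, k))
    } else {
      negs <- if (length(avail) == 1L) avail else sample(avail, k)
    }
  }
  selected <- c(gold, sort(negs))
  bio_subject <- bio_object <- vector("list", length(selected))
  for (si in seq_along(selected)) {
    r <- selected[[si]]
    sub_row <- rep("O", n); obj_row <- rep("O", n)
    for (tr in example$triples) {
      if (tr$relation != r) next
      sub_row <- mark_bio(sub_row, tr$subject)
      obj_row <- mark_bio(obj_row, tr$object)
    }
    bio_subject[[si]] <- sub_row
    bio_object[[si]] <- obj_row
  }
  list(relation_vector = relation_vector, pair_matrix = pair_matrix,
       selected_relations = selected, bio_subject = bio_subject,
       bio_object = bio_object)
}

mark_bio <- function(row, span) {
  idx <- (span$start + 1L):span$end
  row[idx] <- "I"
  row[idx[1L]] <- "B"
  row
}

# evaluate expr under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Decode a BIO tag sequence into spans
#'
#' A span starts at each `B` and extends through the maximal run of
#' following `I` tags. An orphan `I` (not preceded by `B` or `I`) is
#' ignored rather than promoted to `B`: conservative decoding never
#' hallucinates a span whose start the tagger did not commit to.
#'
#' @param tags character vector over `B`, `I`, `O`.
#' @return List of `rx_span`.
#' @export
bio_decode <- function(tags) {
  if (length(tags) == 0L) return(list())
  if (!all(tags %in% c("B", "I", "O"))) stop("tags must be drawn from {B, I, O}")
  spans <- list()
  i <- 1L; n <- length(tags)
  while (i <= n) {
    if (tags[[i]] == "B") {
      j <- i + 1L
      while (j <= n && tags[[j]] == "I") j <- j + 1L
      spans[[length(spans) + 1L]] <- rx_span(i - 1L, j - 1L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  spans
}

#' Classify the overlap pattern of a sentence's triples
#'
#' Assigns exactly one label per sentence with precedence
#' EPO > SOO > SEO > normal (the rarest, most specific pattern wins):
#' \describe{
#'   \item{epo}{two triples share both subject and object spans (entity
#'     pair overlap).}
#'   \item{soo}{some subject span overlaps some object span, within or
#'     across triples (subject-object overlap).}
#'   \item{seo}{two triples share exactly one of subject/object span
#'     (single entity overlap).}
#'   \item{normal}{no sharing.}
#' }
#'
#' @param triples non-empty list of `rx_triple`.
#' @return One of `"normal"`, `"seo"`, `"epo"`, `"soo"`.
#' @export
classify_overlap <- function(triples) {
  if (length(triples) == 0L) stop("cannot classify an empty triple list")
  m <- length(triples)
  # epo
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (span_eq(triples[[i]]$subject, triples[[j]]$subject) &&
          span_eq(triples[[i]]$object, triples[[j]]$object)) return("epo")
    }
  }
  # soo: any subject span overlapping any object span
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (span_overlaps(triples[[i]]$subject, triples[[j]]$object)) return("soo")
  }
  # seo: a pair sharing subject or object span
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      if (span_eq(triples[[i]]$subject, triples[[j]]$subject) ||
          span_eq(triples[[i]]$object, triples[[j]]$object)) return("seo")
    }
  }
  "normal"
}
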