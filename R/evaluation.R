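# Exact-match scoring: a predicted triple counts only when subject,
# relation and object all match the gold triple. Reports micro
# precision/recall/F1 overall and stratified by overlap pattern and by the
# number of gold triples per sentence.

#' Match predicted against gold triples
#'
#' @param predicted,gold lists of `rx_triple` (deduplicated).
#' @param mode `"span"` compares token spans plus relation (default,
#'   stricter when the same surface string occurs twice); `"string"`
#'   compares surface strings plus relation.
#' @return List with `tp`, `fp`, `fn`.
#' @export
match_triples <- function(predicted, gold, mode = c("span", "string")) {
  mode <- match.arg(mode)
  key <- function(tr) {
    if (mode == "span") triple_key(tr)
    else paste(tr$subject_text, tr$relation, tr$object_text, sep = "\r")
  }
  pk <- unique(vapply(predicted, key, ""))
  gk <- unique(vapply(gold, key, ""))
  tp <- length(intersect(pk, gk))
  list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

#' Micro precision, recall and F1
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`; each is 0 when its
#' denominator is 0.
#'
#' @param counts list with `tp`, `fp`, `fn`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
micro_prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

count_bucket <- function(n) if (n >= 5L) "N>=5" else paste0("N=", n)

#' Stratified evaluation report
#'
#' Scores predictions against gold triples overall and within strata: each
#' sentence is assigned one overlap pattern by [classify_overlap()] and one
#' triple-count bucket (N=1..4, N>=5). Stratum counts sum exactly to the
#' overall counts.
#'
#' @param corpus list of `rx_example` carrying gold triples.
#' @param predictions list of predicted triple lists, one per example.
#' @param mode match mode, see [match_triples()].
#' @return Data frame of class `rx_eval_report` with columns `stratum`,
#'   `n_sentences`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
stratified_report <- function(corpus, predictions, mode = "span") {
  if (length(corpus) != length(predictions))
    stop("corpus and predictions differ in length (", length(corpus), " vs ",
         length(predictions), ")")
  strata <- c("overall", "normal", "seo", "epo", "soo",
              "N=1", "N=2", "N=3", "N=4", "N>=5")
  zero <- function() list(tp = 0L, fp = 0L, fn = 0L, n = 0L)
  acc <- stats::setNames(lapply(strata, function(s) zero()), strata)
  bump <- function(s, m) {
    acc[[s]]$tp <<- acc[[s]]$tp + m$tp
    acc[[s]]$fp <<- acc[[s]]$fp + m$fp
    acc[[s]]$fn <<- acc[[s]]$fn + m$fn
    acc[[s]]$n <<- acc[[s]]$n + 1L
  }
  for (i in seq_along(corpus)) {
    gold <- corpus[[i]]$triples
    m <- match_triples(predictions[[i]], gold, mode)
    bump("overall", m)
    if (length(gold) > 0L) {
      bump(classify_overlap(gold), m)
      bump(count_bucket(length(gold)), m)
    }
  }
  rows <- lapply(strata, function(s) {
    a <- acc[[s]]
    prf <- micro_prf(a)
    data.frame(stratum = s, n_sentences = a$n, tp = a$tp, fp = a$fp, fn = a$fn,
               precision = prf[["precision"]], recall = prf[["recall"]],
               f1 = prf[["f1"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rx_eval_report", class(out))
  out
}
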