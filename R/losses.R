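# Joint loss: three equally weighted terms.
#
#   loss1 - binary cross-entropy over the relation slots (mean over n_r)
#   loss2 - binary cross-entropy over the n x n pair-matrix cells (mean
#           over the unmasked cells)
#   loss3 - categorical cross-entropy of the B/I/O tag rows, averaged over
#           2 roles x selected relations x tokens
#
# These plain-numeric functions are the reporting/reference surface; the
# training graph computes the same quantities with fused stable ops and is
# tested for agreement against them.

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Relation-classification loss
#'
#' Mean binary cross-entropy over the relation slots:
#' `-(1/n_r) sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]`.
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p_rel probability vector in (0,1).
#' @param y_rel 0/1 vector of the same length.
#' @return Scalar loss.
#' @export
relation_loss <- function(p_rel, y_rel) {
  p <- clip01(as.numeric(p_rel)); y <- as.numeric(y_rel)
  stopifnot(length(p) == length(y))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Pair-matrix loss
#'
#' Mean binary cross-entropy over the unmasked cells of the global
#' correspondence matrix (normalizer = number of real-token cells).
#'
#' @param p n x n probability matrix.
#' @param y n x n 0/1 label matrix.
#' @param mask optional logical real-token vector; only cells with both
#'   row and column real enter the sum and the normalizer.
#' @return Scalar loss.
#' @export
matrix_loss <- function(p, y, mask = NULL) {
  stopifnot(all(dim(p) == dim(y)))
  keep <- if (is.null(mask)) matrix(TRUE, nrow(p), ncol(p)) else outer(mask, mask, "&")
  pc <- clip01(p[keep]); yc <- y[keep]
  -mean(yc * log(pc) + (1 - yc) * log(1 - pc))
}

#' Tagging loss
#'
#' `-(1 / (2 n n_pot)) sum` over the two roles, the selected relations and
#' the (unmasked) tokens of `log p(true tag)`, where `n` is the number of
#' unmasked tokens and `n_pot` the number of selected relations. Returns 0
#' when no relations are selected.
#'
#' @param pred list with `sub` and `obj`: each a list (per selected
#'   relation) of n x 3 tag distributions (columns B, I, O).
#' @param labels list with `bio_subject` and `bio_object`: each a list of
#'   length-n character tag rows.
#' @param mask optional logical real-token vector.
#' @return Scalar loss.
#' @export
tagging_loss <- function(pred, labels, mask = NULL) {
  n_pot <- length(pred$sub)
  if (n_pot == 0L) return(0)
  stopifnot(length(pred$obj) == n_pot,
            length(labels$bio_subject) == n_pot,
            length(labels$bio_object) == n_pot)
  n_tok <- nrow(pred$sub[[1L]])
  keep <- if (is.null(mask)) rep(TRUE, n_tok) else mask
  n <- sum(keep)
  if (n == 0L) return(0)
  total <- 0
  for (k in seq_len(n_pot)) {
    for (role in c("sub", "obj")) {
      probs <- pred[[role]][[k]]
      tags <- if (role == "sub") labels$bio_subject[[k]] else labels$bio_object[[k]]
      idx <- match(tags, BIO_LEVELS)
      picked <- clip01(probs[cbind(seq_len(n_tok), idx)])
      total <- total + sum(log(picked)[keep])
    }
  }
  -total / (2 * n * n_pot)
}

#' Combine the three loss terms
#'
#' @param loss1,loss2,loss3 scalar losses.
#' @param weights length-3 vector, default equal proportions `c(1, 1, 1)`.
#' @return List of class `rx_loss_breakdown` with the three terms and
#'   `total`.
#' @export
loss_breakdown <- function(loss1, loss2, loss3, weights = c(1, 1, 1)) {
  structure(list(loss1 = loss1, loss2 = loss2, loss3 = loss3,
                 total = weights[1] * loss1 + weights[2] * loss2 + weights[3] * loss3),
            class = "rx_loss_breakdown")
}
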