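# Minimal reverse-mode automatic differentiation over base R matrices.
#
# Nodes are environments carrying a matrix `value`, an accumulated `grad`,
# their `parents` and a `backfn` mapping the incoming gradient to a list of
# parent gradients. Creation order is a valid topological order, so backward
# walks reachable nodes sorted by id in reverse. Gradients ACCUMULATE into
# parameter nodes until `ad_zero_grad()` — this is what the two-pass
# adversarial schedule relies on.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

ad_new_node <- function(value, parents = list(), backfn = NULL, requires = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1L
  e$id <- .ad_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  if (is.null(requires)) {
    requires <- FALSE
    for (p in parents) if (p$requires) { requires <- TRUE; break }
  }
  e$requires <- requires
  class(e) <- "ad_node"
  e
}

#' Create a trainable parameter node
#'
#' Wraps a numeric matrix as a leaf node of the computation graph whose
#' gradient is accumulated by [ad_backward()].
#'
#' @param value numeric matrix (vectors are promoted to 1-column matrices).
#' @return An `ad_node` with `requires = TRUE`.
#' @keywords internal
ad_param <- function(value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_new_node(value, requires = TRUE)
}

ad_const <- function(value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_new_node(value, requires = FALSE)
}

is_ad_node <- function(x) is.environment(x)  # only ad_nodes are environments here

as_ad <- function(x) if (is_ad_node(x)) x else ad_const(x)

ad_value <- function(x) if (is_ad_node(x)) x$value else x

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into every reachable node with `requires = TRUE`.
#' Parameter gradients are added to whatever is already stored, so two
#' successive calls (clean pass + perturbed pass) leave the summed gradient.
#'
#' @param loss an `ad_node` holding a 1x1 matrix.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad_node(loss), length(loss$value) == 1L)
  # collect reachable subgraph that requires gradients; `stamp` marks
  # visited nodes without hashing
  # consume an id so the stamp is unique even across back-to-back calls
  .ad_state$counter <- .ad_state$counter + 1L
  stamp <- .ad_state$counter
  stack <- list(loss)
  n_stack <- 1L
  nodes <- vector("list", 1024L)
  ids <- integer(1024L)
  n_nodes <- 0L
  loss$stamp <- stamp
  while (n_stack > 0L) {
    nd <- stack[[n_stack]]
    n_stack <- n_stack - 1L
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) {
      nodes <- c(nodes, vector("list", length(nodes)))
      ids <- c(ids, integer(length(ids)))
    }
    nodes[[n_nodes]] <- nd
    ids[[n_nodes]] <- nd$id
    for (p in nd$parents) {
      if (p$requires && !identical(p$stamp, stamp)) {
        p$stamp <- stamp
        n_stack <- n_stack + 1L
        stack[[n_stack]] <- p
      }
    }
  }
  ord <- order(ids[seq_len(n_nodes)], decreasing = TRUE)
  if (is.null(loss$grad)) loss$grad <- matrix(1, 1, 1) else loss$grad <- loss$grad + 1
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    pgrads <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$requires) next
      g <- pgrads[[k]]
      if (is.null(g)) next
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
    }
    if (!identical(nd, loss) && length(nd$parents) > 0L) nd$grad <- NULL  # free intermediate
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- operations ------------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new_node(a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

# elementwise add; b may be a 1-row matrix broadcast over rows of a (bias)
ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  if (length(bv) == 1L && length(av) > 1L) {
    val <- av + as.numeric(bv)
    ad_new_node(val, list(a, b), function(g) {
      list(g, matrix(sum(g), 1L, 1L))
    })
  } else if (nrow(bv) == 1L && nrow(av) > 1L) {
    val <- sweep(av, 2L, as.numeric(bv), "+")
    ad_new_node(val, list(a, b), function(g) {
      list(g, matrix(colSums(g), 1L))
    })
  } else {
    ad_new_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

ad_scale <- function(a, k) {
  a <- as_ad(a)
  ad_new_node(a$value * k, list(a), function(g) list(g * k))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new_node(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

# multiply matrix `a` by a 1x1 node `s` (trainable scalar weight)
ad_scalar_mul <- function(a, s) {
  a <- as_ad(a); s <- as_ad(s)
  sv <- as.numeric(s$value)
  ad_new_node(a$value * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * a$value), 1L, 1L))
  })
}

# inverted dropout: zero a fraction p of entries and rescale by 1/(1-p);
# identity when p = 0 (inference)
ad_dropout <- function(a, p) {
  if (p <= 0) return(as_ad(a))
  a <- as_ad(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ad_new_node(a$value * keep, list(a), function(g) list(g * keep))
}

# multiply by a fixed numeric mask / matrix (no gradient into the mask)
ad_mulconst <- function(a, m) {
  a <- as_ad(a)
  ad_new_node(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  s <- 1 / (1 + exp(-a$value))
  ad_new_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(a) {
  a <- as_ad(a)
  v <- a$value
  pos <- v > 0
  ad_new_node(v * pos, list(a), function(g) list(g * pos))
}

# row-wise softmax; `keep` is an optional logical column-mask (per matrix or
# vector recycled over rows): masked-out columns get zero probability.
ad_softmax_rows <- function(a, keep = NULL) {
  a <- as_ad(a)
  z <- a$value
  if (!is.null(keep)) {
    km <- if (is.matrix(keep)) keep else matrix(keep, nrow(z), ncol(z), byrow = TRUE)
    z <- ifelse(km, z, -Inf)
  }
  zmax <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  ez <- exp(z - zmax)
  s <- ez / rowSums(ez)
  ad_new_node(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list((g - dot) * s)
  })
}

# row-wise layer normalization with affine gain/bias (1 x d parameters):
# y = g * (x - mean(x)) / sqrt(var(x) + eps) + b, per row
ad_layernorm <- function(a, gain, bias, eps = 1e-5) {
  a <- as_ad(a); gain <- as_ad(gain); bias <- as_ad(bias)
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowSums(xc * xc) / d + eps)
  xhat <- xc / s
  gv <- as.numeric(gain$value)
  val <- sweep(xhat, 2L, gv, "*")
  val <- sweep(val, 2L, as.numeric(bias$value), "+")
  ad_new_node(val, list(a, gain, bias), function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / s, per row
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) / s
    list(dx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
}

ad_transpose <- function(a) {
  a <- as_ad(a)
  ad_new_node(t(a$value), list(a), function(g) list(t(g)))
}

# a %*% t(b) without materializing the transpose
ad_tcrossprod <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_new_node(tcrossprod(a$value, b$value), list(a, b), function(g) {
    list(g %*% b$value, crossprod(g, a$value))
  })
}

ad_cbind <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- ncol(a$value)
  ad_new_node(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# column selection
ad_cols <- function(a, cols) {
  a <- as_ad(a)
  nc <- ncol(a$value)
  ad_new_node(a$value[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

# row selection / embedding lookup; idx may repeat
ad_rows <- function(a, idx) {
  a <- as_ad(a)
  nr <- nrow(a$value)
  ad_new_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, idx)
    out <- matrix(0, nr, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# mean over a subset of rows -> 1 x d
ad_mean_rows <- function(a, rows) {
  a <- as_ad(a)
  k <- length(rows)
  nr <- nrow(a$value)
  ad_new_node(matrix(colMeans(a$value[rows, , drop = FALSE]), 1L), list(a), function(g) {
    out <- matrix(0, nr, length(g))
    out[rows, ] <- matrix(as.numeric(g) / k, k, length(g), byrow = TRUE)
    list(out)
  })
}

# group-wise row means: groups is a list of row-index vectors -> |groups| x d
ad_group_means <- function(a, groups) {
  a <- as_ad(a)
  av <- a$value
  nr <- nrow(av); d <- ncol(av)
  rows <- unlist(groups, use.names = FALSE)
  gid <- rep.int(seq_along(groups), lengths(groups))
  sizes <- lengths(groups)
  val <- rowsum(av[rows, , drop = FALSE], gid, reorder = TRUE) / sizes
  ad_new_node(val, list(a), function(g) {
    spread <- (g / sizes)[gid, , drop = FALSE]
    acc <- rowsum(spread, rows)
    out <- matrix(0, nr, d)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

# repeat a 1 x d row n times -> n x d
ad_repeat_row <- function(a, n) {
  a <- as_ad(a)
  d <- ncol(a$value)
  ad_new_node(matrix(a$value, n, d, byrow = TRUE), list(a), function(g) {
    list(matrix(colSums(g), 1L))
  })
}

# u (n x 1), v (m x 1) -> n x m matrix M[i,j] = u[i] + v[j]
ad_outer_sum <- function(u, v) {
  u <- as_ad(u); v <- as_ad(v)
  un <- as.numeric(u$value); vn <- as.numeric(v$value)
  ad_new_node(outer(un, vn, "+"), list(u, v), function(g) {
    list(matrix(rowSums(g), ncol = 1L), matrix(colSums(g), ncol = 1L))
  })
}

ad_sum <- function(a) {
  a <- as_ad(a)
  dims <- dim(a$value)
  ad_new_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    list(matrix(as.numeric(g), dims[1L], dims[2L]))
  })
}

# Numerically stable fused sigmoid + binary cross-entropy, averaged over the
# cells where include != 0. Backward: (sigmoid(z) - y) * include / N.
ad_sigmoid_bce <- function(z, y, include = NULL) {
  z <- as_ad(z)
  zv <- z$value
  if (is.null(include)) include <- matrix(1, nrow(zv), ncol(zv))
  n_incl <- sum(include)
  if (n_incl == 0) return(ad_const(matrix(0, 1L, 1L)))
  # softplus(z) - y*z, stable form
  loss_cells <- pmax(zv, 0) - zv * y + log1p(exp(-abs(zv)))
  val <- sum(loss_cells * include) / n_incl
  ad_new_node(matrix(val, 1L, 1L), list(z), function(g) {
    s <- 1 / (1 + exp(-zv))
    list(as.numeric(g) * (s - y) * include / n_incl)
  })
}

# Fused row-wise softmax + categorical cross-entropy. `target` is an n-vector
# of class indices (1-based), `rowmask` selects rows, `norm` is the divisor.
ad_softmax_ce_rows <- function(z, target, rowmask = NULL, norm = NULL) {
  z <- as_ad(z)
  zv <- z$value
  n <- nrow(zv)
  if (is.null(rowmask)) rowmask <- rep(1, n)
  if (is.null(norm)) norm <- sum(rowmask)
  if (norm == 0) return(ad_const(matrix(0, 1L, 1L)))
  zmax <- zv[cbind(seq_len(n), max.col(zv, ties.method = "first"))]
  lse <- zmax + log(rowSums(exp(zv - zmax)))
  picked <- zv[cbind(seq_len(n), target)]
  val <- sum((lse - picked) * rowmask) / norm
  ad_new_node(matrix(val, 1L, 1L), list(z), function(g) {
    p <- exp(zv - lse)   # row-wise softmax
    onehot <- matrix(0, n, ncol(zv))
    onehot[cbind(seq_len(n), target)] <- 1
    list(as.numeric(g) * (p - onehot) * rowmask / norm)
  })
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
             weight_decay = weight_decay, t = 0L,
             m = lapply(params, function(p) p$value * 0),
             v = lapply(params, function(p) p$value * 0))
  st
}

# adaptive-moment update with decoupled weight decay (AdamW-style)
adam_step <- function(opt, params) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  wd <- opt$weight_decay
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / corr1
    vhat <- opt$v[[i]] / corr2
    upd <- mhat / (sqrt(vhat) + opt$eps)
    if (wd > 0) upd <- upd + wd * p$value
    p$value <- p$value - opt$lr * upd
  }
  opt
}
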