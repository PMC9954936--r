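# Reverse-mode gradient tape.
#
# A tape records a DAG of matrix-valued nodes as a forward computation
# runs; tape_backward() then accumulates gradients from a scalar root to
# every leaf.  Only the operations the TREPH layer and the training
# harness need are implemented; each op stores a closure computing the
# gradients of its parents from its own gradient.  Gradient correctness
# is checked against central finite differences in the test suite.

#' Create an empty gradient tape
#'
#' @return tape object (an environment) to pass to the `tp_*` ops.
#' @export
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$nodes <- vector("list", 64L)
  tp
}

.tp_push <- function(tp, value, parents = integer(0), backfn = NULL) {
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- list(value = value, parents = parents, backfn = backfn)
  tp$n
}

#' Fetch the forward value of a tape node
#' @param tp tape; @param id node id.
#' @export
tp_value <- function(tp, id) {
  force(id)
  tp$nodes[[id]]$value
}

#' Register a leaf node (parameter or constant) on the tape
#' @param tp tape; @param value numeric matrix or vector.
#' @return node id.
#' @export
tp_leaf <- function(tp, value) .tp_push(tp, value)

#' Run backpropagation from a scalar root node
#'
#' @param tp tape.
#' @param root id of a scalar node.
#' @return list of gradients indexed by node id (`NULL` where the node
#'   does not influence the root).
#' @export
tape_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  grads[[root]] <- 1
  for (id in seq.int(root, 1L)) {
    g <- grads[[id]]
    node <- tp$nodes[[id]]
    if (is.null(g) || is.null(node$backfn)) next
    pg <- node$backfn(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

# ---- arithmetic ----------------------------------------------------------

#' @rdname tape_ops
#' @param tp tape; `a`, `b` node ids; remaining arguments are op-specific
#'   constants.
#' @description Matrix operations recorded on the tape: `tp_mm` (matrix
#'   product), `tp_add`, `tp_sub`, `tp_mul` (elementwise), `tp_add_bias`
#'   (add a row vector to every row), `tp_scale` (constant scalar),
#'   `tp_addc` (constant shift), `tp_recip` (elementwise reciprocal),
#'   `tp_abs`, `tp_sigmoid`, `tp_relu`, `tp_leaky_relu`, `tp_cbind`,
#'   `tp_cols` (column slice), `tp_gather` (linear-index gather to a
#'   column), `tp_rows` (row gather), `tp_scatter_rows` (row scatter-add),
#'   `tp_mean_rows_by` (grouped row means), `tp_scale_rows` (per-row
#'   scaling), `tp_segment_softmax`, `tp_batchnorm`, `tp_sum` and
#'   `tp_softmax_ce`.
#' @name tape_ops
NULL

#' @rdname tape_ops
#' @export
tp_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$nodes[[a]]$value; B <- tp$nodes[[b]]$value
  .tp_push(tp, A %*% B, c(a, b), function(g)
    list(g %*% t(B), t(A) %*% g))
}

#' @rdname tape_ops
#' @export
tp_add <- function(tp, a, b) {
  force(a); force(b)
  .tp_push(tp, tp$nodes[[a]]$value + tp$nodes[[b]]$value, c(a, b),
           function(g) list(g, g))
}

#' @rdname tape_ops
#' @export
tp_sub <- function(tp, a, b) {
  force(a); force(b)
  .tp_push(tp, tp$nodes[[a]]$value - tp$nodes[[b]]$value, c(a, b),
           function(g) list(g, -g))
}

#' @rdname tape_ops
#' @export
tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$nodes[[a]]$value; B <- tp$nodes[[b]]$value
  .tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

#' @rdname tape_ops
#' @export
tp_add_bias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$nodes[[a]]$value
  b <- tp$nodes[[bias]]$value
  .tp_push(tp, A + matrix(b, nrow(A), length(b), byrow = TRUE),
           c(a, bias), function(g) list(g, colSums(g)))
}

#' @rdname tape_ops
#' @export
tp_scale <- function(tp, a, s) {
  force(a)
  .tp_push(tp, tp$nodes[[a]]$value * s, a, function(g) list(g * s))
}

#' @rdname tape_ops
#' @export
tp_addc <- function(tp, a, s) {
  force(a)
  .tp_push(tp, tp$nodes[[a]]$value + s, a, function(g) list(g))
}

#' @rdname tape_ops
#' @export
tp_recip <- function(tp, a) {
  force(a)
  v <- 1 / tp$nodes[[a]]$value
  .tp_push(tp, v, a, function(g) list(-g * v * v))
}

#' @rdname tape_ops
#' @export
tp_abs <- function(tp, a) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, abs(A), a, function(g) list(g * sign(A)))
}

#' @rdname tape_ops
#' @export
tp_sigmoid <- function(tp, a) {
  force(a)
  v <- 1 / (1 + exp(-tp$nodes[[a]]$value))
  .tp_push(tp, v, a, function(g) list(g * v * (1 - v)))
}

#' @rdname tape_ops
#' @export
tp_relu <- function(tp, a) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

#' @rdname tape_ops
#' @export
tp_leaky_relu <- function(tp, a, slope = 0.2) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, ifelse(A > 0, A, slope * A), a,
           function(g) list(g * ifelse(A > 0, 1, slope)))
}

# ---- shape ops -----------------------------------------------------------

#' @rdname tape_ops
#' @export
tp_cbind <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$nodes[[a]]$value; B <- tp$nodes[[b]]$value
  ka <- ncol(A)
  .tp_push(tp, cbind(A, B), c(a, b), function(g)
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE]))
}

#' @rdname tape_ops
#' @export
tp_cols <- function(tp, a, j) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, A[, j, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, j] <- g
    list(out)
  })
}

#' @rdname tape_ops
#' @export
tp_gather <- function(tp, a, idx) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, matrix(A[idx], ncol = 1L), a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(as.numeric(g), idx)
    out[as.integer(rownames(acc))] <- acc
    list(out)
  })
}

#' @rdname tape_ops
#' @export
tp_rows <- function(tp, a, rows) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, A[rows, , drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    acc <- rowsum(g, rows)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

#' @rdname tape_ops
#' @export
tp_scatter_rows <- function(tp, a, rows, nrow_out) {
  force(a)
  A <- tp$nodes[[a]]$value
  out <- matrix(0, nrow_out, ncol(A))
  acc <- rowsum(A, rows)
  out[as.integer(rownames(acc)), ] <- acc
  .tp_push(tp, out, a, function(g) list(g[rows, , drop = FALSE]))
}

#' @rdname tape_ops
#' @export
tp_mean_rows_by <- function(tp, a, group, ngroups) {
  force(a)
  A <- tp$nodes[[a]]$value
  cnt <- tabulate(group, nbins = ngroups)
  out <- matrix(0, ngroups, ncol(A))
  acc <- rowsum(A, group)
  out[as.integer(rownames(acc)), ] <- acc
  out <- out / pmax(cnt, 1L)
  .tp_push(tp, out, a, function(g)
    list(g[group, , drop = FALSE] / cnt[group]))
}

#' @rdname tape_ops
#' @export
tp_scale_rows <- function(tp, a, s) {
  force(a); force(s)
  A <- tp$nodes[[a]]$value
  v <- as.numeric(tp$nodes[[s]]$value)
  .tp_push(tp, A * v, c(a, s), function(g)
    list(g * v, matrix(rowSums(g * A), ncol = 1L)))
}

#' @rdname tape_ops
#' @export
tp_spmm_const <- function(tp, A_const, b) {
  force(b)
  B <- tp$nodes[[b]]$value
  .tp_push(tp, as.matrix(A_const %*% B), b, function(g)
    list(as.matrix(Matrix::crossprod(A_const, g))))
}

# ---- normalization, softmax, losses --------------------------------------

#' @rdname tape_ops
#' @export
tp_segment_softmax <- function(tp, a, seg, nseg) {
  force(a)
  s <- as.numeric(tp$nodes[[a]]$value)
  mx <- tapply(s, seg, max)
  e <- exp(s - as.numeric(mx[as.character(seg)]))
  tot <- rowsum(e, seg)
  den <- as.numeric(tot[as.character(seg), 1L])
  al <- e / den
  .tp_push(tp, matrix(al, ncol = 1L), a, function(g) {
    g <- as.numeric(g)
    dot <- rowsum(al * g, seg)
    list(matrix(al * (g - as.numeric(dot[as.character(seg), 1L])),
                ncol = 1L))
  })
}

#' @rdname tape_ops
#' @export
tp_batchnorm <- function(tp, a, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  X <- tp$nodes[[a]]$value
  gm <- as.numeric(tp$nodes[[gamma]]$value)
  bt <- as.numeric(tp$nodes[[beta]]$value)
  N <- nrow(X)
  if (training && N > 1L) {
    mu <- colMeans(X)
    v <- colMeans(X * X) - mu * mu
    v <- pmax(v, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  sd_ <- sqrt(v + eps)
  xn <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
  out <- sweep(sweep(xn, 2L, gm, "*"), 2L, bt, "+")
  use_batch <- training && N > 1L
  .tp_push(tp, out, c(a, gamma, beta), function(g) {
    dgamma <- colSums(g * xn)
    dbeta <- colSums(g)
    dxn <- sweep(g, 2L, gm, "*")
    if (use_batch) {
      t1 <- sweep(dxn, 2L, colMeans(dxn))
      t2 <- sweep(xn, 2L, colMeans(dxn * xn), "*")
      dx <- sweep(t1 - t2, 2L, sd_, "/")
    } else {
      dx <- sweep(dxn, 2L, sd_, "/")
    }
    list(dx, dgamma, dbeta)
  })
}

#' @rdname tape_ops
#' @export
tp_sum <- function(tp, a) {
  force(a)
  A <- tp$nodes[[a]]$value
  .tp_push(tp, sum(A), a, function(g)
    list(matrix(g, nrow(as.matrix(A)), ncol(as.matrix(A)))))
}

#' @rdname tape_ops
#' @param labels integer class labels in `[0, n_classes)`.
#' @export
tp_softmax_ce <- function(tp, a, labels) {
  force(a)
  L <- tp$nodes[[a]]$value
  L <- L - apply(L, 1L, max)
  P <- exp(L) / rowSums(exp(L))
  n <- nrow(L)
  pick <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[pick], 1e-300)))
  .tp_push(tp, loss, a, function(g) {
    D <- P
    D[pick] <- D[pick] - 1
    list(as.numeric(g) * D / n)
  })
}

# batchnorm running-statistics holder
bn_state <- function(width) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(width)
  st$var <- rep(1, width)
  st
}
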