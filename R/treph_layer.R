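# The TREPH layer: learnable filtration (GIN-eps + MLP + sigmoid),
# extended persistence per filter function, rational-hat vectorization of
# diagram points, and aggregation of each point's vector to the nodes
# marking its birth and death, followed by batch norm, ReLU, residual and
# a fully connected output.
#
# The forward pass is built on the gradient tape (tape.R).  The pairing
# computed by the persistence engine is treated as locally constant during
# differentiation: gradients flow only through the filter values at the
# vertices where paired simplices enter, which is exactly the regime in
# which the layer is differentiable (injective filter functions).

PLANAR_CLASSES <- c("ord0", "ext0", "ext1", "rel1")
LINE_CLASSES <- c("inf0p", "inf0n", "inf1p", "inf1n")

#' TREPH layer configuration
#'
#' @param d input node-feature dimension.
#' @param df number of learned filter functions.
#' @param dv dimension of the vectorized representation of a diagram
#'   point.
#' @param d_out output dimension (defaults to `d` so layers stack).
#' @param hidden hidden width of the filtration MLPs.
#' @param aggregation `"concat"` keeps one accumulator per filtration and
#'   concatenates them (node output width `df * dv` before the FC);
#'   `"sum"` pools accumulators across filtrations (width `dv`).
#' @param residual `"concat"` feeds `[x | aggregated]` to the FC;
#'   `"add"` projects both and adds.
#' @return a `treph_config` list.
#' @export
treph_config <- function(d = 64L, df = 8L, dv = 32L, d_out = d,
                         hidden = 64L,
                         aggregation = c("concat", "sum"),
                         residual = c("concat", "add")) {
  cfg <- list(d = as.integer(d), df = as.integer(df), dv = as.integer(dv),
              d_out = as.integer(d_out), hidden = as.integer(hidden),
              aggregation = match.arg(aggregation),
              residual = match.arg(residual))
  stopifnot(cfg$d >= 1L, cfg$df >= 1L, cfg$dv >= 1L, cfg$d_out >= 1L)
  cfg$agg_width <- if (cfg$aggregation == "concat") cfg$df * cfg$dv else cfg$dv
  structure(cfg, class = "treph_config")
}

.glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize TREPH layer parameters
#'
#' Weights use Glorot-uniform initialization; the GIN epsilon starts at 0
#' (learnable); rational-hat centers start uniform in the unit square
#' (the sigmoid range of the filtration) with radii 0.5.
#'
#' @param cfg a [treph_config()].
#' @param seed integer seed.
#' @return named list of parameter arrays (class `treph_params`);
#'   entries whose name starts with `"."` are non-trainable state.
#' @export
treph_params <- function(cfg, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  d <- cfg$d; h <- cfg$hidden; dv <- cfg$dv
  p <- list(
    gin_eps = 0,
    gin_W1 = .glorot(d, h), gin_b1 = numeric(h),
    gin_W2 = .glorot(h, h), gin_b2 = numeric(h),
    head_W1 = .glorot(d + h, h), head_b1 = numeric(h),
    head_W2 = .glorot(h, cfg$df), head_b2 = numeric(cfg$df),
    bn_gamma = rep(1, cfg$agg_width), bn_beta = numeric(cfg$agg_width)
  )
  for (cl in PLANAR_CLASSES) {
    p[[paste0("hat_C_", cl)]] <- matrix(stats::runif(2 * dv), 2L, dv)
    p[[paste0("hat_r_", cl)]] <- matrix(0.5, 1L, dv)
  }
  for (cl in LINE_CLASSES) {
    p[[paste0("hat_C_", cl)]] <- matrix(stats::runif(dv, -1, 1), 1L, dv)
    p[[paste0("hat_r_", cl)]] <- matrix(0.5, 1L, dv)
  }
  if (cfg$residual == "concat") {
    p$fc_W <- .glorot(d + cfg$agg_width, cfg$d_out)
    p$fc_b <- numeric(cfg$d_out)
  } else {
    p$fc_W <- .glorot(cfg$agg_width, cfg$d_out)
    p$fc_Wres <- .glorot(d, cfg$d_out)
    p$fc_b <- numeric(cfg$d_out)
  }
  p$.bn_state <- bn_state(cfg$agg_width)
  structure(p, class = "treph_params")
}

#' Rational-hat coordinate function
#'
#' Evaluates `1 / (1 + ||p - c||_1) - 1 / (1 + | |r| - ||p - c||_1 |)` for
#' planar (or one-dimensional) diagram points `p`.  The function peaks at
#' `p = c` with value `1 - 1/(1 + |r|)` and vanishes identically when
#' `r = 0`.
#'
#' @param p numeric matrix of points (rows) or a single point vector.
#' @param c center, same dimension as a point.
#' @param r radius (any sign; only `|r|` matters).
#' @return numeric vector, one value per point.
#' @examples
#' rational_hat(c(0.3, 0.7), c(0.3, 0.7), 1)  # 1 - 1/2 = 0.5
#' @export
rational_hat <- function(p, c, r) {
  p <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  dist <- rowSums(abs(sweep(p, 2L, c)))
  1 / (1 + dist) - 1 / (1 + abs(abs(r) - dist))
}

#' Vectorize extended-persistence diagram points
#'
#' Applies each class's `dv` rational-hat coordinate functions to every
#' point of that class, for each filtration.  Coordinate-function
#' parameters are shared across filtrations.
#'
#' @param eph_results list from [eph()] (one element per filter).
#' @param params a [treph_params()] list (entries `hat_C_*`, `hat_r_*`).
#' @return list over filtrations; each element a list over classes of
#'   `n_points x dv` matrices.
#' @export
vectorize <- function(eph_results, params) {
  lapply(eph_results, function(r) {
    out <- list()
    for (cl in PLANAR_CLASSES) {
      pts <- r$diagrams[[cl]]
      C <- params[[paste0("hat_C_", cl)]]
      rr <- params[[paste0("hat_r_", cl)]]
      out[[cl]] <- if (nrow(pts)) {
        vapply(seq_len(ncol(C)), function(j)
          rational_hat(pts, C[, j], rr[1L, j]), numeric(nrow(pts)))
      } else matrix(numeric(0), 0L, ncol(C))
      if (nrow(pts) == 1L) out[[cl]] <- matrix(out[[cl]], nrow = 1L)
    }
    out
  })
}

#' Aggregate vectorized diagram points to graph nodes
#'
#' Each point's vector is added to the node where its birth simplex
#' enters the filtration and to the node where its death simplex enters
#' (a point whose two locations coincide contributes twice).  Per-filter
#' accumulators are concatenated (or summed, per the config) into a
#' `n_vertices x agg_width` matrix.  This is the raw accumulator, before
#' the layer's batch normalization and ReLU.
#'
#' @param g a [vf_graph()].
#' @param eph_results list from [eph()].
#' @param point_vectors output of [vectorize()].
#' @param cfg a [treph_config()].
#' @return numeric matrix `n_vertices x agg_width`.
#' @export
aggregate_points <- function(g, eph_results, point_vectors, cfg) {
  n <- g$n_vertices
  df <- length(eph_results)
  dv <- cfg$dv
  acc <- matrix(0, n, cfg$agg_width)
  for (k in seq_len(df)) {
    r <- eph_results[[k]]
    cols <- if (cfg$aggregation == "concat") (k - 1L) * dv + seq_len(dv)
            else seq_len(dv)
    for (cl in PLANAR_CLASSES) {
      sel <- which(r$pairing$class == cl)
      if (!length(sel)) next
      vec <- point_vectors[[k]][[cl]]
      bloc <- r$locate[r$pairing$birth_pos[sel]] + 1L
      dloc <- r$locate[r$pairing$death_pos[sel]] + 1L
      for (i in seq_along(sel)) {
        acc[bloc[i], cols] <- acc[bloc[i], cols] + vec[i, ]
        acc[dloc[i], cols] <- acc[dloc[i], cols] + vec[i, ]
      }
    }
  }
  acc
}

# ---- batched tape forward ------------------------------------------------

# stack a list of graphs into one disjoint union
.batch_graphs <- function(graphs) {
  nv <- vapply(graphs, function(g) g$n_vertices, 0L)
  offsets <- c(0L, cumsum(nv))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i)
    graphs[[i]]$edges + offsets[i]))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2L)
  list(n_total = sum(nv), offsets = offsets[-length(offsets)],
       nv = nv, edges = edges,
       graph_id = rep(seq_along(graphs), nv))
}

# block-diagonal (symmetric) adjacency of the batch
.batch_adjacency <- function(batch) {
  n <- batch$n_total
  e <- batch$edges
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(e[, 1L], e[, 2L]) + 1L,
                       j = c(e[, 2L], e[, 1L]) + 1L,
                       x = 1, dims = c(n, n))
}

# filtration module on the tape: GIN-eps convolution, skip concat,
# two-layer head, sigmoid
.tp_filtration <- function(tp, A, x_id, P, training) {
  eps_plus <- tp_addc(tp, P$gin_eps, 1)
  xe <- .tp_scale_by_scalar(tp, x_id, eps_plus)
  agg <- tp_spmm_const(tp, A, x_id)
  s <- tp_add(tp, xe, agg)
  h <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, s, P$gin_W1), P$gin_b1))
  h <- tp_add_bias(tp, tp_mm(tp, h, P$gin_W2), P$gin_b2)
  cat_ <- tp_cbind(tp, x_id, h)
  z <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, cat_, P$head_W1), P$head_b1))
  z <- tp_add_bias(tp, tp_mm(tp, z, P$head_W2), P$head_b2)
  tp_sigmoid(tp, z)
}

# multiply matrix node by scalar node (the learnable 1 + eps)
.tp_scale_by_scalar <- function(tp, a, s) {
  force(a); force(s)
  A <- tp$nodes[[a]]$value; sv <- as.numeric(tp$nodes[[s]]$value)
  .tp_push(tp, A * sv, c(a, s), function(g)
    list(g * sv, sum(g * A)))
}

# rational hat on the tape: P_id is np x k points, C (k x dv), r (1 x dv)
.tp_hat <- function(tp, P_id, C_id, r_id) {
  force(P_id); force(C_id); force(r_id)
  Pv <- tp$nodes[[P_id]]$value
  np <- nrow(Pv); k <- ncol(Pv)
  dv <- ncol(tp$nodes[[r_id]]$value)
  ones_col <- tp_leaf(tp, matrix(1, np, 1L))
  ones_row <- tp_leaf(tp, matrix(1, 1L, dv))
  D <- NULL
  for (j in seq_len(k)) {
    term <- tp_abs(tp, tp_sub(tp,
      tp_mm(tp, tp_cols(tp, P_id, j), ones_row),
      tp_mm(tp, ones_col, tp_rows(tp, C_id, j))))
    D <- if (is.null(D)) term else tp_add(tp, D, term)
  }
  rabs <- tp_mm(tp, ones_col, tp_abs(tp, r_id))
  tp_sub(tp,
         tp_recip(tp, tp_addc(tp, D, 1)),
         tp_recip(tp, tp_addc(tp, tp_abs(tp, tp_sub(tp, rabs, D)), 1)))
}

# Point tables for the batch: for every diagram point, linear indices of
# its birth/death coordinates in the filter matrix (column-major into
# N_total x df) and the scatter rows of its birth/death locations.
# stride = N_total for per-filter accumulators, 0 for summed ones.
.point_tables_full <- function(graphs, batch, fvals, stride) {
  N <- batch$n_total; df <- ncol(fvals)
  tab <- lapply(PLANAR_CLASSES, function(cl)
    list(b = list(), d = list(), tb = list(), td = list()))
  names(tab) <- PLANAR_CLASSES
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    off <- batch$offsets[i]
    rows <- off + seq_len(g$n_vertices)
    for (k in seq_len(df)) {
      gk <- g; gk$values <- fvals[rows, k]
      ord <- build_filtration_order(gk)
      pc <- .pair_core(build_extended_boundary_matrix(ord), ord)
      loc <- build_locating_map(ord)
      bloc <- off + loc[pc$birth] + 1L
      dloc <- off + loc[pc$death] + 1L
      cshift <- (k - 1L) * N
      for (cl in PLANAR_CLASSES) {
        sel <- pc$class == cl
        if (!any(sel)) next
        key <- length(tab[[cl]]$b) + 1L
        tab[[cl]]$b[[key]] <- bloc[sel] + cshift
        tab[[cl]]$d[[key]] <- dloc[sel] + cshift
        tab[[cl]]$tb[[key]] <- bloc[sel] + (k - 1L) * stride
        tab[[cl]]$td[[key]] <- dloc[sel] + (k - 1L) * stride
      }
    }
  }
  lapply(tab, function(t) list(b = unlist(t$b), d = unlist(t$d),
                               tb = unlist(t$tb), td = unlist(t$td)))
}

# ordinary-persistence point tables for the ablation variants.
# Entries: planar classes with both locations (noext finite points) or
# birth-only (trunc), and 1-D classes (noext infinite points).
.point_tables_ablation <- function(graphs, batch, fvals, stride, truncate) {
  N <- batch$n_total; df <- ncol(fvals)
  classes <- c(PLANAR_CLASSES, if (!truncate) LINE_CLASSES)
  tab <- lapply(classes, function(cl) list())
  names(tab) <- classes
  add <- function(cl, entry) {
    tab[[cl]][[length(tab[[cl]]) + 1L]] <<- entry
  }
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    off <- batch$offsets[i]
    rows <- off + seq_len(g$n_vertices)
    for (k in seq_len(df)) {
      f <- fvals[rows, k]
      cshift <- (k - 1L) * N
      tshift <- (k - 1L) * stride
      pp <- .ph_locations(g, f)
      pn <- .ph_locations(g, -f)
      # finite dim-0 of f == Ord0; of -f == Rel1 (raw f coordinates)
      if (truncate) {
        # PDs of f and -f in their own coordinates, infinite deaths
        # truncated to the filter maximum; birth location only
        amax <- pp$argmax; amin <- pn$argmax  # argmax of -f = argmin of f
        add("ord0", list(b = off + c(pp$fin_bv, pp$ess_v) + cshift,
                         d = off + c(pp$fin_dv, rep(amax, length(pp$ess_v))) +
                           cshift,
                         tb = off + c(pp$fin_bv, pp$ess_v) + tshift,
                         neg = FALSE))
        add("ext1", list(b = off + pp$cyc_v + cshift,
                         d = off + rep(amax, length(pp$cyc_v)) + cshift,
                         tb = off + pp$cyc_v + tshift, neg = FALSE))
        add("rel1", list(b = off + c(pn$fin_bv, pn$ess_v) + cshift,
                         d = off + c(pn$fin_dv, rep(amin, length(pn$ess_v))) +
                           cshift,
                         tb = off + c(pn$fin_bv, pn$ess_v) + tshift,
                         neg = TRUE))
        add("ext0", list(b = off + pn$cyc_v + cshift,
                         d = off + rep(amin, length(pn$cyc_v)) + cshift,
                         tb = off + pn$cyc_v + tshift, neg = TRUE))
      } else {
        add("ord0", list(b = off + pp$fin_bv + cshift,
                         d = off + pp$fin_dv + cshift,
                         tb = off + pp$fin_bv + tshift,
                         td = off + pp$fin_dv + tshift, neg = FALSE))
        # Rel1 representation of the finite dim-0 points of -f:
        # coordinates are raw f values at the same locations
        add("rel1", list(b = off + pn$fin_bv + cshift,
                         d = off + pn$fin_dv + cshift,
                         tb = off + pn$fin_bv + tshift,
                         td = off + pn$fin_dv + tshift, neg = FALSE))
        add("inf0p", list(b = off + pp$ess_v + cshift,
                          tb = off + pp$ess_v + tshift, neg = FALSE))
        add("inf0n", list(b = off + pn$ess_v + cshift,
                          tb = off + pn$ess_v + tshift, neg = TRUE))
        add("inf1p", list(b = off + pp$cyc_v + cshift,
                          tb = off + pp$cyc_v + tshift, neg = FALSE))
        add("inf1n", list(b = off + pn$cyc_v + cshift,
                          tb = off + pn$cyc_v + tshift, neg = TRUE))
      }
    }
  }
  tab
}

# union-find persistence of one filter with 1-based vertex locations:
# finite dim-0 pairs (birth vertex, death-edge location), essential
# minima, cycle-edge locations and the argmax vertex
.ph_locations <- function(g, f) {
  gk <- g; gk$values <- f
  ord <- build_filtration_order(gk)
  d0 <- .ph_dim0(gk, ord)
  loc <- build_locating_map(ord)
  list(fin_bv = d0$birth_vertex,
       fin_dv = if (length(d0$death_edge))
         loc[ord$pos_ae[d0$death_edge]] + 1L else integer(0),
       ess_v = d0$essential_vertex,
       cyc_v = if (length(d0$cycle_edges))
         loc[ord$pos_ae[d0$cycle_edges]] + 1L else integer(0),
       argmax = which.max(f))
}

# core tape forward over a batch of graphs; returns the output node id
.treph_tape_forward <- function(tp, graphs, x_id, P, params, cfg,
                                variant = c("full", "noext", "noext_trunc"),
                                training = FALSE, filtration = NULL) {
  variant <- match.arg(variant)
  batch <- .batch_graphs(graphs)
  N <- batch$n_total
  filt_id <- if (is.null(filtration)) {
    A <- .batch_adjacency(batch)
    .tp_filtration(tp, A, x_id, P, training)
  } else {
    stopifnot(nrow(filtration) == N, ncol(filtration) == cfg$df)
    tp_leaf(tp, as.matrix(filtration))
  }
  fvals <- tp$nodes[[filt_id]]$value
  stride <- if (cfg$aggregation == "concat") N else 0L
  acc_rows <- if (cfg$aggregation == "concat") N * cfg$df else N

  contrib <- list()
  if (variant == "full") {
    tabs <- .point_tables_full(graphs, batch, fvals, stride)
    for (cl in PLANAR_CLASSES) {
      t <- tabs[[cl]]
      if (is.null(t$b) || !length(t$b)) next
      Pt <- tp_cbind(tp, tp_gather(tp, filt_id, t$b),
                     tp_gather(tp, filt_id, t$d))
      S <- .tp_hat(tp, Pt, P[[paste0("hat_C_", cl)]],
                   P[[paste0("hat_r_", cl)]])
      np <- length(t$b)
      both <- tp_rows(tp, S, c(seq_len(np), seq_len(np)))
      contrib[[length(contrib) + 1L]] <-
        tp_scatter_rows(tp, both, c(t$tb, t$td), acc_rows)
    }
  } else {
    tabs <- .point_tables_ablation(graphs, batch, fvals, stride,
                                   truncate = (variant == "noext_trunc"))
    for (cl in names(tabs)) {
      entries <- tabs[[cl]]
      if (!length(entries)) next
      b <- unlist(lapply(entries, `[[`, "b"))
      if (!length(b)) next
      neg <- unlist(lapply(entries, function(e)
        rep(e$neg, length(e$b))))
      sgn <- ifelse(neg, -1, 1)
      tb <- unlist(lapply(entries, `[[`, "tb"))
      planar <- cl %in% PLANAR_CLASSES
      Pb <- tp_mul(tp, tp_gather(tp, filt_id, b),
                   tp_leaf(tp, matrix(sgn, ncol = 1L)))
      Pt <- if (planar) {
        d <- unlist(lapply(entries, `[[`, "d"))
        Pd <- tp_mul(tp, tp_gather(tp, filt_id, d),
                     tp_leaf(tp, matrix(sgn, ncol = 1L)))
        tp_cbind(tp, Pb, Pd)
      } else Pb
      S <- .tp_hat(tp, Pt, P[[paste0("hat_C_", cl)]],
                   P[[paste0("hat_r_", cl)]])
      if (variant == "noext" && planar) {
        td <- unlist(lapply(entries, `[[`, "td"))
        np <- length(b)
        both <- tp_rows(tp, S, c(seq_len(np), seq_len(np)))
        contrib[[length(contrib) + 1L]] <-
          tp_scatter_rows(tp, both, c(tb, td), acc_rows)
      } else {
        contrib[[length(contrib) + 1L]] <-
          tp_scatter_rows(tp, S, tb, acc_rows)
      }
    }
  }

  acc <- if (length(contrib)) {
    out <- contrib[[1L]]
    for (j in seq_along(contrib)[-1L]) out <- tp_add(tp, out, contrib[[j]])
    out
  } else tp_leaf(tp, matrix(0, acc_rows, cfg$dv))

  if (cfg$aggregation == "concat")
    acc <- .tp_blocks_to_wide(tp, acc, cfg$df, N)

  bn <- tp_batchnorm(tp, acc, P$bn_gamma, P$bn_beta, params$.bn_state,
                     training = training)
  agg_out <- tp_relu(tp, bn)

  if (cfg$residual == "concat") {
    tp_add_bias(tp, tp_mm(tp, tp_cbind(tp, x_id, agg_out), P$fc_W), P$fc_b)
  } else {
    tp_add(tp, tp_add_bias(tp, tp_mm(tp, agg_out, P$fc_W), P$fc_b),
           tp_mm(tp, x_id, P$fc_Wres))
  }
}

# (n*df) x dv stacked per-filter accumulators -> n x (df*dv)
.tp_blocks_to_wide <- function(tp, a, df, n) {
  force(a)
  A <- tp$nodes[[a]]$value
  wide <- do.call(cbind, lapply(seq_len(df), function(k)
    A[(k - 1L) * n + seq_len(n), , drop = FALSE]))
  dv <- ncol(A)
  .tp_push(tp, wide, a, function(g)
    list(do.call(rbind, lapply(seq_len(df), function(k)
      g[, (k - 1L) * dv + seq_len(dv), drop = FALSE]))))
}

# register all trainable params of a list on a tape
.tp_register_params <- function(tp, params) {
  ids <- list()
  for (nm in names(params)) {
    if (startsWith(nm, ".")) next
    ids[[nm]] <- tp_leaf(tp, params[[nm]])
  }
  ids
}

#' Filtration module forward pass
#'
#' GIN-epsilon convolution `h'_v = MLP((1 + eps) x_v + sum_u x_u)`,
#' concatenation `[x | h']`, a two-layer MLP head and a final sigmoid, so
#' every filter value lies in (0, 1).
#'
#' @param g a [vf_graph()].
#' @param x numeric `n_vertices x d` node-feature matrix.
#' @param params a [treph_params()].
#' @param cfg a [treph_config()].
#' @return `n_vertices x df` matrix of filter values in (0, 1).
#' @export
filtration_forward <- function(g, x, params, cfg) {
  stopifnot(nrow(x) == g$n_vertices, ncol(x) == cfg$d)
  tp <- tape_new()
  P <- .tp_register_params(tp, params)
  x_id <- tp_leaf(tp, as.matrix(x))
  batch <- .batch_graphs(list(g))
  A <- .batch_adjacency(batch)
  tp_value(tp, .tp_filtration(tp, A, x_id, P, training = FALSE))
}

#' TREPH layer forward pass
#'
#' The full differentiable layer: learned (or supplied) filter functions,
#' extended persistence per filter, rational-hat vectorization of every
#' diagram point, aggregation of each point's vector to its birth and
#' death nodes, batch normalization, ReLU, residual connection and a
#' fully connected output.
#'
#' @param g a [vf_graph()] or list of graphs (treated as a mini-batch /
#'   disjoint union; persistence is computed per graph).
#' @param x node-feature matrix (rows stacked over the batch).
#' @param params a [treph_params()].
#' @param cfg a [treph_config()].
#' @param filtration optional `n x df` matrix of fixed filter values to
#'   use instead of the learned filtration module.
#' @param training logical; use batch statistics (and update running
#'   statistics) in the batch norm.
#' @return `n x d_out` output node-feature matrix.
#' @export
treph_forward <- function(g, x, params, cfg, filtration = NULL,
                          training = FALSE) {
  .treph_numeric(g, x, params, cfg, "full", filtration, training)
}

#' @rdname treph_forward
#' @description `treph_forward_noext` replaces extended persistence with
#'   ordinary persistence of the filter and its negation; finite
#'   dimension-0 points are vectorized as planar points exactly as in the
#'   full layer, while each essential point `(a, Inf)` is vectorized as
#'   the one-dimensional point `a` and aggregated only to its birth node.
#' @export
treph_forward_noext <- function(g, x, params, cfg, filtration = NULL,
                                training = FALSE) {
  .treph_numeric(g, x, params, cfg, "noext", filtration, training)
}

#' @rdname treph_forward
#' @description `treph_forward_noext_trunc` truncates every essential
#'   point `(a, Inf)` of the ordinary diagrams of the filter (resp. its
#'   negation) to `(a, max f)` (resp. `(a, max(-f))`), vectorizes all
#'   points uniformly as planar points, and aggregates each vector only
#'   to its birth node.
#' @export
treph_forward_noext_trunc <- function(g, x, params, cfg, filtration = NULL,
                                      training = FALSE) {
  .treph_numeric(g, x, params, cfg, "noext_trunc", filtration, training)
}

.treph_numeric <- function(g, x, params, cfg, variant, filtration, training) {
  graphs <- if (inherits(g, "vf_graph")) list(g) else g
  stopifnot(ncol(x) == cfg$d)
  tp <- tape_new()
  P <- .tp_register_params(tp, params)
  x_id <- tp_leaf(tp, as.matrix(x))
  out <- .treph_tape_forward(tp, graphs, x_id, P, params, cfg,
                             variant = variant, training = training,
                             filtration = filtration)
  tp_value(tp, out)
}
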