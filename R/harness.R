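# Graph-classification harness: four-layer GNN backbones (GCN, GAT, GIN)
# with TREPH substituted at a chosen position, mean pooling, a two-layer
# MLP classifier, and the training schedule (Adam, plateau halving,
# ten-fold cross-validation).

# ---- parameter trees -----------------------------------------------------

.tree_map <- function(f, tree) {
  out <- lapply(names(tree), function(nm) {
    x <- tree[[nm]]
    if (startsWith(nm, ".")) x
    else if (is.list(x) && !is.null(names(x))) .tree_map(f, x)
    else f(x)
  })
  names(out) <- names(tree)
  out
}

.tree_register <- function(tp, tree) {
  out <- lapply(names(tree), function(nm) {
    x <- tree[[nm]]
    if (startsWith(nm, ".")) NULL
    else if (is.list(x) && !is.null(names(x))) .tree_register(tp, x)
    else tp_leaf(tp, x)
  })
  names(out) <- names(tree)
  out
}

.tree_grads <- function(grads, ids, tree) {
  out <- lapply(names(tree), function(nm) {
    x <- tree[[nm]]
    if (startsWith(nm, ".")) NULL
    else if (is.list(x) && !is.null(names(x)))
      .tree_grads(grads, ids[[nm]], x)
    else {
      g <- grads[[ids[[nm]]]]
      if (is.null(g)) array(0, dim = dim(as.matrix(x))) else g
    }
  })
  names(out) <- names(tree)
  out
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(tree) {
  list(m = .tree_map(function(x) x * 0, tree),
       v = .tree_map(function(x) x * 0, tree),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step1 <- function(p, g, m, v) {
    if (is.null(g)) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      if (startsWith(nm, ".")) next
      if (is.list(p[[nm]]) && !is.null(names(p[[nm]]))) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        r <- step1(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# ---- backbone layers -----------------------------------------------------

.gcn_norm_adjacency <- function(batch) {
  n <- batch$n_total
  A <- .batch_adjacency(batch) + Matrix::Diagonal(n)
  d <- Matrix::rowSums(A)
  Di <- Matrix::Diagonal(n, 1 / sqrt(d))
  Di %*% A %*% Di
}

.init_gcn <- function(d_in, d_out)
  list(W = .glorot(d_in, d_out), b = numeric(d_out))

.init_gin <- function(d_in, d_out)
  list(eps = 0,
       W1 = .glorot(d_in, d_out), b1 = numeric(d_out),
       W2 = .glorot(d_out, d_out), b2 = numeric(d_out))

.init_gat <- function(d_in, d_out)
  list(W = .glorot(d_in, d_out),
       a_src = .glorot(d_out, 1L), a_dst = .glorot(d_out, 1L),
       b = numeric(d_out))

.gcn_forward <- function(tp, batch, x_id, P) {
  Ah <- .gcn_norm_adjacency(batch)
  tp_relu(tp, tp_add_bias(tp, tp_mm(tp, tp_spmm_const(tp, Ah, x_id), P$W),
                          P$b))
}

.gin_forward <- function(tp, batch, x_id, P) {
  A <- .batch_adjacency(batch)
  eps_plus <- tp_addc(tp, P$eps, 1)
  s <- tp_add(tp, .tp_scale_by_scalar(tp, x_id, eps_plus),
              tp_spmm_const(tp, A, x_id))
  h <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, s, P$W1), P$b1))
  tp_relu(tp, tp_add_bias(tp, tp_mm(tp, h, P$W2), P$b2))
}

.gat_forward <- function(tp, batch, x_id, P) {
  n <- batch$n_total
  e <- batch$edges
  src <- c(e[, 1L], e[, 2L], seq_len(n) - 1L) + 1L
  dst <- c(e[, 2L], e[, 1L], seq_len(n) - 1L) + 1L
  HW <- tp_mm(tp, x_id, P$W)
  Hs <- tp_rows(tp, HW, src)
  Hd <- tp_rows(tp, HW, dst)
  s <- tp_leaky_relu(tp, tp_add(tp, tp_mm(tp, Hs, P$a_src),
                                tp_mm(tp, Hd, P$a_dst)))
  al <- tp_segment_softmax(tp, s, dst, n)
  msg <- tp_scale_rows(tp, Hs, al)
  out <- tp_scatter_rows(tp, msg, dst, n)
  tp_relu(tp, tp_add_bias(tp, out, P$b))
}

# ---- architecture --------------------------------------------------------

#' Architecture specification for the classification harness
#'
#' A stack of `n_layers` message-passing layers of one backbone type,
#' optionally with the TREPH layer substituted at one position, followed
#' by mean pooling and a two-layer MLP classifier (hidden width 32).
#'
#' @param backbone `"gcn"`, `"gat"` or `"gin"`.
#' @param n_layers number of node-transform layers (default 4).
#' @param treph_position optional position in `1..n_layers` whose
#'   backbone layer is replaced by TREPH; `NULL` for a pure baseline.
#' @param hidden hidden node-feature width.
#' @param clf_hidden classifier hidden width.
#' @return an `arch_spec` list.
#' @export
arch_spec <- function(backbone = c("gin", "gcn", "gat"), n_layers = 4L,
                      treph_position = NULL, hidden = 64L,
                      clf_hidden = 32L) {
  backbone <- match.arg(backbone)
  n_layers <- as.integer(n_layers)
  if (!is.null(treph_position)) {
    treph_position <- as.integer(treph_position)
    stopifnot(treph_position >= 1L, treph_position <= n_layers)
  }
  structure(list(backbone = backbone, n_layers = n_layers,
                 treph_position = treph_position,
                 hidden = as.integer(hidden),
                 clf_hidden = as.integer(clf_hidden)),
            class = "arch_spec")
}

#' Build a graph classifier
#'
#' @param spec an [arch_spec()].
#' @param cfg a [treph_config()] used for the TREPH layer (its `d` and
#'   `d_out` are overridden by the position's widths); ignored for pure
#'   baselines.
#' @param n_classes number of output classes.
#' @param d_in input node-feature dimension.
#' @param seed integer seed for parameter initialization.
#' @param variant TREPH variant to use at the substituted position:
#'   `"full"`, `"noext"` or `"noext_trunc"`.
#' @return a `graph_classifier` object holding the layer stack and all
#'   parameters.  The number of parameters depends only on the widths,
#'   never on graph sizes.
#' @export
build_model <- function(spec, cfg = treph_config(d = spec$hidden),
                        n_classes, d_in, seed = 1L,
                        variant = c("full", "noext", "noext_trunc")) {
  variant <- match.arg(variant)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  layers <- vector("list", spec$n_layers)
  d_cur <- as.integer(d_in)
  for (i in seq_len(spec$n_layers)) {
    if (!is.null(spec$treph_position) && i == spec$treph_position) {
      lcfg <- treph_config(d = d_cur, df = cfg$df, dv = cfg$dv,
                           d_out = spec$hidden, hidden = cfg$hidden,
                           aggregation = cfg$aggregation,
                           residual = cfg$residual)
      layers[[i]] <- list(type = "treph", cfg = lcfg, variant = variant,
                          params = treph_params(lcfg,
                                                seed = sample.int(1e6, 1L)))
    } else {
      init <- switch(spec$backbone,
                     gcn = .init_gcn(d_cur, spec$hidden),
                     gin = .init_gin(d_cur, spec$hidden),
                     gat = .init_gat(d_cur, spec$hidden))
      layers[[i]] <- list(type = spec$backbone, params = init)
    }
    d_cur <- spec$hidden
  }
  clf <- list(W1 = .glorot(spec$hidden, spec$clf_hidden),
              b1 = numeric(spec$clf_hidden),
              W2 = .glorot(spec$clf_hidden, n_classes),
              b2 = numeric(n_classes))
  params <- c(stats::setNames(lapply(layers, `[[`, "params"),
                              paste0("layer", seq_along(layers))),
              list(clf = clf))
  structure(list(spec = spec, layers = layers, params = params,
                 n_classes = as.integer(n_classes), d_in = as.integer(d_in)),
            class = "graph_classifier")
}

#' @export
print.graph_classifier <- function(x, ...) {
  pos <- x$spec$treph_position
  cat(sprintf("graph_classifier: %d-layer %s%s, %d classes, %d parameters\n",
              x$spec$n_layers, toupper(x$spec$backbone),
              if (is.null(pos)) "" else sprintf(" with TREPH at layer %d", pos),
              x$n_classes, n_parameters(x)))
  invisible(x)
}

#' Count trainable parameters of a classifier
#' @param model a [build_model()] result.
#' @export
n_parameters <- function(model) {
  tot <- 0L
  walk <- function(tree) {
    for (nm in names(tree)) {
      if (startsWith(nm, ".")) next
      x <- tree[[nm]]
      if (is.list(x) && !is.null(names(x))) walk(x)
      else tot <<- tot + length(x)
    }
  }
  walk(model$params)
  tot
}

# forward over a batch; returns list(loss_id, logits_id, ids) on the tape
.model_tape_forward <- function(tp, model, graphs, feats, labels = NULL,
                                training = FALSE) {
  batch <- .batch_graphs(graphs)
  ids <- .tree_register(tp, model$params)
  x_id <- tp_leaf(tp, do.call(rbind, feats))
  for (i in seq_along(model$layers)) {
    L <- model$layers[[i]]
    P <- ids[[paste0("layer", i)]]
    x_id <- switch(L$type,
      gcn = .gcn_forward(tp, batch, x_id, P),
      gin = .gin_forward(tp, batch, x_id, P),
      gat = .gat_forward(tp, batch, x_id, P),
      treph = .treph_tape_forward(tp, graphs, x_id, P,
                                  model$params[[paste0("layer", i)]],
                                  L$cfg, variant = L$variant,
                                  training = training))
  }
  pooled <- tp_mean_rows_by(tp, x_id, batch$graph_id, length(graphs))
  z <- tp_relu(tp, tp_add_bias(tp, tp_mm(tp, pooled, ids$clf$W1),
                               ids$clf$b1))
  logits <- tp_add_bias(tp, tp_mm(tp, z, ids$clf$W2), ids$clf$b2)
  loss <- if (is.null(labels)) NULL else tp_softmax_ce(tp, logits, labels)
  list(loss = loss, logits = logits, ids = ids, nodes = x_id)
}

#' Forward pass of a classifier
#'
#' @param model a [build_model()] result.
#' @param graphs list of [vf_graph()].
#' @param feats list of node-feature matrices.
#' @param training logical (batch-norm mode).
#' @return list with `logits` (`n_graphs x n_classes`), `pred`
#'   (0-based class labels) and `node_repr` (stacked node features after
#'   the last layer).
#' @export
model_forward <- function(model, graphs, feats, training = FALSE) {
  tp <- tape_new()
  fw <- .model_tape_forward(tp, model, graphs, feats, training = training)
  logits <- tp_value(tp, fw$logits)
  list(logits = logits, pred = max.col(logits) - 1L,
       node_repr = tp_value(tp, fw$nodes))
}

# ---- training ------------------------------------------------------------

#' Training configuration
#'
#' Adam with initial learning rate 1e-3; the rate is halved when the
#' validation accuracy has not improved for `patience` epochs, and
#' training stops when it falls below `lr_min` or after `max_epochs`
#' epochs.  Cross-entropy loss; 10% of the training set is held out for
#' validation.
#'
#' @param lr initial learning rate.
#' @param patience plateau patience in epochs.
#' @param max_epochs epoch cap.
#' @param lr_min stopping threshold for the learning rate.
#' @param batch_size graphs per mini-batch (the batch is processed as a
#'   disjoint union; persistence stays per-graph).
#' @param val_frac fraction of the training set reserved for validation.
#' @param seed integer seed for shuffling and splits.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, patience = 10L, max_epochs = 200L,
                         lr_min = 1e-5, batch_size = 32L, val_frac = 0.1,
                         seed = 1L, verbose = FALSE) {
  structure(list(lr = lr, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), lr_min = lr_min,
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

.accuracy <- function(model, ds, idx) {
  if (!length(idx)) return(NA_real_)
  preds <- integer(0)
  for (chunk in split(idx, ceiling(seq_along(idx) / 64))) {
    fw <- model_forward(model, ds$graphs[chunk], ds$features[chunk],
                        training = FALSE)
    preds <- c(preds, fw$pred)
  }
  mean(preds == ds$labels[idx])
}

#' Fit a classifier on (a subset of) a dataset
#'
#' Runs the plateau-halving Adam schedule of [train_config()].  When
#' `stop_at_train_acc` is set, training also stops as soon as the running
#' training accuracy of an epoch reaches that value.
#'
#' @param model a [build_model()] result.
#' @param ds a [graph_dataset()].
#' @param tc a [train_config()].
#' @param train_idx,val_idx 1-based graph indices; by default a
#'   `val_frac` split of the whole dataset.
#' @param stop_at_train_acc optional early-stop threshold on training
#'   accuracy.
#' @return list with `model` (trained), `history` (per-epoch data frame
#'   with loss, training/validation accuracy and learning rate) and
#'   `n_lr_halvings`.
#' @export
fit_model <- function(model, ds, tc = train_config(), train_idx = NULL,
                      val_idx = NULL, stop_at_train_acc = NULL) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(tc$seed)
  n <- length(ds$graphs)
  if (is.null(train_idx)) {
    sh <- sample.int(n)
    nval <- max(1L, round(tc$val_frac * n))
    val_idx <- sh[seq_len(nval)]
    train_idx <- sh[-seq_len(nval)]
  } else if (is.null(val_idx)) {
    sh <- sample(train_idx)
    nval <- max(1L, round(tc$val_frac * length(train_idx)))
    val_idx <- sh[seq_len(nval)]
    train_idx <- sh[-seq_len(nval)]
  }
  state <- .adam_init(model$params)
  lr <- tc$lr
  best_val <- -Inf
  stall <- 0L
  halvings <- 0L
  hist <- list()
  for (epoch in seq_len(tc$max_epochs)) {
    perm <- sample(train_idx)
    batches <- split(perm, ceiling(seq_along(perm) / tc$batch_size))
    tot_loss <- 0
    correct <- 0L
    for (b in batches) {
      tp <- tape_new()
      fw <- .model_tape_forward(tp, model, ds$graphs[b], ds$features[b],
                                labels = ds$labels[b], training = TRUE)
      loss <- tp_value(tp, fw$loss)
      grads <- tape_backward(tp, fw$loss)
      gtree <- .tree_grads(grads, fw$ids, model$params)
      upd <- .adam_step(model$params, gtree, state, lr)
      model$params <- upd$params
      state <- upd$state
      for (i in seq_along(model$layers))
        model$layers[[i]]$params <- model$params[[paste0("layer", i)]]
      tot_loss <- tot_loss + loss * length(b)
      correct <- correct +
        sum(max.col(tp_value(tp, fw$logits)) - 1L == ds$labels[b])
    }
    train_acc <- correct / length(train_idx)
    val_acc <- .accuracy(model, ds, val_idx)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                loss = tot_loss / length(train_idx),
                                train_acc = train_acc, val_acc = val_acc,
                                lr = lr)
    if (tc$verbose)
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f  lr %.2g",
                      epoch, tot_loss / length(train_idx), train_acc,
                      val_acc, lr))
    if (!is.null(stop_at_train_acc) && train_acc >= stop_at_train_acc) break
    if (!is.na(val_acc) && val_acc > best_val + 1e-12) {
      best_val <- val_acc
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience) {
        lr <- lr / 2
        halvings <- halvings + 1L
        stall <- 0L
        if (tc$verbose) message(sprintf("  lr halved to %.2g", lr))
        if (lr < tc$lr_min) break
      }
    }
  }
  list(model = model, history = do.call(rbind, hist),
       n_lr_halvings = halvings)
}

#' Ten-fold cross-validated training and evaluation
#'
#' Partitions the dataset into `n_folds` test folds; for each fold a
#' fresh model is built, trained on the remaining graphs (with 10% of
#' them as validation for the plateau schedule) and evaluated on the
#' held-out fold.
#'
#' @param spec an [arch_spec()].
#' @param ds a [graph_dataset()].
#' @param tc a [train_config()].
#' @param cfg a [treph_config()] template for TREPH positions.
#' @param n_folds number of folds (default 10).
#' @param variant TREPH variant.
#' @return list with `fold_accuracy`, `mean`, `sd` and the fold
#'   assignment.
#' @export
train_eval <- function(spec, ds, tc = train_config(),
                       cfg = treph_config(d = spec$hidden), n_folds = 10L,
                       variant = "full") {
  n <- length(ds$graphs)
  stopifnot(n >= n_folds, ds$n_classes >= 2L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(tc$seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  accs <- numeric(n_folds)
  for (kf in seq_len(n_folds)) {
    test_idx <- which(fold == kf)
    train_pool <- which(fold != kf)
    if (!length(test_idx) || !length(train_pool)) stop("empty fold")
    model <- build_model(spec, cfg, ds$n_classes,
                         d_in = ncol(ds$features[[1L]]),
                         seed = tc$seed + kf, variant = variant)
    fit <- fit_model(model, ds, tc, train_idx = train_pool)
    accs[kf] <- .accuracy(fit$model, ds, test_idx)
  }
  list(fold_accuracy = accs, mean = mean(accs), sd = stats::sd(accs),
       fold = fold)
}
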