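# Verification that the layer is differentiable end-to-end: reverse-mode
# gradients are compared against central finite differences of a scalar
# loss at (generically injective) learned filter values.

#' Gradient check of the TREPH layer
#'
#' For each of `n_graphs` random graphs, takes a random linear functional
#' of the layer output as scalar loss, computes all parameter gradients
#' with the reverse-mode tape, and compares a sample of coordinates per
#' parameter against central finite differences.  At injective filter
#' values the pairing is locally constant, so the two must agree; with
#' deliberately tied filter values the finite-difference quotient may
#' straddle a pairing switch and disagree (the gradient is then
#' one-sided but still finite), which `tie_demo = TRUE` demonstrates.
#'
#' @param n_graphs number of random graphs to test.
#' @param seed integer seed.
#' @param variant `"full"`, `"noext"` or `"noext_trunc"`.
#' @param cfg layer configuration (small defaults keep the finite
#'   differencing cheap).
#' @param h central-difference step.
#' @param n_coords coordinates sampled per parameter tensor.
#' @param tie_demo evaluate at a constant (non-injective) filtration
#'   instead of the learned one.
#' @return list with `max_rel_error`, per-graph errors `per_graph`, and
#'   `tol`-free details data frame.
#' @export
treph_gradcheck <- function(n_graphs = 10L, seed = 0L,
                            variant = c("full", "noext", "noext_trunc"),
                            cfg = treph_config(d = 3L, df = 2L, dv = 3L,
                                               d_out = 4L, hidden = 5L),
                            h = 1e-6, n_coords = 4L, tie_demo = FALSE) {
  variant <- match.arg(variant)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  per_graph <- numeric(n_graphs)
  rows <- list()
  for (gi in seq_len(n_graphs)) {
    n <- sample(5:9, 1L)
    m <- sample(seq(n - 1L, min(n + 4L, n * (n - 1L) / 2)), 1L)
    g <- random_vf_graph(n, m, seed = sample.int(1e6, 1L))
    x <- matrix(stats::rnorm(n * cfg$d), n, cfg$d)
    pars <- treph_params(cfg, seed = sample.int(1e6, 1L))
    W <- matrix(stats::rnorm(n * cfg$d_out), n, cfg$d_out)
    filt <- if (tie_demo) matrix(0.5, n, cfg$df) else NULL
    lossfun <- function(p) {
      out <- .treph_numeric(g, x, p, cfg, variant, filt, training = FALSE)
      sum(out * W)
    }
    tp <- tape_new()
    P <- .tp_register_params(tp, pars)
    x_id <- tp_leaf(tp, x)
    out <- .treph_tape_forward(tp, list(g), x_id, P, pars, cfg,
                               variant = variant, filtration = filt)
    loss <- tp_sum(tp, tp_mul(tp, out, tp_leaf(tp, W)))
    grads <- tape_backward(tp, loss)
    worst <- 0
    for (nm in names(pars)) {
      if (startsWith(nm, ".")) next
      gt <- grads[[P[[nm]]]]
      if (is.null(gt)) gt <- pars[[nm]] * 0
      for (ii in sample(length(pars[[nm]]),
                        min(n_coords, length(pars[[nm]])))) {
        pp <- pars; pp[[nm]][ii] <- pp[[nm]][ii] + h
        pm <- pars; pm[[nm]][ii] <- pm[[nm]][ii] - h
        fd <- (lossfun(pp) - lossfun(pm)) / (2 * h)
        e <- abs(fd - gt[ii]) / max(1, abs(fd), abs(gt[ii]))
        worst <- max(worst, e)
        rows[[length(rows) + 1L]] <-
          data.frame(graph = gi, param = nm, coord = ii,
                     autodiff = gt[ii], finite_diff = fd, rel_error = e)
      }
    }
    per_graph[gi] <- worst
  }
  list(max_rel_error = max(per_graph), per_graph = per_graph,
       details = do.call(rbind, rows))
}
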