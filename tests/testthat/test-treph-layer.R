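small_cfg <- function(...) treph_config(d = 3, df = 2, dv = 4, d_out = 5,
                                        hidden = 6, ...)

test_that("rational hat matches its closed forms", {
  expect_equal(rational_hat(c(0.2, 0.9), c(0.2, 0.9), 1), 0.5)
  expect_equal(rational_hat(c(0.7, 0.1), c(0.2, 0.9), 0), 0)
  expect_equal(rational_hat(matrix(rnorm(20), 10, 2),
                            c(0, 0), 0), rep(0, 10))
  expect_equal(rational_hat(c(2, 0), c(0, 0), 2), 1 / 3 - 1, tolerance = 1e-12)
  expect_equal(rational_hat(c(0, 2), c(0, 0), -2), 1 / 3 - 1)  # |r| is used
})

test_that("configuration and parameters respect the contracts", {
  cfg <- small_cfg()
  p <- treph_params(cfg, seed = 1)
  # 4 planar diagram classes with dv coordinate functions each
  planar <- grep("^hat_C_(ord0|ext0|ext1|rel1)$", names(p), value = TRUE)
  expect_length(planar, 4L)
  for (nm in planar) expect_equal(dim(p[[nm]]), c(2L, cfg$dv))
  expect_equal(cfg$agg_width, cfg$df * cfg$dv)
  expect_equal(treph_config(d = 2, df = 3, dv = 5,
                            aggregation = "sum")$agg_width, 5L)
  expect_error(treph_config(d = 0), "not TRUE")
})

test_that("vectorization applies each class's own coordinate functions", {
  g <- random_vf_graph(8, 11, seed = 4)
  res <- eph(g, matrix(runif(16), 8, 2))
  cfg <- small_cfg()
  p <- treph_params(cfg, seed = 2)
  pv <- vectorize(res, p)
  expect_length(pv, 2L)
  for (k in 1:2) {
    for (cl in c("ord0", "ext0", "ext1", "rel1")) {
      pts <- res[[k]]$diagrams[[cl]]
      expect_equal(dim(pv[[k]][[cl]]), c(nrow(pts), cfg$dv))
      if (nrow(pts)) {
        C <- p[[paste0("hat_C_", cl)]]
        rr <- p[[paste0("hat_r_", cl)]]
        manual <- sapply(seq_len(cfg$dv), function(j)
          rational_hat(pts, C[, j], rr[1, j]))
        if (nrow(pts) == 1) manual <- matrix(manual, 1)
        expect_equal(pv[[k]][[cl]], manual)
      }
    }
  }
  # a duplicated point gets an identical vector
  twin <- vf_graph(2, values = c(0.3, 0.3))
  res2 <- eph(twin, matrix(0.3, 2, 1))
  pv2 <- vectorize(res2, p)
  expect_equal(pv2[[1]]$ext0[1, ], pv2[[1]]$ext0[2, ])
})

test_that("aggregation scatters each point to birth and death locations", {
  g <- t135()
  cfg <- treph_config(d = 2, df = 1, dv = 3, hidden = 4)
  p <- treph_params(cfg, seed = 3)
  res <- eph(g)
  pv <- vectorize(res, p)
  acc <- aggregate_points(g, res, pv, cfg)
  expect_equal(dim(acc), c(3L, 3L))
  # every point lands exactly twice: row sums add to 2 * sum of vectors
  total <- Reduce(`+`, lapply(pv[[1]], function(m)
    if (nrow(m)) colSums(m) else numeric(cfg$dv)))
  expect_equal(colSums(acc), 2 * total)
  # the Ext1 vector lands at the max vertex (birth) and min vertex (death)
  ext1_vec <- pv[[1]]$ext1[1, ]
  ord0_3 <- pv[[1]]$ord0[1, ]  # point (3,3) lives entirely at vertex 1
  rel1_33 <- pv[[1]]$rel1[1, ]
  expect_equal(acc[2, ], 2 * ord0_3 + 2 * rel1_33)
  # isolated vertices receive their own Ext0 vector twice (diagram rows
  # follow pairing order, so match points to vertices by birth value)
  iso <- vf_graph(2, values = c(0.2, 0.9))
  res_i <- eph(iso)
  pv_i <- vectorize(res_i, p)
  acc_i <- aggregate_points(iso, res_i, pv_i, cfg)
  births <- res_i[[1]]$pairing$birth_value[res_i[[1]]$pairing$class == "ext0"]
  expect_equal(acc_i[1, ], 2 * pv_i[[1]]$ext0[which(births == 0.2), ])
  expect_equal(acc_i[2, ], 2 * pv_i[[1]]$ext0[which(births == 0.9), ])
})

test_that("filtration outputs lie in (0,1) and respect symmetry", {
  cfg <- small_cfg()
  p <- treph_params(cfg, seed = 5)
  g <- random_vf_graph(10, 15, seed = 6)
  x <- matrix(rnorm(30), 10, 3)
  f <- filtration_forward(g, x, p, cfg)
  expect_equal(dim(f), c(10L, cfg$df))
  expect_true(all(f > 0 & f < 1))
  # identical features + equal degree => equal filter values (path ends)
  path <- vf_graph(3, rbind(c(0, 1), c(1, 2)))
  ones <- matrix(1, 3, 3)
  fp <- filtration_forward(path, ones, p, cfg)
  expect_equal(fp[1, ], fp[3, ])
  # isolated vertex: neighbor sum is zero, value depends on x_v alone
  iso <- vf_graph(2)
  fi <- filtration_forward(iso, ones[1:2, ], p, cfg)
  expect_equal(fi[1, ], fi[2, ])
})

test_that("the layer forward has the contracted shape and equivariance", {
  cfg <- small_cfg()
  p <- treph_params(cfg, seed = 7)
  g <- random_vf_graph(9, 14, seed = 8)
  x <- matrix(rnorm(27), 9, 3)
  out <- treph_forward(g, x, p, cfg)
  expect_equal(dim(out), c(9L, cfg$d_out))
  # vertex relabeling permutes output rows identically
  set.seed(9)
  perm <- sample(9L)  # perm[old + 1] = new + 1
  g2 <- vf_graph(9, cbind(perm[g$edges[, 1] + 1] - 1L,
                          perm[g$edges[, 2] + 1] - 1L),
                 values = NULL)
  # keep the stored edge order comparable: relabeling may flip u<v, which
  # changes edge tie-breaking only at equal entry values (absent here)
  x2 <- x; x2[perm, ] <- x
  out2 <- treph_forward(g2, x2, p, cfg)
  expect_equal(out2[perm, ], out, tolerance = 1e-10)
})

test_that("zero radii disable the topological signal entirely", {
  cfg <- small_cfg()
  p <- treph_params(cfg, seed = 10)
  for (nm in grep("^hat_r_", names(p), value = TRUE)) p[[nm]][] <- 0
  g <- random_vf_graph(7, 10, seed = 11)
  x <- matrix(rnorm(21), 7, 3)
  out <- treph_forward(g, x, p, cfg)
  # aggregated block is all zeros pre-normalization; in eval mode the
  # batch norm maps 0 to 0 (fresh running stats), so the layer reduces to
  # the FC of the residual input
  ref <- cbind(x, matrix(0, 7, cfg$agg_width)) %*% p$fc_W +
    matrix(p$fc_b, 7, cfg$d_out, byrow = TRUE)
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("ablation variants vectorize the ordinary diagrams of both signs", {
  g <- t135()
  filt <- matrix(g$values / 10, 3, 1)  # values .1, .3, .5
  batch <- treph:::.batch_graphs(list(g))
  tabs <- treph:::.point_tables_ablation(list(g), batch, filt, 3L,
                                         truncate = FALSE)
  f <- filt[, 1]
  # essential points: dim0 of f at min (0.1); dim0 of -f at -max (-0.5);
  # dim1 of f at cycle max (0.5); dim1 of -f at -cycle min (-0.1)
  val_of <- function(cl) {
    e <- tabs[[cl]][[1]]
    sgn <- if (e$neg) -1 else 1
    sgn * f[e$b]
  }
  expect_equal(val_of("inf0p"), 0.1)
  expect_equal(val_of("inf0n"), -0.5)
  expect_equal(val_of("inf1p"), 0.5)
  expect_equal(val_of("inf1n"), -0.1)
  # truncation replaces (a, Inf) with (a, max f)
  tt <- treph:::.point_tables_ablation(list(g), batch, filt, 3L,
                                       truncate = TRUE)
  e0 <- tt$ord0[[1]]
  ess <- length(e0$b)  # last entry is the essential point
  expect_equal(f[e0$b[ess]], 0.1)
  expect_equal(f[e0$d[ess]], 0.5)
  # a forest contributes no dimension-1 points in either direction
  tree <- vf_graph(4, rbind(c(0, 1), c(1, 2), c(2, 3)))
  tb <- treph:::.point_tables_ablation(list(tree),
                                       treph:::.batch_graphs(list(tree)),
                                       matrix(c(.1, .4, .2, .8), 4, 1), 4L,
                                       truncate = FALSE)
  expect_length(tb$inf1p[[1]]$b, 0L)
  expect_length(tb$inf1n[[1]]$b, 0L)
})

test_that("autodiff matches finite differences through all variants", {
  for (v in c("full", "noext", "noext_trunc")) {
    gc_ <- treph_gradcheck(n_graphs = 3L, seed = 21L, variant = v)
    expect_lt(gc_$max_rel_error, 1e-6)
  }
})

test_that("tied filter values do not crash the layer or gradcheck", {
  gc_ <- treph_gradcheck(n_graphs = 1L, seed = 5L, tie_demo = TRUE)
  expect_true(is.finite(gc_$max_rel_error))
})
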