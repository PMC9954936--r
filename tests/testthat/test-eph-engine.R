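test_that("sublevel subgraphs restrict vertices and edges correctly", {
  g <- t135()
  s1 <- sublevel_subgraph(g, 2)
  expect_equal(s1$n_vertices, 1L)
  expect_equal(nrow(s1$edges), 0L)
  s2 <- sublevel_subgraph(g, 5)
  expect_equal(s2$n_vertices, 3L)
  expect_equal(nrow(s2$edges), 3L)
  s3 <- sublevel_subgraph(g, 3)
  expect_equal(s3$n_vertices, 2L)
  expect_equal(nrow(s3$edges), 1L)
})

test_that("filtration order scans bottom-up then top-down with tie rules", {
  ord <- build_filtration_order(t135())
  # ascending: v(1), v(3), e13, v(5), e35, e51; then descending:
  # vbar(5), vbar(3), ebar35, vbar(1), ebar13, ebar51
  expect_equal(ord$pass, rep(c(1L, 2L), each = 6L))
  expect_equal(ord$dim, c(0, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1))
  expect_equal(ord$index, c(0, 1, 0, 2, 1, 2, 2, 1, 1, 0, 0, 2))
  expect_equal(ord$entry_value, c(1, 3, 3, 5, 5, 5, 5, 3, 3, 1, 1, 1))

  single <- vf_graph(1, values = 0.4)
  o1 <- build_filtration_order(single)
  expect_equal(o1$pass, c(1L, 2L))
  expect_equal(o1$dim, c(0L, 0L))

  # equal values: smaller vertex index first in both passes
  twin <- vf_graph(2, values = c(0.5, 0.5))
  ot <- build_filtration_order(twin)
  expect_equal(ot$index, c(0L, 1L, 0L, 1L))

  # edges always after both endpoints in their own pass
  g <- random_vf_graph(10, 20, seed = 2)
  og <- build_filtration_order(g)
  for (e in seq_len(nrow(g$edges))) {
    u <- g$edges[e, 1] + 1; v <- g$edges[e, 2] + 1
    expect_gt(og$pos_ae[e], max(og$pos_av[u], og$pos_av[v]))
    expect_gt(og$pos_de[e], max(og$pos_dv[u], og$pos_dv[v]))
  }
})

test_that("extended boundary matrix follows the cone construction", {
  ok2 <- build_filtration_order(k2())
  Mk2 <- build_extended_boundary_matrix(ok2)
  expect_equal(Mk2$n, 6L)
  # column of ebar (position 6) has rows {e, vbar2, vbar1} = {3, 4, 5}
  cols <- lapply(seq_len(Mk2$n), function(j)
    if (Mk2$ptr[j + 1] > Mk2$ptr[j]) Mk2$idx[(Mk2$ptr[j] + 1):Mk2$ptr[j + 1]]
    else integer(0))
  expect_equal(sort(cols[[6]]), c(3L, 4L, 5L))

  # single vertex: column of vbar is exactly {v}
  o1 <- build_filtration_order(vf_graph(1, values = 0))
  M1 <- build_extended_boundary_matrix(o1)
  expect_equal(M1$ptr, c(0L, 0L, 1L))
  expect_equal(M1$idx, 1L)

  # T135: 12 columns, exactly 3 empty (the ascending vertices)
  ot <- build_filtration_order(t135())
  Mt <- build_extended_boundary_matrix(ot)
  expect_equal(Mt$n, 12L)
  expect_equal(sum(diff(Mt$ptr) == 0L), 3L)
  # every row strictly precedes its column
  expect_true(all(Mt$idx < rep.int(seq_len(Mt$n), diff(Mt$ptr))))
})

test_that("reduction pairs every simplex with the hand-derived classes", {
  ok2 <- build_filtration_order(k2())
  pk2 <- reduce_and_pair(build_extended_boundary_matrix(ok2), ok2)
  expect_equal(sort(pk2$class), sort(c("ord0", "ext0", "rel1")))
  expect_equal(pk2$birth_value[pk2$class == "ext0"], 1)
  expect_equal(pk2$death_value[pk2$class == "ext0"], 2)

  ot <- build_filtration_order(t135())
  pt <- reduce_and_pair(build_extended_boundary_matrix(ot), ot)
  d <- extract_diagrams(pt, t135())
  expect_multiset_equal(d$ord0, rbind(c(3, 3), c(5, 5)))
  expect_multiset_equal(d$ext0, rbind(c(1, 5)))
  expect_multiset_equal(d$ext1, rbind(c(5, 1)))
  expect_multiset_equal(d$rel1, rbind(c(3, 3), c(1, 1)))

  iso <- vf_graph(1, values = 2.5)
  oi <- build_filtration_order(iso)
  pi_ <- reduce_and_pair(build_extended_boundary_matrix(oi), oi)
  expect_equal(pi_$class, "ext0")
  expect_equal(pi_$birth_value, 2.5)
  expect_equal(pi_$death_value, 2.5)
})

test_that("locating map sends simplices to their entrance vertices", {
  ord <- build_filtration_order(t135())
  loc <- build_locating_map(ord)
  # vertex simplices map to themselves in both passes
  expect_equal(loc[ord$pos_av], 0:2)
  expect_equal(loc[ord$pos_dv], 0:2)
  # ascending edge {0,2} (values 1,5) -> vertex 2; descending -> vertex 0
  expect_equal(loc[ord$pos_ae[3]], 2L)
  expect_equal(loc[ord$pos_de[3]], 0L)
})

test_that("eph runs one reduction per filter column", {
  g <- t135()
  res <- eph(g, cbind(g$values, g$values))
  expect_length(res, 2L)
  expect_equal(res[[1]]$diagrams, res[[2]]$diagrams)
  res8 <- eph(random_vf_graph(6, 8, seed = 1),
              matrix(runif(48), 6, 8))
  expect_length(res8, 8L)
  expect_equal(sum(vapply(res8, function(r) length(r$diagrams), 0L)), 32L)
  expect_error(eph(g, matrix(c(1, 2, Inf), 3, 1)), "finite")
})

test_that("pairing-count identities hold on random graphs", {
  for (s in 1:25) {
    n <- sample(2:25, 1)
    m <- sample(0:min(40, n * (n - 1) / 2), 1)
    g <- random_vf_graph(n, m, seed = s)
    r <- eph_one(g)
    d <- r$diagrams
    n_comp <- igraph::count_components(treph:::.as_igraph(g))
    expect_equal(nrow(d$ext0), n_comp)
    expect_equal(nrow(d$ext1), m - n + n_comp)
    expect_equal(nrow(d$ord0) + nrow(d$ext0), n)
    expect_equal(nrow(d$ord0) + nrow(d$ext1), m)
    expect_equal(nrow(d$rel1) + nrow(d$ext0), n)
    expect_equal(nrow(d$rel1) + nrow(d$ext1), m)
    # uniformity: everything is paired, all coordinates finite
    expect_equal(nrow(r$pairing) * 2L, 2L * (n + m))
    expect_true(all(is.finite(unlist(unclass(d)))))
    # per-class birth/death inequalities
    if (nrow(d$ord0)) expect_true(all(d$ord0[, 1] <= d$ord0[, 2]))
    if (nrow(d$ext0)) expect_true(all(d$ext0[, 1] <= d$ext0[, 2]))
    if (nrow(d$ext1)) expect_true(all(d$ext1[, 1] >= d$ext1[, 2]))
    if (nrow(d$rel1)) expect_true(all(d$rel1[, 1] >= d$rel1[, 2]))
  }
})

test_that("diagrams are additive over disjoint unions", {
  for (s in 1:5) {
    g1 <- random_vf_graph(7, 9, seed = s)
    g2 <- random_vf_graph(5, 6, seed = s + 50)
    gu <- treph:::disjoint_union(g1, g2)
    du <- eph_one(gu)$diagrams
    d1 <- eph_one(g1)$diagrams
    d2 <- eph_one(g2)$diagrams
    for (cl in c("ord0", "ext0", "ext1", "rel1"))
      expect_multiset_equal(du[[cl]], rbind(d1[[cl]], d2[[cl]]))
  }
})

test_that("diagrams are shift- and monotone-equivariant in the filter", {
  for (s in 1:5) {
    g <- random_vf_graph(8, 12, seed = s)
    d <- eph_one(g)$diagrams
    gs <- g; gs$values <- g$values + 2.5
    ds <- eph_one(gs)$diagrams
    gm <- g; gm$values <- g$values^3  # strictly increasing on (0,1)
    dm <- eph_one(gm)$diagrams
    for (cl in c("ord0", "ext0", "ext1", "rel1")) {
      expect_multiset_equal(ds[[cl]], d[[cl]] + 2.5)
      expect_multiset_equal(dm[[cl]], d[[cl]]^3)
    }
  }
})

test_that("negating the filter swaps Ord0 with Rel1 and mirrors Ext", {
  for (s in 1:5) {
    g <- random_vf_graph(9, 13, seed = s)
    gn <- g; gn$values <- -g$values
    d <- eph_one(g)$diagrams
    dn <- eph_one(gn)$diagrams
    expect_multiset_equal(dn$ord0, neg_pts(d$rel1))
    expect_multiset_equal(dn$rel1, neg_pts(d$ord0))
    expect_multiset_equal(dn$ext0, negswap_pts(d$ext0))
    expect_multiset_equal(dn$ext1, negswap_pts(d$ext1))
  }
})

test_that("diagram export writes valid JSON and CSV", {
  res <- eph(t135())
  js <- tempfile(fileext = ".json")
  write_diagrams(res, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$schema_version, 1L)
  expect_equal(unlist(parsed$filtrations[[1]]$ext0), c(1, 5))
  cs <- tempfile(fileext = ".csv")
  write_diagrams(res, cs, "csv")
  tab <- read.csv(cs)
  expect_setequal(names(tab), c("filter_index", "class", "birth", "death",
                                "birth_vertex", "death_vertex"))
  expect_equal(nrow(tab), 6L)
  ext1 <- tab[tab$class == "ext1", ]
  expect_equal(ext1$birth_vertex, 2L)
  expect_equal(ext1$death_vertex, 0L)
})
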