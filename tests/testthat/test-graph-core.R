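test_that("vf_graph validates its invariants", {
  g <- vf_graph(3, rbind(c(2, 0), c(1, 2)), values = c(1, 2, 3))
  # canonical u < v orientation, input order kept
  expect_equal(g$edges, rbind(c(0L, 2L), c(1L, 2L)))
  expect_error(vf_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(vf_graph(3, rbind(c(0, 1), c(1, 0))), "duplicate")
  expect_error(vf_graph(2, rbind(c(0, 2))), "out of range")
  expect_error(vf_graph(2, rbind(c(0, 1)), values = 1), "one entry per")
  expect_error(vf_graph(1, values = NaN), "finite")
})

test_that("edge-list and value files round-trip through read/write", {
  ed <- tempfile(); vl <- tempfile()
  g <- random_vf_graph(9, 14, seed = 11)
  write_graph(g, ed, vl)
  g2 <- read_graph(ed, vl)
  expect_equal(g2$n_vertices, g$n_vertices)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$values, g$values)
})

test_that("read_graph reports malformed input with line numbers", {
  ed <- tempfile()
  writeLines(c("0 1", "3 3"), ed)
  expect_error(read_graph(ed), "2: self-loop")
  writeLines(c("0 1", "1 0"), ed)
  expect_error(read_graph(ed), "duplicate edge")
  writeLines(c("0 1"), ed)
  vl <- tempfile()
  writeLines(c("0 1.0", "1 abc"), vl)
  expect_error(read_graph(ed, vl), "non-numeric value")
  writeLines(c("0 1.0"), vl)
  expect_error(read_graph(ed, vl), "missing value for vertex 1")
  # smallest nonempty case
  writeLines("0 1", ed)
  writeLines(c("0 1.0", "1 2.0"), vl)
  g <- read_graph(ed, vl)
  expect_equal(g$n_vertices, 2L)
  expect_equal(g$values, c(1, 2))
})

test_that("separation fixture realizes the component min-max matchings", {
  fx <- eph_separation_fixture()
  for (g in fx) {
    expect_equal(g$n_vertices, 6L)
    expect_equal(nrow(g$edges), 6L)
  }
  comp_of <- function(g, val) {
    memb <- igraph::components(treph:::.as_igraph(g))$membership
    memb[which(g$values == val)[1L]]
  }
  # g1: 5 lives with 1, 4 with 2; g2: 5 with 2, 4 with 1
  expect_equal(comp_of(fx$g1, 5), comp_of(fx$g1, 1))
  expect_equal(comp_of(fx$g1, 4), comp_of(fx$g1, 2))
  expect_equal(comp_of(fx$g2, 5), comp_of(fx$g2, 2))
  expect_equal(comp_of(fx$g2, 4), comp_of(fx$g2, 1))
  expect_equal(igraph::count_components(treph:::.as_igraph(fx$g1)), 2)
})

test_that("random_vf_graph is reproducible, feasible and injective", {
  g1 <- random_vf_graph(8, 12, seed = 5)
  g2 <- random_vf_graph(8, 12, seed = 5)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$values, g2$values)
  # only one simple graph has n = 5, m = 10: the complete one
  k5 <- random_vf_graph(5, 10, seed = 7)
  expect_equal(nrow(k5$edges), 10L)
  expect_equal(sort(unique(as.vector(k5$edges))), 0:4)
  expect_equal(anyDuplicated(k5$values), 0L)
  expect_error(random_vf_graph(4, 7, seed = 1), "infeasible")
  single <- random_vf_graph(1, 0, seed = 0)
  expect_equal(single$n_vertices, 1L)
  expect_equal(nrow(single$edges), 0L)
  for (s in 1:20)
    expect_equal(anyDuplicated(random_vf_graph(12, 15, seed = s)$values), 0L)
})

test_that("loop-count labels equal the first Betti number", {
  ds <- loop_count_task(30, seed = 3)
  expect_equal(sort(unique(ds$labels)), 0:2)
  expect_equal(as.vector(table(ds$labels)), rep(10L, 3L))
  for (i in seq_along(ds$graphs)) {
    g <- ds$graphs[[i]]
    ig <- treph:::.as_igraph(g)
    b1 <- nrow(g$edges) - g$n_vertices + igraph::count_components(ig)
    expect_equal(ds$labels[i], b1)
    expect_true(all(ds$features[[i]] == 1))
  }
})

test_that("TU-format files written by hand round-trip", {
  root <- tempfile(); dir.create(root)
  # two graphs: a triangle (nodes 1..3) and a path on 4 nodes (4..7),
  # both edge orientations listed as in the TU convention
  A <- rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1),
             c(4, 5), c(5, 4), c(5, 6), c(6, 5), c(6, 7), c(7, 6))
  write.table(A, file.path(root, "TOY_A.txt"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  writeLines(as.character(c(1, 1, 1, 2, 2, 2, 2)),
             file.path(root, "TOY_graph_indicator.txt"))
  writeLines(c("1", "-1"), file.path(root, "TOY_graph_labels.txt"))
  ds <- read_tu_dataset(root, "TOY")
  expect_equal(length(ds$graphs), 2L)
  expect_equal(ds$n_classes, 2L)
  expect_equal(ds$graphs[[1]]$n_vertices, 3L)
  expect_equal(nrow(ds$graphs[[1]]$edges), 3L)
  expect_equal(ds$graphs[[2]]$n_vertices, 4L)
  expect_equal(sort_rows(ds$graphs[[2]]$edges),
               sort_rows(rbind(c(0, 1), c(1, 2), c(2, 3))))
  # degree features
  expect_equal(as.vector(ds$features[[1]]), c(2, 2, 2))
  expect_error(read_tu_dataset(root, "MISSING"), "missing TU file")
})
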