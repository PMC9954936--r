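#' Construct a vertex-filtered graph
#'
#' A `vf_graph` is an undirected simple graph together with an optional
#' real-valued filter function on its vertices.  It is the basic input of
#' the extended-persistence engine and of the TREPH layer (which computes
#' the filter itself when `values` is absent).
#'
#' Vertices are indexed `0, ..., n_vertices - 1`.  Edges are stored in the
#' order supplied, each canonicalised to `u < v`; the stored order matters
#' only for deterministic tie-breaking in the filtration.
#'
#' @param n_vertices number of vertices (non-negative integer).
#' @param edges two-column integer matrix (or empty) of 0-based endpoints,
#'   one row per undirected edge.
#' @param values optional numeric vector of filter values, one per vertex.
#' @return an object of class `vf_graph` with fields `n_vertices`,
#'   `edges` (m x 2 integer matrix, `u < v` per row) and `values`
#'   (numeric or `NULL`).
#' @examples
#' tri <- vf_graph(3, rbind(c(0, 1), c(1, 2), c(0, 2)), values = c(1, 3, 5))
#' tri
#' @export
vf_graph <- function(n_vertices, edges = NULL, values = NULL) {
  n_vertices <- as.integer(n_vertices)
  stopifnot(length(n_vertices) == 1L, n_vertices >= 0L)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
  }
  if (any(edges < 0L) || any(edges >= n_vertices))
    stop("edge endpoint out of range [0, n_vertices)")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed")
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, c(2L, 1L)]
  key <- edges[, 1L] * n_vertices + edges[, 2L]
  if (anyDuplicated(key))
    stop("duplicate edges are not allowed")
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (length(values) != n_vertices)
      stop("values must have one entry per vertex")
    if (!all(is.finite(values)))
      stop("filter values must be finite")
  }
  structure(list(n_vertices = n_vertices, edges = edges, values = values),
            class = "vf_graph")
}

#' @export
print.vf_graph <- function(x, ...) {
  cat(sprintf("vf_graph: %d vertices, %d edges, filter %s\n",
              x$n_vertices, nrow(x$edges),
              if (is.null(x$values)) "absent" else "present"))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

#' Read a vertex-filtered graph from edge-list and value files
#'
#' The edge file contains one whitespace-separated pair `u v` of 0-based
#' vertex indices per line.  The optional values file contains lines
#' `vertex value` and must cover every vertex.  The vertex count is
#' `1 + max index` seen in either file unless `n_vertices` is given.
#'
#' @param edge_list_path path to the edge-list file.
#' @param values_path optional path to the vertex-value file.
#' @param n_vertices optional explicit vertex count (overrides inference).
#' @return a [vf_graph()].
#' @export
read_graph <- function(edge_list_path, values_path = NULL, n_vertices = NULL) {
  if (!file.exists(edge_list_path))
    stop("cannot open edge-list file: ", edge_list_path)
  if (!is.null(values_path) && !file.exists(values_path))
    stop("cannot open values file: ", values_path)
  lines <- readLines(edge_list_path)
  keep <- nzchar(trimws(lines))
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  lineno <- which(keep)
  edges <- matrix(integer(0), ncol = 2L)
  if (length(toks)) {
    bad <- which(vapply(toks, length, 0L) != 2L)
    if (length(bad))
      stop(sprintf("%s:%d: expected two vertex indices", edge_list_path,
                   lineno[bad[1L]]))
    uv <- suppressWarnings(vapply(toks, function(t) as.integer(t), integer(2)))
    nab <- which(colSums(is.na(uv)) > 0L)
    if (length(nab))
      stop(sprintf("%s:%d: non-integer vertex index", edge_list_path,
                   lineno[nab[1L]]))
    edges <- t(uv)
    sl <- which(edges[, 1L] == edges[, 2L])
    if (length(sl))
      stop(sprintf("%s:%d: self-loop", edge_list_path, lineno[sl[1L]]))
    canon <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    dup <- which(duplicated(canon[, 1L] * (max(edges) + 1L) + canon[, 2L]))
    if (length(dup))
      stop(sprintf("%s:%d: duplicate edge", edge_list_path, lineno[dup[1L]]))
  }
  values <- NULL
  nv <- if (length(edges)) max(edges) + 1L else 0L
  if (!is.null(values_path)) {
    vl <- readLines(values_path)
    vkeep <- nzchar(trimws(vl))
    vtok <- strsplit(trimws(vl[vkeep]), "[[:space:]]+")
    vln <- which(vkeep)
    bad <- which(vapply(vtok, length, 0L) != 2L)
    if (length(bad))
      stop(sprintf("%s:%d: expected 'vertex value'", values_path, vln[bad[1L]]))
    idx <- suppressWarnings(as.integer(vapply(vtok, `[`, "", 1L)))
    val <- suppressWarnings(as.numeric(vapply(vtok, `[`, "", 2L)))
    if (anyNA(idx))
      stop(sprintf("%s:%d: non-integer vertex index", values_path,
                   vln[which(is.na(idx))[1L]]))
    if (anyNA(val))
      stop(sprintf("%s:%d: non-numeric value", values_path,
                   vln[which(is.na(val))[1L]]))
    nv <- max(nv, if (length(idx)) max(idx) + 1L else 0L)
    if (!is.null(n_vertices)) nv <- as.integer(n_vertices)
    values <- rep(NA_real_, nv)
    values[idx + 1L] <- val
    miss <- which(is.na(values))
    if (length(miss))
      stop(sprintf("%s: missing value for vertex %d", values_path,
                   miss[1L] - 1L))
  } else if (!is.null(n_vertices)) {
    nv <- as.integer(n_vertices)
  }
  vf_graph(nv, edges, values)
}

#' Write a vertex-filtered graph to edge-list and value files
#'
#' Inverse of [read_graph()]: writes one `u v` line per edge and, when the
#' graph carries a filter, one `vertex value` line per vertex.
#'
#' @param g a [vf_graph()].
#' @param edge_list_path,values_path output paths; `values_path` may be
#'   `NULL` when `g` has no filter values.
#' @export
write_graph <- function(g, edge_list_path, values_path = NULL) {
  writeLines(sprintf("%d %d", g$edges[, 1L], g$edges[, 2L]), edge_list_path)
  if (!is.null(values_path) && !is.null(g$values))
    writeLines(sprintf("%d %.17g", seq_len(g$n_vertices) - 1L, g$values),
               values_path)
  invisible(g)
}

triangle_graph <- function(values) {
  vf_graph(3L, rbind(c(0L, 1L), c(1L, 2L), c(0L, 2L)), values = values)
}

disjoint_union <- function(g1, g2) {
  off <- g1$n_vertices
  vf_graph(off + g2$n_vertices,
           rbind(g1$edges, g2$edges + off),
           values = if (is.null(g1$values) || is.null(g2$values)) NULL
                    else c(g1$values, g2$values))
}

#' Fixture pair separating extended from ordinary persistence
#'
#' Two disconnected graphs, each a disjoint union of two filtered
#' triangles: `g1` carries vertex values (1,3,5) and (2,3,4), `g2` carries
#' (1,3,4) and (2,3,5).  Both graphs have component minima {1,2} and maxima
#' {4,5}, so their ordinary persistence diagrams — for the filter and for
#' its negation — coincide.  Extended persistence records *which* maximum
#' lives in the component of which minimum: in `g1` the pairings are (1,5)
#' and (2,4), in `g2` they are (1,4) and (2,5), so Ext0 (and likewise Ext1)
#' distinguish the pair.
#'
#' @return list with elements `g1` and `g2`, each a [vf_graph()] on 6
#'   vertices with 6 edges and 2 components.
#' @examples
#' fx <- eph_separation_fixture()
#' extract_diagrams(reduce_and_pair(
#'   build_extended_boundary_matrix(build_filtration_order(fx$g1)),
#'   build_filtration_order(fx$g1)), fx$g1)$ext0
#' @export
eph_separation_fixture <- function() {
  list(g1 = disjoint_union(triangle_graph(c(1, 3, 5)),
                           triangle_graph(c(2, 3, 4))),
       g2 = disjoint_union(triangle_graph(c(1, 3, 4)),
                           triangle_graph(c(2, 3, 5))))
}

#' Sample a uniform random simple graph with random filter values
#'
#' Draws a G(n, m) graph uniformly among simple graphs with `n` vertices
#' and `m` edges, and filter values i.i.d. uniform on (0, 1).  With
#' `injective = TRUE` values are re-drawn until pairwise distinct, so the
#' filtration has no ties.
#'
#' @param n,m vertex and edge counts; `m <= n * (n - 1) / 2`.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @param injective logical; force pairwise-distinct filter values.
#' @return a [vf_graph()] with values.
#' @export
random_vf_graph <- function(n, m, seed, injective = TRUE) {
  n <- as.integer(n); m <- as.integer(m)
  if (m > n * (n - 1) / 2 || m < 0L || n < 0L)
    stop("infeasible (n, m) for a simple graph")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  ig <- igraph::sample_gnm(n, m, directed = FALSE)
  edges <- matrix(as.integer(t(igraph::as_edgelist(ig, names = FALSE)) - 1L),
                  ncol = 2L, byrow = TRUE)
  vals <- stats::runif(n)
  while (injective && anyDuplicated(vals) > 0L) vals <- stats::runif(n)
  vf_graph(n, edges, values = vals)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' A labelled graph-classification dataset
#'
#' Plain container tying graphs, per-graph node-feature matrices and class
#' labels together for the training harness.
#'
#' @param graphs list of [vf_graph()] objects.
#' @param features list of numeric matrices, one per graph, rows matching
#'   vertices.
#' @param labels integer class labels in `[0, n_classes)`.
#' @param n_classes number of classes.
#' @return an object of class `graph_dataset`.
#' @export
graph_dataset <- function(graphs, features, labels, n_classes) {
  labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  stopifnot(length(graphs) == length(labels),
            length(graphs) == length(features),
            all(labels >= 0L), all(labels < n_classes))
  for (i in seq_along(graphs))
    stopifnot(nrow(features[[i]]) == graphs[[i]]$n_vertices)
  structure(list(graphs = graphs, features = features, labels = labels,
                 n_classes = n_classes),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf("graph_dataset: %d graphs, %d classes\n",
              length(x$graphs), x$n_classes))
  invisible(x)
}

# connected random graph with b extra (cycle-creating) edges: spanning tree
# from a uniform Pruefer sequence plus b uniformly chosen non-tree edges
.random_connected_graph <- function(n, extra) {
  ig <- igraph::sample_tree(n, method = "prufer")
  edges <- matrix(as.integer(t(igraph::as_edgelist(ig, names = FALSE)) - 1L),
                  ncol = 2L, byrow = TRUE)
  if (extra > 0L) {
    have <- pmin(edges[, 1], edges[, 2]) * n + pmax(edges[, 1], edges[, 2])
    all_u <- rep(0:(n - 2L), times = (n - 1L):1L)
    all_v <- unlist(lapply(0:(n - 2L), function(u) (u + 1L):(n - 1L)))
    free <- which(!(all_u * n + all_v) %in% have)
    pick <- sample(free, extra)
    edges <- rbind(edges, cbind(all_u[pick], all_v[pick]))
  }
  vf_graph(n, edges)
}

#' Synthetic loop-counting classification task
#'
#' Generates a balanced dataset whose class label is the first Betti number
#' of the graph: random trees (label 0), unicyclic (label 1) and bicyclic
#' (label 2) connected graphs of matched size.  Node features are
#' uninformative all-ones vectors, so only structure can solve the task;
#' message-passing networks cannot count independent loops while extended
#' persistence reads them off as `|Ext1|`.
#'
#' @param n_graphs total number of graphs (multiple of 3 recommended).
#' @param seed integer seed.
#' @param n_range inclusive range of vertex counts to sample from.
#' @param feature_dim width of the all-ones node features.
#' @return a [graph_dataset()] with labels 0, 1, 2.
#' @export
loop_count_task <- function(n_graphs, seed, n_range = c(8L, 12L),
                            feature_dim = 1L) {
  stopifnot(n_graphs >= 6L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  labels <- rep(0:2, length.out = n_graphs)
  graphs <- vector("list", n_graphs)
  for (i in seq_len(n_graphs)) {
    n <- sample(n_range[1L]:n_range[2L], 1L)
    graphs[[i]] <- .random_connected_graph(n, labels[i])
  }
  feats <- lapply(graphs, function(g)
    matrix(1, nrow = g$n_vertices, ncol = feature_dim))
  graph_dataset(graphs, feats, labels, 3L)
}

#' Read a graph-classification dataset in TU plain-text format
#'
#' Parses the standard TU layout: `<name>_A.txt` (comma-separated 1-based
#' directed adjacency pairs), `<name>_graph_indicator.txt` (graph id per
#' node), `<name>_graph_labels.txt` (one label per graph) and optionally
#' `<name>_node_labels.txt`.  Both orientations of each undirected edge may
#' be listed; duplicates are collapsed.  Node features default to degree
#' indices (for a downstream learnable embedding); pass
#' `features = "ones"` for the uninformative all-ones setting.
#'
#' @param root directory containing the files.
#' @param name dataset name prefix.
#' @param features `"degree"` (1-column matrix of degrees) or `"ones"`.
#' @return a [graph_dataset()].
#' @export
read_tu_dataset <- function(root, name, features = c("degree", "ones")) {
  features <- match.arg(features)
  p <- function(suffix) file.path(root, paste0(name, "_", suffix, ".txt"))
  for (s in c("A", "graph_indicator", "graph_labels"))
    if (!file.exists(p(s))) stop("missing TU file: ", p(s))
  A <- utils::read.table(p("A"), sep = ",", col.names = c("u", "v"),
                         colClasses = "integer")
  gi <- scan(p("graph_indicator"), what = integer(), quiet = TRUE)
  gl <- scan(p("graph_labels"), what = integer(), quiet = TRUE)
  n_graphs <- length(gl)
  if (any(gi < 1L) || any(gi > n_graphs))
    stop("graph indicator out of range")
  if (any(gi[A$u] != gi[A$v]))
    stop("inconsistent graph indicator: edge crosses graphs")
  # relabel classes to 0-based contiguous
  labs <- as.integer(factor(gl)) - 1L
  offset <- c(0L, cumsum(tabulate(gi, nbins = n_graphs)))
  graphs <- vector("list", n_graphs)
  eg <- gi[A$u]
  ue <- pmin(A$u, A$v); ve <- pmax(A$u, A$v)
  keep <- !duplicated(cbind(ue, ve))
  ue <- ue[keep]; ve <- ve[keep]; eg <- eg[keep]
  for (k in seq_len(n_graphs)) {
    nk <- sum(gi == k)
    sel <- eg == k
    graphs[[k]] <- vf_graph(nk, cbind(ue[sel] - offset[k] - 1L,
                                      ve[sel] - offset[k] - 1L))
  }
  feats <- lapply(graphs, function(g) {
    if (features == "ones") matrix(1, g$n_vertices, 1L)
    else {
      deg <- tabulate(g$edges + 1L, nbins = g$n_vertices)
      matrix(as.numeric(deg), ncol = 1L)
    }
  })
  graph_dataset(graphs, feats, labs, max(labs) + 1L)
}
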