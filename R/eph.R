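# Extended persistence engine for vertex-filtered graphs.
#
# Every vertex and edge appears twice as an "algebraic simplex": once in
# the ascending (sublevel) pass and once in the descending (superlevel)
# pass.  A total order on the 2(|V|+|E|) simplices defines the filtration;
# Z2 reduction of the coned boundary matrix pairs every simplex, and the
# pairs split by shape into the four diagrams Ord0, Ext0, Ext1 and Rel1.

PASS_ASC <- 1L
PASS_DESC <- 2L
DIM_VERTEX <- 0L
DIM_EDGE <- 1L

#' Sublevel subgraph of a vertex-filtered graph
#'
#' Restricts `g` to the vertices with filter value at most `a`, keeping the
#' edges with both endpoints retained.  Vertices are re-indexed
#' contiguously; the mapping back to the original indices is attached as
#' attribute `"vertex_map"`.
#'
#' @param g a [vf_graph()] with values.
#' @param a threshold.
#' @return a [vf_graph()].
#' @export
sublevel_subgraph <- function(g, a) {
  stopifnot(!is.null(g$values))
  keep <- which(g$values <= a)
  new_id <- rep(NA_integer_, g$n_vertices)
  new_id[keep] <- seq_along(keep) - 1L
  u <- g$edges[, 1L] + 1L; v <- g$edges[, 2L] + 1L
  esel <- !is.na(new_id[u]) & !is.na(new_id[v])
  sub <- vf_graph(length(keep),
                  cbind(new_id[u[esel]], new_id[v[esel]]),
                  values = g$values[keep])
  attr(sub, "vertex_map") <- keep - 1L
  sub
}

#' Build the extended filtration order
#'
#' Orders the 2(|V|+|E|) algebraic simplices of `g`: the ascending block
#' sorted by entry value (vertex before edge, then stored index, on ties),
#' followed by the descending block sorted by decreasing entry value with
#' the same tie rule.  Entry values are `f(v)` for vertices, the larger
#' endpoint value for ascending edges and the smaller endpoint value for
#' descending edges, so every edge follows both of its endpoints in its
#' own pass.
#'
#' @param g a [vf_graph()] with values.
#' @return an object of class `eph_order`: parallel vectors `pass`, `dim`,
#'   `index` (0-based vertex/edge index), `entry_value` over filtration
#'   positions, and position lookups `pos_av`, `pos_ae`, `pos_dv`,
#'   `pos_de` (1-based positions of ascending/descending
#'   vertices/edges).
#' @export
build_filtration_order <- function(g) {
  stopifnot(!is.null(g$values))
  n <- g$n_vertices; m <- n_edges(g)
  f <- g$values
  eu <- g$edges[, 1L] + 1L; ev <- g$edges[, 2L] + 1L
  e_asc <- pmax(f[eu], f[ev])
  e_desc <- pmin(f[eu], f[ev])

  val_a <- c(f, e_asc)
  dim_a <- c(rep(DIM_VERTEX, n), rep(DIM_EDGE, m))
  idx_a <- c(seq_len(n) - 1L, seq_len(m) - 1L)
  o_a <- order(val_a, dim_a, idx_a)

  val_d <- c(f, e_desc)
  o_d <- order(-val_d, dim_a, idx_a)

  pass <- c(rep(PASS_ASC, n + m), rep(PASS_DESC, n + m))
  dim <- c(dim_a[o_a], dim_a[o_d])
  index <- c(idx_a[o_a], idx_a[o_d])
  entry_value <- c(val_a[o_a], val_d[o_d])

  N <- 2L * (n + m)
  pos_a <- integer(n + m); pos_a[o_a] <- seq_len(n + m)
  pos_d <- integer(n + m); pos_d[o_d] <- seq_len(n + m) + (n + m)

  structure(list(
    n_vertices = n, n_edges = m, n_simplices = N,
    pass = pass, dim = dim, index = index, entry_value = entry_value,
    pos_av = pos_a[seq_len(n)],
    pos_ae = if (m) pos_a[n + seq_len(m)] else integer(0),
    pos_dv = pos_d[seq_len(n)],
    pos_de = if (m) pos_d[n + seq_len(m)] else integer(0),
    edges = g$edges
  ), class = "eph_order")
}

#' @export
print.eph_order <- function(x, ...) {
  cat(sprintf("eph_order: %d simplices (%d vertices, %d edges, two passes)\n",
              x$n_simplices, x$n_vertices, x$n_edges))
  invisible(x)
}

#' Boundary matrix of the extended filtration
#'
#' Builds the Z2 boundary matrix of the cone construction in compressed
#' sparse column form, one column per filtration position.  Ascending
#' vertices have empty columns; an ascending edge hits its two ascending
#' endpoints; a descending vertex hits its ascending copy; a descending
#' edge hits its ascending copy and its two descending endpoints.  Row
#' indices are strictly below the column index and sorted within columns.
#'
#' @param order an [build_filtration_order()] result.
#' @return list with fields `ptr` (0-based column offsets, length
#'   `n_simplices + 1`), `idx` (1-based row positions) and `n`.
#' @export
build_extended_boundary_matrix <- function(order) {
  n <- order$n_vertices; m <- order$n_edges; N <- order$n_simplices
  eu <- order$edges[, 1L] + 1L; ev <- order$edges[, 2L] + 1L
  cnt <- integer(N)
  cnt[order$pos_ae] <- 2L
  cnt[order$pos_dv] <- 1L
  cnt[order$pos_de] <- 3L
  ptr <- c(0L, cumsum(cnt))
  idx <- integer(ptr[N + 1L])
  if (m) {
    # ascending edge {u, v}: ascending endpoint positions, sorted
    p1 <- pmin(order$pos_av[eu], order$pos_av[ev])
    p2 <- pmax(order$pos_av[eu], order$pos_av[ev])
    at <- ptr[order$pos_ae]
    idx[at + 1L] <- p1
    idx[at + 2L] <- p2
  }
  # descending vertex: its ascending copy
  idx[ptr[order$pos_dv] + 1L] <- order$pos_av
  if (m) {
    # descending edge: ascending edge copy, then descending endpoints
    q1 <- pmin(order$pos_dv[eu], order$pos_dv[ev])
    q2 <- pmax(order$pos_dv[eu], order$pos_dv[ev])
    at <- ptr[order$pos_de]
    idx[at + 1L] <- order$pos_ae
    idx[at + 2L] <- q1
    idx[at + 3L] <- q2
  }
  if (any(idx >= rep.int(seq_len(N), cnt)))
    stop("internal ordering violation: row at or after its column")
  list(ptr = ptr, idx = idx, n = N)
}

.classify_pair <- function(order, birth, death) {
  bp <- order$pass[birth]; bd <- order$dim[birth]
  dp <- order$pass[death]; dd <- order$dim[death]
  cls <- character(length(birth))
  cls[bp == PASS_ASC & bd == DIM_VERTEX & dp == PASS_ASC] <- "ord0"
  cls[bp == PASS_ASC & bd == DIM_VERTEX & dp == PASS_DESC] <- "ext0"
  cls[bp == PASS_ASC & bd == DIM_EDGE] <- "ext1"
  cls[bp == PASS_DESC] <- "rel1"
  cls
}

#' Reduce the boundary matrix and pair all simplices
#'
#' Standard left-to-right persistence reduction over Z2: each column is
#' repeatedly summed with an earlier column sharing its lowest nonzero row
#' until the column is zero or its lowest row is unique; surviving lowest
#' rows define the pairing (row = birth, column = death).  On a graph's
#' extended filtration every simplex is paired; the pairs are classified
#' by shape as Ord0 `(v, e)`, Ext0 `(v, v-bar)`, Ext1 `(e, e-bar)` or
#' Rel1 `(v-bar, e-bar)`.
#'
#' @param M boundary matrix from [build_extended_boundary_matrix()].
#' @param order the matching [build_filtration_order()] result.
#' @return an object of class `eph_pairing`: a data frame with columns
#'   `birth_pos`, `death_pos` (filtration positions), `class`,
#'   `birth_value`, `death_value` (entry values).
#' @export
reduce_and_pair <- function(M, order) {
  core <- .pair_core(M, order)
  pr <- data.frame(
    birth_pos = core$birth,
    death_pos = core$death,
    class = core$class,
    birth_value = order$entry_value[core$birth],
    death_value = order$entry_value[core$death]
  )
  class(pr) <- c("eph_pairing", "data.frame")
  pr
}

# lean pairing used both by reduce_and_pair and by the layer's inner loop
.pair_core <- function(M, order) {
  low <- reduce_boundary(M$ptr, M$idx - 1L, M$n)
  death <- which(low >= 0L)
  birth <- low[death] + 1L
  if (2L * length(death) != order$n_simplices ||
      anyDuplicated(c(birth, death)) > 0L)
    stop("internal error: extended persistence must pair every simplex")
  list(birth = birth, death = death,
       class = .classify_pair(order, birth, death))
}

#' Extract the four extended persistence diagrams
#'
#' Each pair (alpha, beta) contributes the planar point
#' (entry value of alpha, entry value of beta) to the multiset of its
#' class.  Coordinates are raw filter values; the reversed-order
#' convention of the descending pass shows up only as the per-class
#' birth/death inequality (Ord0 and Ext0 have birth <= death, Ext1 and
#' Rel1 have birth >= death), never as negated numbers.
#'
#' @param pairing an [reduce_and_pair()] result.
#' @param g the graph it was computed from (used for sanity checks).
#' @return an object of class `eph_diagrams`: list with elements `ord0`,
#'   `ext0`, `ext1`, `rel1`, each a 2-column matrix `(birth, death)`.
#' @export
extract_diagrams <- function(pairing, g = NULL) {
  out <- lapply(c(ord0 = "ord0", ext0 = "ext0", ext1 = "ext1", rel1 = "rel1"),
                function(cl) {
    sel <- pairing$class == cl
    cbind(birth = pairing$birth_value[sel], death = pairing$death_value[sel])
  })
  if (!is.null(g)) {
    stopifnot(nrow(out$ord0) + nrow(out$ext0) == g$n_vertices,
              nrow(out$ord0) + nrow(out$ext1) == n_edges(g))
  }
  structure(out, class = "eph_diagrams")
}

#' @export
print.eph_diagrams <- function(x, ...) {
  cat(sprintf("eph_diagrams: |Ord0|=%d |Ext0|=%d |Ext1|=%d |Rel1|=%d\n",
              nrow(x$ord0), nrow(x$ext0), nrow(x$ext1), nrow(x$rel1)))
  invisible(x)
}

#' Locating map from algebraic simplices to vertices
#'
#' Maps every filtration position to the vertex marking its entrance:
#' vertex simplices map to themselves; an edge maps to whichever of its
#' endpoints enters later in the edge's own pass (under an injective
#' filter, the argmax endpoint ascending and the argmin endpoint
#' descending).
#'
#' @param order an [build_filtration_order()] result.
#' @return integer vector over filtration positions with 0-based vertex
#'   indices.
#' @export
build_locating_map <- function(order) {
  n <- order$n_vertices; m <- order$n_edges
  loc <- integer(order$n_simplices)
  loc[order$pos_av] <- seq_len(n) - 1L
  loc[order$pos_dv] <- seq_len(n) - 1L
  if (m) {
    eu <- order$edges[, 1L]; ev <- order$edges[, 2L]
    later_a <- ifelse(order$pos_av[eu + 1L] > order$pos_av[ev + 1L], eu, ev)
    later_d <- ifelse(order$pos_dv[eu + 1L] > order$pos_dv[ev + 1L], eu, ev)
    loc[order$pos_ae] <- later_a
    loc[order$pos_de] <- later_d
  }
  loc
}

#' Extended persistence of one or more filter functions
#'
#' Runs the full pipeline (ordering, boundary reduction, pairing,
#' diagrams, locating map) once per filter column.
#'
#' @param g a [vf_graph()]; its own `values` are ignored when `filters`
#'   is supplied.
#' @param filters optional numeric matrix `n_vertices x df` of filter
#'   functions; defaults to the single column `g$values`.
#' @return a list of length `df`; each element has fields `diagrams`
#'   ([extract_diagrams()]), `pairing` ([reduce_and_pair()]), `locate`
#'   ([build_locating_map()]) and `order`.
#' @examples
#' tri <- vf_graph(3, rbind(c(0, 1), c(1, 2), c(0, 2)), values = c(1, 3, 5))
#' eph(tri)[[1]]$diagrams$ext0   # the min-max pair (1, 5)
#' @export
eph <- function(g, filters = NULL) {
  if (is.null(filters)) {
    stopifnot(!is.null(g$values))
    filters <- matrix(g$values, ncol = 1L)
  }
  filters <- as.matrix(filters)
  stopifnot(nrow(filters) == g$n_vertices, ncol(filters) >= 1L)
  if (!all(is.finite(filters))) stop("filter values must be finite")
  lapply(seq_len(ncol(filters)), function(k) {
    gk <- g; gk$values <- filters[, k]
    ord <- build_filtration_order(gk)
    pairing <- reduce_and_pair(build_extended_boundary_matrix(ord), ord)
    list(diagrams = extract_diagrams(pairing, gk),
         pairing = pairing,
         locate = build_locating_map(ord),
         order = ord)
  })
}
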