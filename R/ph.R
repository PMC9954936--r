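# Ordinary persistence by union-find (elder rule) and the independent
# oracle used to cross-check the matrix reduction.

# union-find with path halving; roots carry the position of the earliest
# vertex of their component in the ascending order (the "elder")
.uf_find <- function(parent, x) {
  while (parent[x] != x) {
    parent[x] <- parent[parent[x]]
    x <- parent[x]
  }
  x
}

# 0-dimensional persistence pairs of the sublevel filtration.
# Returns finite pairs (birth vertex, killing edge) and one essential
# vertex (the filter minimum) per component.  Age is measured by position
# in the ascending filtration order, so ties resolve exactly as in the
# boundary reduction.
.ph_dim0 <- function(g, order = build_filtration_order(g)) {
  n <- g$n_vertices; m <- n_edges(g)
  parent <- seq_len(n)
  elder <- order$pos_av  # per vertex, its own position; per root, the min
  birth_v <- integer(0); death_e <- integer(0)
  cyc <- integer(0)
  eo <- order(order$pos_ae)
  for (e in eo) {
    u <- g$edges[e, 1L] + 1L; v <- g$edges[e, 2L] + 1L
    ru <- .uf_find(parent, u); rv <- .uf_find(parent, v)
    if (ru == rv) { cyc <- c(cyc, e); next }
    # the younger root (later elder position) dies
    if (elder[ru] < elder[rv]) { older <- ru; younger <- rv }
    else { older <- rv; younger <- ru }
    yv <- match(elder[younger], order$pos_av)
    birth_v <- c(birth_v, yv)
    death_e <- c(death_e, e)
    parent[younger] <- older
  }
  roots <- vapply(seq_len(n), function(v) .uf_find(parent, v), 0L)
  ess <- if (n) match(elder[unique(roots)], order$pos_av) else integer(0)
  list(birth_vertex = birth_v, death_edge = death_e,
       essential_vertex = ess, cycle_edges = cyc)
}

#' Ordinary persistence diagrams of the sublevel filtration
#'
#' Dimension 0: one finite point `(f(v), f(e))` per component that merges
#' into an older one, plus one essential point `(min f, Inf)` per
#' component.  Dimension 1: one essential point `(f(e), Inf)` per
#' cycle-creating edge.  Infinite deaths are stored as `Inf`, never as a
#' finite sentinel.  Computed by union-find, independently of the
#' boundary-matrix reduction.
#'
#' @param g a [vf_graph()] with values.
#' @return object of class `ph_diagrams`: list with `dim0` and `dim1`,
#'   2-column matrices `(birth, death)`, plus 0-based location columns
#'   `dim0_vertex` (vertex creating each dim-0 feature, essential points
#'   last) and `dim1_vertex` (later-entering endpoint of each cycle
#'   edge).
#' @export
ph <- function(g) {
  stopifnot(!is.null(g$values))
  ord <- build_filtration_order(g)
  d0 <- .ph_dim0(g, ord)
  f <- g$values
  e_entry <- ord$entry_value[ord$pos_ae]
  loc <- build_locating_map(ord)
  dim0 <- cbind(birth = c(f[d0$birth_vertex], f[d0$essential_vertex]),
                death = c(e_entry[d0$death_edge],
                          rep(Inf, length(d0$essential_vertex))))
  dim1 <- cbind(birth = e_entry[d0$cycle_edges],
                death = rep(Inf, length(d0$cycle_edges)))
  structure(list(
    dim0 = dim0, dim1 = dim1,
    dim0_vertex = c(d0$birth_vertex, d0$essential_vertex) - 1L,
    dim1_vertex = if (length(d0$cycle_edges))
      loc[ord$pos_ae[d0$cycle_edges]] else integer(0)
  ), class = "ph_diagrams")
}

#' @export
print.ph_diagrams <- function(x, ...) {
  cat(sprintf("ph_diagrams: %d dim-0 points (%d essential), %d dim-1 points\n",
              nrow(x$dim0), sum(is.infinite(x$dim0[, 2L])), nrow(x$dim1)))
  invisible(x)
}

#' Project extended persistence onto ordinary persistence
#'
#' Recovers the ordinary diagrams from the extended ones: dimension 0 is
#' Ord0 plus a point `(a, Inf)` for each Ext0 point `(a, b)`; dimension 1
#' is a point `(c, Inf)` for each Ext1 point `(c, d)`.
#'
#' @param d an [extract_diagrams()] result.
#' @return a `ph_diagrams` object (without location columns).
#' @export
ph_from_eph <- function(d) {
  dim0 <- rbind(d$ord0,
                cbind(birth = d$ext0[, 1L],
                      death = rep(Inf, nrow(d$ext0))))
  dim1 <- cbind(birth = if (nrow(d$ext1)) d$ext1[, 1L] else numeric(0),
                death = rep(Inf, nrow(d$ext1)))
  colnames(dim0) <- colnames(dim1) <- c("birth", "death")
  structure(list(dim0 = dim0, dim1 = dim1,
                 dim0_vertex = NULL, dim1_vertex = NULL),
            class = "ph_diagrams")
}

#' Independent oracle for the extended diagrams
#'
#' Recomputes the extended diagrams without any matrix reduction, using
#' only union-find and component minima/maxima:
#' Ord0 from the elder rule on the ascending order; Rel1 as Ord0 of `-f`
#' with both coordinates negated back; Ext0 as one `(min f, max f)` point
#' per connected component; Ext1 only as the separate birth and death
#' value multisets (entry values of cycle-creating edges in the ascending
#' and descending passes) — the oracle does not determine how Ext1 births
#' and deaths pair up.
#'
#' @param g a [vf_graph()] with values.
#' @return list with `ord0`, `rel1`, `ext0` (2-column matrices) and
#'   `ext1_births`, `ext1_deaths` (numeric multisets).
#' @export
oracle_diagrams <- function(g) {
  stopifnot(!is.null(g$values))
  ord <- build_filtration_order(g)
  d0 <- .ph_dim0(g, ord)
  f <- g$values
  e_entry <- ord$entry_value[ord$pos_ae]
  ord0 <- cbind(birth = f[d0$birth_vertex], death = e_entry[d0$death_edge])

  gneg <- g; gneg$values <- -g$values
  ordn <- build_filtration_order(gneg)
  d0n <- .ph_dim0(gneg, ordn)
  en_entry <- ordn$entry_value[ordn$pos_ae]
  rel1 <- cbind(birth = f[d0n$birth_vertex],
                death = -en_entry[d0n$death_edge])
  colnames(rel1) <- c("birth", "death")

  comp <- igraph::components(.as_igraph(g))$membership
  n_comp <- if (g$n_vertices) max(comp) else 0L
  ext0 <- t(vapply(seq_len(n_comp), function(k) {
    vals <- f[comp == k]
    c(min(vals), max(vals))
  }, numeric(2)))
  if (n_comp == 0L) ext0 <- matrix(numeric(0), ncol = 2L)
  colnames(ext0) <- c("birth", "death")

  list(ord0 = ord0, rel1 = rel1, ext0 = ext0,
       ext1_births = e_entry[d0$cycle_edges],
       ext1_deaths = -en_entry[d0n$cycle_edges])
}

.as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_vertices, directed = FALSE)
  if (n_edges(g)) ig <- igraph::add_edges(ig, as.vector(t(g$edges + 1L)))
  ig
}

#' Export extended diagrams to JSON or CSV
#'
#' JSON uses keys `ord0`/`ext0`/`ext1`/`rel1`, each a list of
#' `[birth, death]` pairs, plus a `schema_version` field.  CSV emits one
#' row per point with columns `filter_index`, `class`, `birth`, `death`,
#' `birth_vertex`, `death_vertex` (0-based locating vertices).
#'
#' @param results result list from [eph()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_diagrams <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(schema_version = 1L,
                    filtrations = lapply(results, function(r)
                      lapply(unclass(r$diagrams), function(mm)
                        lapply(seq_len(nrow(mm)), function(i)
                          as.numeric(mm[i, ])))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(seq_along(results), function(k) {
      r <- results[[k]]
      data.frame(filter_index = k - 1L,
                 class = r$pairing$class,
                 birth = r$pairing$birth_value,
                 death = r$pairing$death_value,
                 birth_vertex = r$locate[r$pairing$birth_pos],
                 death_vertex = r$locate[r$pairing$death_pos])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
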