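# shared fixtures and multiset helpers

t135 <- function() vf_graph(3, rbind(c(0, 1), c(1, 2), c(0, 2)),
                            values = c(1, 3, 5))

k2 <- function() vf_graph(2, rbind(c(0, 1)), values = c(1, 2))

cycle_graph <- function(n, values = NULL) {
  vf_graph(n, cbind(0:(n - 1), c(1:(n - 1), 0)), values = values)
}

sort_rows <- function(m) {
  m <- unname(as.matrix(m))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

expect_multiset_equal <- function(a, b, tol = 1e-12) {
  expect_equal(sort_rows(a), sort_rows(b), tolerance = tol)
}

eph_one <- function(g) eph(g)[[1L]]

# negate both coordinates / negate-and-swap, for symmetry checks
neg_pts <- function(m) if (nrow(m)) -m[, , drop = FALSE] else m
negswap_pts <- function(m) {
  if (!nrow(m)) return(m)
  cbind(-m[, 2L], -m[, 1L])
}
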