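# Independent pure-R oracle: from-scratch objective evaluation and plain
# full enumeration over all bipartitions. Deliberately kept separate from
# the package's evaluation path (C++/incremental) so the two can be
# compared against each other.

oracle_evaluate <- function(graph, side) {
  w <- graph$w
  s <- side[graph$labels]
  cut <- 0
  intra <- 0
  n <- graph$n
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is.na(w[i, j])) next
      if (s[[i]] == s[[j]]) intra <- intra + 1 / w[i, j]
      else cut <- cut + w[i, j]
    }
  }
  list(cut_sum = cut, intra_recip = intra, value = cut * intra)
}

# Plain enumeration: every subset of vertices 2..n forms side 2 (vertex 1
# stays on side 1); the empty subset (trivial partition) is skipped.
oracle_optimum <- function(graph) {
  n <- graph$n
  stopifnot(n >= 2L, n <= 16L)
  best <- -Inf
  best_side <- NULL
  for (mask in 1:(2^(n - 1L) - 1L)) {
    s <- c(1L, 1L + bitwAnd(bitwShiftR(mask, 0:(n - 2L)), 1L))
    names(s) <- graph$labels
    v <- oracle_evaluate(graph, s)$value
    if (v > best) {
      best <- v
      best_side <- s
    }
  }
  list(value = best, side = best_side)
}

# Shared fixtures ------------------------------------------------------

uniform_k4 <- function() {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  ah_graph(m)
}

planted_k4 <- function() {
  planted_partition_graph(c(2, 2), d_within = 1, d_between = 10)$graph
}

three_group_graph <- function() {
  between <- matrix(c(0, 10, 10,
                      10, 0, 4,
                      10, 4, 0), 3, 3)
  planted_partition_graph(c(4, 4, 4), d_within = 1, d_between = between)
}

rel_equal <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}
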