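#' Greedy bipartition construction
#'
#' Seeds the two sides with the endpoints of a maximum-weight edge (the
#' two most distant objects), then assigns the remaining vertices one at a
#' time: the unassigned vertex with the greatest total distance to the
#' already-assigned vertices is placed on whichever side yields the larger
#' partial objective. On a disconnected graph each connected component
#' contributes its own seed pair before the main loop. This construction
#' initialises the memetic population and backs the fixed-parameter
#' decision procedure.
#'
#' In randomized mode (used for diversity restarts) the seed edge is drawn
#' uniformly from the top decile of edges by weight and selection ties
#' break uniformly at random; everything else is unchanged.
#'
#' @param graph An [ah_graph] with `n >= 2`.
#' @param rng_seed Integer seed. When supplied, randomized mode is enabled
#'   and results are reproducible; when `NULL` (default) the construction
#'   is fully deterministic unless `randomized = TRUE`, in which case the
#'   ambient RNG stream is used.
#' @param randomized Enable the randomized variant explicitly.
#' @param strategy Vertex-selection rule for the main loop:
#'   `"attachment"` (default; maximum total weight to assigned vertices),
#'   `"max_edge"` (maximum single edge to an assigned vertex), or
#'   `"fixed"` (lexicographic label order).
#' @return An `ah_greedy`: list with `partition` (an `ah_partition`) and
#'   `trace` (seed edges plus a tibble of per-step assignments and partial
#'   objective values).
#' @examples
#' g <- planted_partition_graph(c(2, 2), 1, 10)$graph
#' greedy_partition(g)$partition$breakdown$value  # 80
#' @export
greedy_partition <- function(graph, rng_seed = NULL,
                             randomized = !is.null(rng_seed),
                             strategy = c("attachment", "max_edge", "fixed")) {
  stopifnot(inherits(graph, "ah_graph"))
  strategy <- match.arg(strategy)
  if (graph$n < 2L) stop("greedy construction requires n >= 2")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- greedy_raw(graph, randomized,
                    switch(strategy, attachment = 1L, max_edge = 2L,
                           fixed = 3L))
  seed_edges <- res$seed_edges
  part <- ah_partition(graph, stats::setNames(res$side, graph$labels))
  trace <- list(
    seed_edges = seed_edges,
    assignments = tibble::tibble(
      vertex = graph$labels[res$order + 1L],
      side = as.integer(res$order_side),
      partial_value = as.numeric(res$partial_value)
    )
  )
  structure(list(partition = part, trace = trace), class = "ah_greedy")
}

#' @export
print.ah_greedy <- function(x, ...) {
  cat("<ah_greedy> value = ", format(x$partition$breakdown$value),
      ", seed(s): ",
      paste(vapply(x$trace$seed_edges, paste, "", collapse = "-"),
            collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Object-free greedy core shared with the memetic initialiser: seeds each
# component, runs the fill, returns the raw result plus the seed edges.
greedy_raw <- function(graph, randomized, strategy_code = 1L) {
  lr <- lex_ranks(graph$labels)
  side0 <- integer(graph$n)
  seed_edges <- list()
  for (comp in graph_components(graph)) {
    if (length(comp) < 2L) next
    e <- pick_seed_edge(graph, comp, randomized)
    # lexicographically smaller endpoint goes to side 1
    if (lr[e[1L]] > lr[e[2L]]) e <- rev(e)
    side0[e[1L]] <- 1L
    side0[e[2L]] <- 2L
    seed_edges[[length(seed_edges) + 1L]] <-
      c(graph$labels[e[1L]], graph$labels[e[2L]])
  }
  if (!any(side0 == 1L) || !any(side0 == 2L)) {
    stop("graph has no edges to seed from")
  }
  res <- cpp_greedy_fill(graph$w, side0, lr, strategy_code, randomized)
  res$seed_edges <- seed_edges
  res
}

# Seed edge inside a component: maximum weight, ties by lexicographic
# endpoint pair; randomized mode draws uniformly from the top decile.
pick_seed_edge <- function(graph, comp, randomized) {
  lr <- lex_ranks(graph$labels)
  pairs <- which(upper.tri(graph$w), arr.ind = TRUE)
  keep <- pairs[, 1L] %in% comp & pairs[, 2L] %in% comp &
    !is.na(graph$w[pairs])
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("component has no edges")
  wts <- graph$w[pairs]
  lo <- pmin(lr[pairs[, 1L]], lr[pairs[, 2L]])
  hi <- pmax(lr[pairs[, 1L]], lr[pairs[, 2L]])
  ord <- order(-wts, lo, hi)
  if (randomized) {
    k <- max(1L, ceiling(nrow(pairs) / 10))
    pick <- ord[sample.int(k, 1L)]
  } else {
    pick <- ord[1L]
  }
  c(pairs[pick, 1L], pairs[pick, 2L])
}
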