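#' Solve one bipartition, choosing the solver by instance size
#'
#' `n = 2` returns the unique split; `n <= exact_threshold` uses exhaustive
#' enumeration; larger instances go to the memetic optimiser.
#'
#' @param graph An [ah_graph] with `n >= 2`.
#' @param exact_threshold Largest `n` solved exactly (default 15:
#'   `2^14` evaluations is sub-second).
#' @param config A [memetic_config()] for the heuristic path.
#' @param hard_cap Passed to [enumerate_optimum()].
#' @return An `ah_partition`.
#' @export
bipartition_dispatch <- function(graph, exact_threshold = 15L,
                                 config = memetic_config(),
                                 hard_cap = 22L) {
  stopifnot(inherits(graph, "ah_graph"))
  if (graph$n < 2L) stop("bipartitioning requires n >= 2")
  if (graph$n == 2L) {
    return(ah_partition(graph, stats::setNames(c(1L, 2L), graph$labels)))
  }
  if (graph$n <= exact_threshold) {
    enumerate_optimum(graph, hard_cap = hard_cap)$best_partition
  } else {
    evolve(graph, config)$partition
  }
}

#' Top-down hierarchical clustering by recursive bipartition
#'
#' Recursively splits the vertex set: each node's graph is bipartitioned
#' (see [bipartition_dispatch()]), the two sides become the node's
#' children on their induced subgraphs, and recursion stops at single
#' vertices. The side containing the lexicographically smallest label is
#' always the first child, so output is reproducible.
#'
#' @inheritParams bipartition_dispatch
#' @return An `ah_dendrogram`: a binary tree whose internal nodes carry
#'   `members` and `split_value` (the objective of the split made there)
#'   and whose leaves are single labels.
#' @examples
#' g <- planted_partition_graph(c(2, 2), 1, 10)$graph
#' d <- build_dendrogram(g)
#' newick_string(d, split_values = FALSE)
#' @export
build_dendrogram <- function(graph, exact_threshold = 15L,
                             config = memetic_config(),
                             hard_cap = 22L) {
  stopifnot(inherits(graph, "ah_graph"))
  if (graph$n < 1L) stop("empty graph")
  if (!is.null(config$rng_seed)) {
    set.seed(config$rng_seed)
    config$rng_seed <- NULL  # one master seed; inner calls share the stream
  }
  rec <- function(members) {
    if (length(members) == 1L) {
      return(list(members = members, split_value = NULL, children = NULL))
    }
    g <- subgraph(graph, members)
    part <- bipartition_dispatch(g, exact_threshold, config, hard_cap)
    s1 <- names(part$side)[part$side == 1L]
    s2 <- names(part$side)[part$side == 2L]
    if (min(s2) < min(s1)) { tmp <- s1; s1 <- s2; s2 <- tmp }
    list(members = members,
         split_value = part$breakdown$value,
         children = list(rec(s1), rec(s2)))
  }
  structure(list(root = rec(graph$labels), labels = graph$labels,
                 n_leaves = graph$n),
            class = "ah_dendrogram")
}

#' @export
print.ah_dendrogram <- function(x, ...) {
  cat("<ah_dendrogram> ", x$n_leaves, " leaves; root split value = ",
      if (is.null(x$root$split_value)) "NA" else format(x$root$split_value),
      "\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' Starting from the root, repeatedly expands the frontier node with the
#' largest split value until the frontier holds `num_clusters` sets.
#' Splits made on large, well-separated vertex sets carry large objective
#' values, so they are undone first.
#'
#' @param dendrogram An `ah_dendrogram`.
#' @param num_clusters Between 1 and the number of leaves.
#' @return A list of character vectors (the member sets), in tree order.
#' @export
cut_tree <- function(dendrogram, num_clusters) {
  stopifnot(inherits(dendrogram, "ah_dendrogram"))
  k <- as.integer(num_clusters)
  if (k < 1L || k > dendrogram$n_leaves) {
    stop("num_clusters must be between 1 and ", dendrogram$n_leaves)
  }
  frontier <- list(dendrogram$root)
  while (length(frontier) < k) {
    vals <- vapply(frontier, function(nd) {
      if (is.null(nd$children)) -Inf else nd$split_value
    }, 0)
    firsts <- vapply(frontier, function(nd) min(nd$members), "")
    pick <- order(-vals, firsts)[1L]
    frontier <- append(frontier[-pick], frontier[[pick]]$children,
                       after = pick - 1L)
  }
  lapply(frontier, function(nd) nd$members)
}

#' @describeIn cut_tree Cluster membership as a tibble (`label`, `cluster`).
#' @export
cluster_assignments <- function(dendrogram, num_clusters) {
  sets <- cut_tree(dendrogram, num_clusters)
  tibble::tibble(
    label = unlist(sets),
    cluster = rep(seq_along(sets), lengths(sets))
  )
}

#' Newick serialisation of a dendrogram
#'
#' Leaf labels are written verbatim (quoted if they contain reserved
#' characters); with `split_values = TRUE` each internal node is followed
#' by a bracketed comment carrying its split value.
#'
#' @param dendrogram An `ah_dendrogram`.
#' @param split_values Attach `[value]` comments to internal nodes.
#' @param digits Significant digits for split values.
#' @return A single Newick string ending in `";"`.
#' @export
newick_string <- function(dendrogram, split_values = TRUE, digits = 10L) {
  stopifnot(inherits(dendrogram, "ah_dendrogram"))
  rec <- function(nd) {
    if (is.null(nd$children)) return(newick_quote(nd$members))
    inner <- paste0("(", rec(nd$children[[1L]]), ",",
                    rec(nd$children[[2L]]), ")")
    if (split_values) {
      inner <- paste0(inner, "[", sprintf("%.*g", digits, nd$split_value), "]")
    }
    inner
  }
  paste0(rec(dendrogram$root), ";")
}

#' @describeIn newick_string Write the Newick string to a file.
#' @param path Output file path.
#' @export
write_newick <- function(dendrogram, path, split_values = TRUE,
                         digits = 10L) {
  writeLines(newick_string(dendrogram, split_values, digits), path)
  invisible(path)
}

newick_quote <- function(label) {
  if (grepl("[][(),:;'\"[:space:]]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

#' @describeIn build_dendrogram Node table: one row per node with `node`,
#'   `parent`, `leaf`, `label`, `n_members`, `split_value`.
#' @param x An `ah_dendrogram`.
#' @param ... Unused.
#' @export
tidy.ah_dendrogram <- function(x, ...) {
  rows <- list()
  id <- 0L
  rec <- function(nd, parent) {
    id <<- id + 1L
    me <- id
    rows[[me]] <<- tibble::tibble(
      node = me, parent = parent,
      leaf = is.null(nd$children),
      label = if (is.null(nd$children)) nd$members else NA_character_,
      n_members = length(nd$members),
      split_value = if (is.null(nd$split_value)) NA_real_ else nd$split_value
    )
    if (!is.null(nd$children)) for (ch in nd$children) rec(ch, me)
  }
  rec(x$root, NA_integer_)
  do.call(rbind, rows)
}

#' @describeIn build_dendrogram One-row summary of the tree.
#' @export
glance.ah_dendrogram <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(
    n_leaves = sum(nodes$leaf),
    n_internal = sum(!nodes$leaf),
    root_split_value = if (is.null(x$root$split_value)) NA_real_
                       else x$root$split_value
  )
}

#' @describeIn build_dendrogram Dendrogram sketch as a ggplot (uniform
#'   depth levels; split values are annotations, not branch lengths).
#' @param object An `ah_dendrogram`.
#' @export
autoplot.ah_dendrogram <- function(object, ...) {
  leaf_x <- stats::setNames(rep(NA_real_, object$n_leaves), character(0))
  next_x <- 0
  segs <- list()
  tips <- list()
  rec <- function(nd, depth) {
    if (is.null(nd$children)) {
      next_x <<- next_x + 1
      tips[[length(tips) + 1L]] <<- tibble::tibble(
        x = next_x, y = -depth, label = nd$members
      )
      return(next_x)
    }
    xs <- vapply(nd$children, rec, 0, depth = depth + 1)
    segs[[length(segs) + 1L]] <<- tibble::tibble(
      x = c(xs[1L], xs[1L], xs[2L]),
      xend = c(xs[2L], xs[1L], xs[2L]),
      y = c(-depth, -depth, -depth),
      yend = c(-depth, -depth - 1, -depth - 1)
    )
    mean(xs)
  }
  rec(object$root, 0)
  segs <- do.call(rbind, segs)
  tips <- do.call(rbind, tips)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = x, xend = xend,
                                       y = y, yend = yend)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = x, y = y, label = label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::theme_void()
}
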