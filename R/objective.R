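#' The arithmetic-harmonic cut objective
#'
#' Evaluates a two-sided vertex assignment on a distance graph. The
#' objective is the product of two terms: `cut_sum`, the total distance
#' over pairs with endpoints on opposite sides (large when the two clusters
#' are far apart), and `intra_recip`, the sum of reciprocal distances over
#' pairs on the same side (large when each cluster is internally tight).
#' Both terms are maximised jointly via `value = cut_sum * intra_recip`.
#' The product is invariant under uniform rescaling of all distances.
#'
#' A side with at most one vertex contributes nothing to `intra_recip`;
#' with `n = 2` the unique split therefore has value 0.
#'
#' @param graph An [ah_graph].
#' @param side Assignment of every vertex to side 1 or 2: a named vector
#'   (names = labels, values in `{1, 2}`), or a data frame with columns
#'   `label` and `side`.
#' @param allow_one_sided Permit an empty side (used internally for
#'   degenerate `n < 2` cases); by default an empty side is an error.
#' @return An `ah_breakdown`: list with `cut_sum`, `intra_recip`, `value`.
#' @examples
#' g <- planted_partition_graph(c(2, 2), d_within = 1, d_between = 10)$graph
#' ah_evaluate(g, c(a1 = 1, a2 = 1, b1 = 2, b2 = 2))
#' @export
ah_evaluate <- function(graph, side, allow_one_sided = FALSE) {
  s <- normalize_side(graph, side)
  if (!allow_one_sided && graph$n >= 2 && length(unique(s)) < 2L) {
    stop("both sides must be non-empty for n >= 2")
  }
  br <- cpp_evaluate(graph$w, s)
  new_breakdown(br)
}

new_breakdown <- function(br) {
  structure(list(cut_sum = br$cut_sum, intra_recip = br$intra_recip,
                 value = br$value),
            class = "ah_breakdown")
}

#' @export
print.ah_breakdown <- function(x, ...) {
  cat("<ah_breakdown> value = ", format(x$value),
      " (cut_sum = ", format(x$cut_sum),
      ", intra_recip = ", format(x$intra_recip), ")\n", sep = "")
  invisible(x)
}

#' @export
glance.ah_breakdown <- function(x, ...) {
  tibble::tibble(cut_sum = x$cut_sum, intra_recip = x$intra_recip,
                 value = x$value)
}

# Coerce the user-facing side representations to an integer vector in graph
# label order.
normalize_side <- function(graph, side) {
  if (is.data.frame(side)) {
    stopifnot(all(c("label", "side") %in% names(side)))
    s <- side$side
    names(s) <- as.character(side$label)
    side <- s
  }
  if (is.null(names(side))) {
    if (length(side) != graph$n) {
      stop("unnamed side vector must have length n = ", graph$n)
    }
    names(side) <- graph$labels
  }
  unknown <- setdiff(names(side), graph$labels)
  if (length(unknown)) {
    stop("unknown vertex label(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(graph$labels, names(side))
  if (length(missing)) {
    stop("side assignment missing for: ", paste(missing, collapse = ", "))
  }
  s <- as.integer(side[graph$labels])
  if (!all(s %in% c(1L, 2L))) stop("sides must be 1 or 2")
  s
}

#' Construct a bipartition with its cached objective breakdown
#'
#' @inheritParams ah_evaluate
#' @return An `ah_partition`: list with `side` (named integer vector over
#'   all labels), `breakdown` (an `ah_breakdown`) and `labels`.
#' @export
ah_partition <- function(graph, side) {
  s <- normalize_side(graph, side)
  if (graph$n >= 2 && length(unique(s)) < 2L) {
    stop("both sides must be non-empty for n >= 2")
  }
  br <- new_breakdown(cpp_evaluate(graph$w, s))
  names(s) <- graph$labels
  structure(list(side = s, breakdown = br, labels = graph$labels),
            class = "ah_partition")
}

#' @export
print.ah_partition <- function(x, ...) {
  n1 <- sum(x$side == 1L)
  cat("<ah_partition> ", n1, " | ", length(x$side) - n1,
      " vertices, value = ", format(x$breakdown$value), "\n", sep = "")
  invisible(x)
}

#' @describeIn ah_partition One row per vertex: `label`, `side`.
#' @param x An `ah_partition`.
#' @param ... Unused.
#' @export
tidy.ah_partition <- function(x, ...) {
  tibble::tibble(label = names(x$side), side = as.integer(x$side))
}

#' @describeIn ah_partition One-row summary with the objective breakdown.
#' @export
glance.ah_partition <- function(x, ...) {
  tibble::tibble(n = length(x$side),
                 n_side1 = sum(x$side == 1L),
                 n_side2 = sum(x$side == 2L),
                 cut_sum = x$breakdown$cut_sum,
                 intra_recip = x$breakdown$intra_recip,
                 value = x$breakdown$value)
}

#' Objective breakdown after flipping one vertex
#'
#' Computes, in time proportional to the vertex degree, the breakdown of
#' the partition obtained by moving `vertex` to the other side. The input
#' partition is not modified.
#'
#' @param graph An [ah_graph].
#' @param partition An `ah_partition` over `graph`.
#' @param vertex A vertex label.
#' @return An `ah_breakdown` for the flipped assignment.
#' @export
move_delta <- function(graph, partition, vertex) {
  stopifnot(inherits(partition, "ah_partition"))
  v <- match(vertex, graph$labels)
  if (is.na(v)) stop("unknown vertex label: ", vertex)
  s <- partition$side[graph$labels]
  if (graph$n >= 2 && sum(s == s[[v]]) == 1L) {
    stop("degenerate move: flipping '", vertex, "' would empty its side")
  }
  br <- cpp_move_delta(graph$w, as.integer(s), v - 1L,
                       partition$breakdown$cut_sum,
                       partition$breakdown$intra_recip)
  new_breakdown(br)
}

# Apply a flip and return the updated ah_partition (internal).
apply_move <- function(graph, partition, vertex) {
  br <- move_delta(graph, partition, vertex)
  s <- partition$side
  s[[vertex]] <- 3L - s[[vertex]]
  structure(list(side = s, breakdown = br, labels = partition$labels),
            class = "ah_partition")
}

#' Does a partition value meet a rational decision target?
#'
#' The decision form of the problem asks whether some bipartition reaches
#' at least `k / l` for two positive integers `k` and `l`. Comparison uses
#' a `1e-12` relative slack so that values computed in floating point at
#' the exact threshold count as meeting it.
#'
#' @param breakdown An `ah_breakdown` (or a bare numeric value).
#' @param k,l Positive integers encoding the threshold `k / l`.
#' @return `TRUE` iff `value >= k / l` (within slack).
#' @export
meets_target <- function(breakdown, k, l = 1L) {
  stopifnot(k >= 1, l >= 1, k == as.integer(k), l == as.integer(l))
  value <- if (inherits(breakdown, "ah_breakdown")) breakdown$value
           else as.numeric(breakdown)
  threshold <- k / l
  value >= threshold - 1e-12 * max(1, abs(threshold))
}
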