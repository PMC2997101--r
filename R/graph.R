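#' Build a distance graph from a square distance matrix
#'
#' Turns a labelled, symmetric distance matrix into the complete weighted
#' graph that every solver in the package consumes. Vertices are the row
#' labels; each unordered pair carries the corresponding distance as its
#' edge weight.
#'
#' Because the objective sums *reciprocals* of within-side distances, zero
#' distances (identical objects) are not representable: any off-diagonal
#' entry below `weight_floor` is clamped up to `weight_floor` with a
#' warning. Small asymmetries (below `tol`) are averaged away; larger ones
#' are an error reporting the worst offending pair.
#'
#' @param x A square numeric matrix with identical row and column names, or
#'   a data frame whose first column holds the labels (as written by
#'   [write_distance_matrix()]).
#' @param weight_floor Positive lower bound applied to every edge weight.
#' @param tol Tolerance for symmetry and zero-diagonal checks.
#' @return An object of class `ah_graph`: a list with elements `labels`,
#'   `n`, `w` (the `n x n` weight matrix, `NA` on the diagonal and for
#'   absent pairs) and `complete`.
#' @examples
#' m <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' g <- ah_graph(m)
#' g$w["a", "b"]
#' @seealso [ah_graph_from_edges()] for sparse (non-complete) graphs,
#'   [read_distance_matrix()] for file input.
#' @export
ah_graph <- function(x, weight_floor = 1e-9, tol = 1e-8) {
  stopifnot(is.numeric(weight_floor), length(weight_floor) == 1L,
            weight_floor > 0)
  if (is.data.frame(x)) {
    labels <- as.character(x[[1L]])
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- labels
  } else {
    m <- as.matrix(x)
    labels <- rownames(m)
    if (is.null(labels)) labels <- colnames(m)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(m)))
  }
  n <- nrow(m)
  if (ncol(m) != n) {
    stop("distance matrix must be square; got ", n, " x ", ncol(m))
  }
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("distance matrix contains missing values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative distance at (", labels[bad[1L]], ", ", labels[bad[2L]], ")")
  }
  asym <- abs(m - t(m))
  if (max(asym) > tol) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop("matrix not symmetric: worst violation ", format(max(asym)),
         " at (", labels[bad[1L]], ", ", labels[bad[2L]], ")")
  }
  if (max(abs(diag(m))) > tol) {
    bad <- which.max(abs(diag(m)))
    stop("diagonal must be zero; entry for ", labels[bad], " is ",
         format(diag(m)[bad]))
  }
  w <- (m + t(m)) / 2
  off <- row(w) != col(w)
  n_clamped <- sum(w[off] < weight_floor)
  if (n_clamped > 0L) {
    warning(n_clamped, " distance(s) below weight_floor clamped to ",
            format(weight_floor))
    w[off & w < weight_floor] <- weight_floor
  }
  diag(w) <- NA_real_
  dimnames(w) <- list(labels, labels)
  new_ah_graph(labels, w, complete = TRUE)
}

new_ah_graph <- function(labels, w, complete) {
  structure(
    list(labels = labels, n = length(labels), w = w, complete = complete),
    class = "ah_graph"
  )
}

#' Build a (possibly non-complete) distance graph from an edge table
#'
#' Pairs absent from `edges` contribute to neither objective term.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param labels Optional full vertex set (to include isolated vertices);
#'   defaults to the labels appearing in `edges`.
#' @inheritParams ah_graph
#' @return An `ah_graph`; `complete` is `TRUE` only if every pair is present.
#' @export
ah_graph_from_edges <- function(edges, labels = NULL, weight_floor = 1e-9) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  wt <- as.numeric(edges$weight)
  if (any(from == to)) stop("self-loops are not allowed")
  if (any(wt < 0)) stop("negative edge weight")
  if (is.null(labels)) labels <- sort(unique(c(from, to)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (!all(c(from, to) %in% labels)) stop("edge endpoint not in labels")
  n <- length(labels)
  w <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_along(from)) {
    prev <- w[from[i], to[i]]
    val <- max(wt[i], weight_floor)
    if (!is.na(prev) && abs(prev - val) > 1e-8) {
      stop("conflicting duplicate edge (", from[i], ", ", to[i], ")")
    }
    w[from[i], to[i]] <- val
    w[to[i], from[i]] <- val
  }
  if (any(wt < weight_floor)) {
    warning(sum(wt < weight_floor),
            " edge weight(s) below weight_floor clamped")
  }
  complete <- !anyNA(w[row(w) != col(w)])
  new_ah_graph(labels, w, complete = complete)
}

#' @export
print.ah_graph <- function(x, ...) {
  m <- sum(!is.na(x$w[upper.tri(x$w)]))
  cat("<ah_graph> ", x$n, " vertices, ", m, " edges",
      if (isTRUE(x$complete)) " (complete)" else "", "\n", sep = "")
  cat("labels: ", paste(head(x$labels, 6L), collapse = ", "),
      if (x$n > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Restrict a graph to a subset of its labels (induced subgraph).
subgraph <- function(graph, members) {
  idx <- match(members, graph$labels)
  stopifnot(!anyNA(idx))
  w <- graph$w[idx, idx, drop = FALSE]
  new_ah_graph(graph$labels[idx], w,
               complete = !anyNA(w[row(w) != col(w)]))
}

# Connected components over present edges; returns a list of index vectors.
graph_components <- function(graph) {
  n <- graph$n
  adj <- !is.na(graph$w)
  seen <- logical(n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Lexicographic rank of each label (1 = smallest); used for all
# deterministic tie-breaks.
lex_ranks <- function(labels) {
  as.integer(rank(labels, ties.method = "first"))
}
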