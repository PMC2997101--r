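#' Exact optimum by exhaustive enumeration
#'
#' Enumerates every non-trivial bipartition (the first label is fixed on
#' side 1; the objective is symmetric under swapping sides) and returns one
#' attaining the maximum. Enumeration walks assignments in gray-code order
#' so each step is an incremental one-vertex update; the winning
#' breakdown is recomputed from scratch before returning. Among
#' equal-valued optima the lexicographically smallest side-1 label set is
#' returned.
#'
#' @param graph An [ah_graph] with `2 <= n <= hard_cap`.
#' @param hard_cap Upper bound on `n` (the search examines
#'   `2^(n-1) - 1` partitions).
#' @return An `ah_exact`: list with `best_partition` (an `ah_partition`),
#'   `best_value` and `partitions_examined`.
#' @examples
#' g <- planted_partition_graph(c(2, 2), 1, 10)$graph
#' enumerate_optimum(g)$best_value  # 80
#' @export
enumerate_optimum <- function(graph, hard_cap = 22L) {
  stopifnot(inherits(graph, "ah_graph"))
  if (graph$n < 2L || graph$n > hard_cap) {
    stop("exact enumeration requires 2 <= n <= ", hard_cap,
         " (n = ", graph$n, "); use the memetic solver for larger graphs")
  }
  res <- cpp_enumerate(graph$w, lex_ranks(graph$labels))
  part <- ah_partition(graph, stats::setNames(res$side, graph$labels))
  structure(
    list(best_partition = part,
         best_value = part$breakdown$value,
         partitions_examined = res$examined),
    class = "ah_exact"
  )
}

#' @export
print.ah_exact <- function(x, ...) {
  cat("<ah_exact> best value ", format(x$best_value), " over ",
      format(x$partitions_examined, big.mark = ","),
      " partitions\n", sep = "")
  invisible(x)
}

#' @export
glance.ah_exact <- function(x, ...) {
  cbind(tibble::tibble(partitions_examined = x$partitions_examined),
        glance(x$best_partition))
}

#' Greedy-localisation decision procedure
#'
#' Decides whether any bipartition reaches the target value `k / l`. A
#' greedy solution is computed first; if it meets the target it is returned
#' as a "yes" certificate. Otherwise a failed greedy bounds the instance
#' (the basis of the fixed-parameter argument), and the procedure falls
#' back to exhaustive search for the exact answer.
#'
#' @inheritParams enumerate_optimum
#' @inheritParams meets_target
#' @return A list with `decision` (logical) and `certificate` (an
#'   `ah_partition` meeting the target, or `NULL` on "no").
#' @export
fpt_decide <- function(graph, k, l = 1L, hard_cap = 22L) {
  stopifnot(inherits(graph, "ah_graph"))
  if (graph$n >= 2L) {
    g <- greedy_partition(graph)
    if (meets_target(g$partition$breakdown, k, l)) {
      return(list(decision = TRUE, certificate = g$partition))
    }
  }
  if (graph$n > hard_cap) {
    stop("instance too large for exact fallback (n = ", graph$n, ")")
  }
  if (graph$n < 2L) {
    return(list(decision = FALSE, certificate = NULL))
  }
  opt <- enumerate_optimum(graph, hard_cap = hard_cap)
  if (meets_target(opt$best_partition$breakdown, k, l)) {
    list(decision = TRUE, certificate = opt$best_partition)
  } else {
    list(decision = FALSE, certificate = NULL)
  }
}
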