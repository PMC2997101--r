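#' Configuration for the memetic optimiser
#'
#' @param depth Number of levels in the complete ternary population tree
#'   (3 levels = 13 pocket/current nodes).
#' @param k_max Maximum neighbourhood order for the variable neighbourhood
#'   search (number of simultaneous vertex flips).
#' @param vns_samples Random k-subsets sampled per order for `k >= 2`
#'   (order 1 is scanned exhaustively).
#' @param stagnation_generations Generations without improvement of the
#'   best value before a diversity restart.
#' @param max_generations Total generations (the stop criterion).
#' @param rng_seed Optional integer seed for full reproducibility.
#' @param eps Absolute slack for strict-improvement comparisons, guarding
#'   against floating-point cycling.
#' @return A `memetic_config` list.
#' @export
memetic_config <- function(depth = 3L, k_max = 3L, vns_samples = 100L,
                           stagnation_generations = 20L,
                           max_generations = 200L, rng_seed = NULL,
                           eps = 1e-12) {
  stopifnot(depth >= 1, k_max >= 1, vns_samples >= 1,
            stagnation_generations >= 1, max_generations >= 1, eps >= 0)
  structure(list(depth = as.integer(depth), k_max = as.integer(k_max),
                 vns_samples = as.integer(vns_samples),
                 stagnation_generations = as.integer(stagnation_generations),
                 max_generations = as.integer(max_generations),
                 rng_seed = rng_seed, eps = eps),
            class = "memetic_config")
}

#' Differential greedy crossover
#'
#' Recombines two bipartitions. The child's side labels are first aligned
#' to the parent's (flipped if that increases agreement); vertices on which
#' both agree seed the offspring's sides; the disagreeing vertices are then
#' re-assigned by the randomized greedy loop. If alignment leaves a side's
#' seed empty, the heaviest edge among the unassigned vertices re-seeds it
#' (see the methods vignette for the exact rule).
#'
#' Uses the ambient RNG stream for greedy tie-breaking; seed the stream for
#' reproducibility.
#'
#' @param parent,child `ah_partition`s over the same graph.
#' @param graph The common [ah_graph].
#' @return The offspring `ah_partition`.
#' @export
crossover <- function(parent, child, graph) {
  p <- normalize_side(graph, partition_side(parent))
  c_ <- normalize_side(graph, partition_side(child))
  side <- xo_sides(graph, p, c_, lex_ranks(graph$labels))
  ah_partition(graph, stats::setNames(side, graph$labels))
}

# Integer-vector core of the crossover (no validation, no objects).
xo_sides <- function(graph, p, c_, lr) {
  agree <- sum(p == c_)
  if (graph$n - agree > agree) c_ <- 3L - c_  # align orientations
  side0 <- p
  side0[p != c_] <- 0L
  if (all(side0 != 0L)) return(p)
  for (s in c(1L, 2L)) {
    if (!any(side0 == s)) side0 <- reseed_side(graph, side0, s)
  }
  cpp_greedy_fill(graph$w, side0, lr, 1L, TRUE)$side
}

partition_side <- function(x) {
  if (inherits(x, "ah_partition")) x$side else x
}

# Re-seed an empty side s of a partial assignment: take the heaviest edge
# among unassigned vertices and move its endpoint with the larger total
# distance to the opposite seed onto side s (ties: lexicographic). With
# fewer than two unassigned vertices, or none sharing an edge, the single
# most distant unassigned vertex is used.
reseed_side <- function(graph, side0, s) {
  un <- which(side0 == 0L)
  opp <- which(side0 == (3L - s))
  lr <- lex_ranks(graph$labels)
  dist_to_opp <- function(v) {
    if (length(opp) == 0L) return(0)
    sum(graph$w[v, opp], na.rm = TRUE)
  }
  cand <- NULL
  if (length(un) >= 2L) {
    sub <- graph$w[un, un, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA_real_
    if (any(!is.na(sub))) {
      best <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)
      # deterministic among ties: lexicographic endpoint pair
      key <- order(pmin(lr[un[best[, 1L]]], lr[un[best[, 2L]]]),
                   pmax(lr[un[best[, 1L]]], lr[un[best[, 2L]]]))[1L]
      e <- c(un[best[key, 1L]], un[best[key, 2L]])
      d <- vapply(e, dist_to_opp, 0)
      cand <- if (d[1L] > d[2L]) e[1L]
              else if (d[2L] > d[1L]) e[2L]
              else e[which.min(lr[e])]
    }
  }
  if (is.null(cand)) {
    d <- vapply(un, dist_to_opp, 0)
    cand <- un[order(-d, lr[un])][1L]
  }
  side0[cand] <- s
  side0
}

#' Variable neighbourhood search
#'
#' First-improvement local search whose order-`k` neighbourhood flips the
#' side of exactly `k` vertices. Order 1 is scanned exhaustively with
#' incremental objective updates; orders `k >= 2` try `vns_samples` random
#' `k`-subsets. Any strict improvement moves the incumbent and resets
#' `k` to 1; the search stops when `k` exceeds `k_max`. Moves emptying a
#' side are never taken, and the returned value is never below the start.
#'
#' @param start An `ah_partition` to improve.
#' @param graph The [ah_graph] it lives on.
#' @param config A [memetic_config()].
#' @return The improved `ah_partition`.
#' @export
vns_search <- function(start, graph, config = memetic_config()) {
  s <- normalize_side(graph, partition_side(start))
  res <- cpp_vns(graph$w, s, config$k_max, config$vns_samples, config$eps)
  ah_partition(graph, stats::setNames(res$side, graph$labels))
}

#' Memetic optimisation of the arithmetic-harmonic cut
#'
#' Population-based search over bipartitions. The population is a complete
#' ternary tree of pocket/current solution pairs: the pocket holds the best
#' solution ever seen at a node, the current the working solution, and
#' every parent's pocket is at least as good as its children's. Each
#' generation crosses every parent's pocket with each child's current
#' (differential greedy crossover), improves the offspring by variable
#' neighbourhood search, and installs it as the child's new current;
#' currents overtake pockets when strictly better, and pocket swaps along
#' tree edges restore the hierarchy. After `stagnation_generations` without
#' improvement the best solution is kept and the rest of the population is
#' re-initialised from randomized greedy starts.
#'
#' @param graph An [ah_graph] with `n >= 3` (smaller instances belong to
#'   the exact solver).
#' @param config A [memetic_config()].
#' @param keep_population Also return the final population state (tibble
#'   `node`, `parent`, `pocket_value`, `current_value`), mainly for
#'   inspecting the tree hierarchy property.
#' @return An `ah_memetic`: list with `partition` (the root pocket), `log`
#'   (tibble with one row per generation: `generation`, `best_value`,
#'   `restarts`, `rng_digest`) and `restarts`.
#' @examples
#' g <- planted_partition_graph(c(2, 2), 1, 10)$graph
#' fit <- evolve(g, memetic_config(max_generations = 5, rng_seed = 1))
#' fit$partition$breakdown$value  # 80
#' @export
evolve <- function(graph, config = memetic_config(),
                   keep_population = FALSE) {
  stopifnot(inherits(graph, "ah_graph"))
  if (graph$n < 3L) {
    stop("memetic search requires n >= 3; use enumerate_optimum()")
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n_nodes <- (3L^config$depth - 1L) %/% 2L
  eps <- config$eps
  lr <- lex_ranks(graph$labels)
  W <- graph$w

  # population state as plain integer side vectors + cached values
  init_side <- function(deterministic) {
    greedy_raw(graph, randomized = !deterministic)$side
  }
  pocket <- vector("list", n_nodes)
  current <- vector("list", n_nodes)
  pv <- numeric(n_nodes)
  cv <- numeric(n_nodes)
  seed_all <- function(keep_root) {
    for (j in seq_len(n_nodes)) {
      if (keep_root && j == 1L) {
        current[[1L]] <<- pocket[[1L]]
        cv[1L] <<- pv[1L]
        next
      }
      s <- init_side(!keep_root && j == 1L)
      v <- cpp_evaluate(W, s)$value
      pocket[[j]] <<- s; current[[j]] <<- s
      pv[j] <<- v; cv[j] <<- v
    }
  }
  # Bubble better individuals up the ternary tree until every parent's
  # pocket is at least as good as its children's. Whole pocket/current
  # pairs move together so pocket >= current stays true at every node.
  fix_tree <- function() {
    repeat {
      changed <- FALSE
      for (j in seq_len(n_nodes)[-1L]) {
        par <- (j + 1L) %/% 3L
        if (pv[j] > pv[par] + eps) {
          tmp <- pocket[[par]]; pocket[[par]] <<- pocket[[j]]
          pocket[[j]] <<- tmp
          tmp <- current[[par]]; current[[par]] <<- current[[j]]
          current[[j]] <<- tmp
          tv <- pv[par]; pv[par] <<- pv[j]; pv[j] <<- tv
          tv <- cv[par]; cv[par] <<- cv[j]; cv[j] <<- tv
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  seed_all(keep_root = FALSE)
  fix_tree()

  best <- pv[1L]
  stagnation <- 0L
  restarts <- 0L
  log_best <- numeric(config$max_generations)
  log_restarts <- integer(config$max_generations)
  log_digest <- character(config$max_generations)

  for (gen in seq_len(config$max_generations)) {
    for (j in seq_len(n_nodes)[-1L]) {        # level order
      par <- (j + 1L) %/% 3L
      off <- xo_sides(graph, pocket[[par]], current[[j]], lr)
      res <- cpp_vns(W, off, config$k_max, config$vns_samples, eps)
      current[[j]] <- res$side
      cv[j] <- res$value
      if (cv[j] > pv[j] + eps) {
        pocket[[j]] <- current[[j]]
        pv[j] <- cv[j]
      }
    }
    fix_tree()

    if (pv[1L] > best + eps) {
      best <- pv[1L]
      stagnation <- 0L
    } else {
      stagnation <- stagnation + 1L
    }
    if (stagnation >= config$stagnation_generations &&
        gen < config$max_generations) {
      seed_all(keep_root = TRUE)
      fix_tree()
      restarts <- restarts + 1L
      stagnation <- 0L
    }
    log_best[gen] <- best
    log_restarts[gen] <- restarts
    log_digest[gen] <- rng_digest()
  }

  out <- structure(
    list(partition = ah_partition(graph,
                                  stats::setNames(pocket[[1L]],
                                                  graph$labels)),
         log = tibble::tibble(generation = seq_len(config$max_generations),
                              best_value = log_best,
                              restarts = log_restarts,
                              rng_digest = log_digest),
         restarts = restarts,
         config = config),
    class = "ah_memetic"
  )
  if (keep_population) {
    out$population <- tibble::tibble(
      node = seq_len(n_nodes),
      parent = c(NA_integer_, (seq_len(n_nodes)[-1L] + 1L) %/% 3L),
      pocket_value = pv,
      current_value = cv
    )
  }
  out
}

# Short printable digest of the RNG state for run logs.
rng_digest <- function() {
  s <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  sprintf("%08x", as.integer(sum(as.numeric(s) %% 65521) %% 2147483647))
}

#' @export
print.ah_memetic <- function(x, ...) {
  cat("<ah_memetic> best value = ", format(x$partition$breakdown$value),
      " after ", nrow(x$log), " generations (", x$restarts,
      " restart(s))\n", sep = "")
  invisible(x)
}

#' @describeIn evolve Per-generation run log as a tibble.
#' @param x An `ah_memetic`.
#' @param ... Unused.
#' @export
tidy.ah_memetic <- function(x, ...) x$log

#' @describeIn evolve One-row summary of the run.
#' @export
glance.ah_memetic <- function(x, ...) {
  tibble::tibble(best_value = x$partition$breakdown$value,
                 generations = nrow(x$log),
                 restarts = x$restarts,
                 n = length(x$partition$side))
}

#' @describeIn evolve Best objective value per generation.
#' @param object An `ah_memetic`.
#' @export
autoplot.ah_memetic <- function(object, ...) {
  ggplot2::ggplot(object$log,
                  ggplot2::aes(x = generation, y = best_value)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best objective value") +
    ggplot2::theme_minimal()
}
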