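#' Specification of the three-group synthetic expression generator
#'
#' Describes three disease subtypes drawn from multivariate normal
#' distributions with diagonal covariance `sigma^2 * I`, identical except
#' for their mean vectors: each group owns a disjoint block of
#' `n_signature` signature genes of which `n_down` are under-expressed
#' (mean `mu_down`) and `n_up` over-expressed (mean `mu_up`); all other
#' genes have mean zero. The default sizes (one predominant subtype, two
#' rarer ones) and the shared standard deviation mirror the structure of
#' large-sample subtype benchmarks; see the methods vignette.
#'
#' @param group_sizes Three positive integers (samples per group).
#' @param n_genes Total number of genes.
#' @param n_signature Signature genes per group (blocks are disjoint, so
#'   `3 * n_signature <= n_genes`).
#' @param n_up,n_down Over-/under-expressed split of each signature
#'   (`n_up + n_down == n_signature`).
#' @param mu_up,mu_down Mean shifts of the signature genes.
#' @param sigma Common standard deviation of every gene.
#' @param rng_seed Optional integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(group_sizes = c(30L, 15L, 15L), n_genes = 500L,
                           n_signature = 30L, n_up = 20L, n_down = 10L,
                           mu_up = 1, mu_down = -1, sigma = 0.5,
                           rng_seed = NULL) {
  if (length(group_sizes) != 3L || any(group_sizes < 1L)) {
    stop("group_sizes must be three positive integers")
  }
  if (n_up + n_down != n_signature) {
    stop("n_up + n_down must equal n_signature")
  }
  if (3L * n_signature > n_genes) {
    stop("signature blocks must be disjoint: need 3 * n_signature <= n_genes")
  }
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(group_sizes = as.integer(group_sizes),
                 n_genes = as.integer(n_genes),
                 n_signature = as.integer(n_signature),
                 n_up = as.integer(n_up), n_down = as.integer(n_down),
                 mu_up = mu_up, mu_down = mu_down, sigma = sigma,
                 rng_seed = rng_seed),
            class = "synthetic_spec")
}

#' Generate a synthetic three-subtype expression matrix
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `expression` (genes x samples matrix with gene and
#'   sample names) and `truth` (tibble `sample`, `group`).
#' @examples
#' sim <- generate_expression(synthetic_spec(rng_seed = 1))
#' dim(sim$expression)  # 500 x 60
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  n_samples <- sum(spec$group_sizes)
  mu <- matrix(0, spec$n_genes, 3L)
  for (g in 1:3) {
    block <- (g - 1L) * spec$n_signature + seq_len(spec$n_signature)
    mu[block[seq_len(spec$n_down)], g] <- spec$mu_down
    mu[block[spec$n_down + seq_len(spec$n_up)], g] <- spec$mu_up
  }
  group_of <- rep(1:3, spec$group_sizes)
  m <- matrix(stats::rnorm(spec$n_genes * n_samples, sd = spec$sigma),
              spec$n_genes, n_samples)
  m <- m + mu[, group_of]
  rownames(m) <- paste0("g", seq_len(spec$n_genes))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  list(expression = m,
       truth = tibble::tibble(sample = colnames(m),
                              group = paste0("G", group_of)))
}

#' Planted-partition distance graph
#'
#' Complete graph over groups of vertices: within-group pairs sit at
#' `d_within`, between-group pairs at `d_between` (a scalar, or a symmetric
#' group-by-group matrix for unequal separations), plus optional uniform
#' noise on `[-noise, +noise]`. The planted grouping is returned as truth.
#'
#' @param sizes Vector of group sizes (vertices are labelled `A1, A2, ...,
#'   B1, ...` by group).
#' @param d_within Positive within-group distance.
#' @param d_between Between-group distance: scalar or symmetric matrix
#'   (one row/column per group); must exceed `d_within`.
#' @param noise Half-width of the uniform noise; must keep all distances
#'   above `weight_floor`.
#' @param rng_seed Optional integer seed (only relevant for `noise > 0`).
#' @param weight_floor Passed through to the graph constructor.
#' @return A list with `graph` (an [ah_graph]) and `truth` (tibble
#'   `label`, `group`).
#' @examples
#' planted_partition_graph(c(2, 2), 1, 10)$graph
#' @export
planted_partition_graph <- function(sizes, d_within, d_between, noise = 0,
                                    rng_seed = NULL, weight_floor = 1e-9) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L), d_within > 0, noise >= 0)
  k <- length(sizes)
  if (is.matrix(d_between)) {
    stopifnot(nrow(d_between) == k, ncol(d_between) == k,
              isTRUE(all.equal(d_between, t(d_between))))
    db <- d_between
  } else {
    db <- matrix(d_between, k, k)
  }
  if (any(db[upper.tri(db)] <= d_within)) {
    stop("d_between must exceed d_within")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  group_of <- rep(seq_len(k), sizes)
  labels <- unlist(lapply(seq_len(k), function(g) {
    paste0(LETTERS[g], seq_len(sizes[g]))
  }))
  n <- length(labels)
  base <- matrix(d_within, n, n)
  for (g1 in seq_len(k)) {
    for (g2 in seq_len(k)) {
      if (g1 != g2) base[group_of == g1, group_of == g2] <- db[g1, g2]
    }
  }
  if (noise > 0) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::runif(n * (n - 1) / 2, -noise, noise)
    eps <- eps + t(eps)
    base <- base + eps
  }
  diag(base) <- 0
  dimnames(base) <- list(labels, labels)
  if (any(base[upper.tri(base)] < weight_floor)) {
    stop("noise drives some distances below weight_floor")
  }
  list(graph = ah_graph(base, weight_floor = weight_floor),
       truth = tibble::tibble(label = labels,
                              group = LETTERS[group_of]))
}

#' Random complete graph with i.i.d. uniform weights
#'
#' Test-instance generator for oracle-equivalence experiments.
#'
#' @param n Number of vertices (`>= 2`).
#' @param weight_low,weight_high Positive bounds of the uniform weight
#'   distribution.
#' @param rng_seed Optional integer seed.
#' @return An [ah_graph].
#' @export
random_weighted_graph <- function(n, weight_low = 1, weight_high = 10,
                                  rng_seed = NULL) {
  stopifnot(n >= 2L, weight_low > 0, weight_low <= weight_high)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  labels <- sprintf("v%02d", seq_len(n))
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, weight_low, weight_high)
  w <- w + t(w)
  dimnames(w) <- list(labels, labels)
  ah_graph(w)
}
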