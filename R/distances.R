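#' Correlation distance between samples of an expression matrix
#'
#' Computes the pairwise distance `d(x, y) = 1 - r(x, y)` between sample
#' columns, where `r` is by default the mean-centred (Pearson) correlation
#' of the two samples' gene vectors. Entries lie in `[0, 2]`: 0 for
#' perfectly correlated samples, 2 for perfectly anticorrelated ones. The
#' distance is invariant under per-sample affine transforms
#' `value -> a * value + b` with `a > 0`.
#'
#' The uncentred variant (`r = sum(xy) / sqrt(sum(x^2) sum(y^2))`, i.e.
#' cosine similarity) is offered because expression tooling historically
#' distinguishes the two; centred is the default.
#'
#' @param expr Numeric matrix, genes in rows and samples in columns
#'   (column names become sample labels), or a data frame whose first
#'   column holds gene labels (as written by [write_expression()]).
#' @param method `"centered"` (default) or `"uncentered"`.
#' @return Square symmetric distance matrix over samples with zero
#'   diagonal, ready for [ah_graph()].
#' @examples
#' m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(3, 2, 1))
#' correlation_distance(m)
#' @export
correlation_distance <- function(expr, method = c("centered", "uncentered")) {
  method <- match.arg(method)
  m <- as_expression_matrix(expr)
  if (nrow(m) < 2L) stop("need at least 2 genes")
  if (method == "centered") {
    v <- apply(m, 2L, stats::var)
    if (any(v == 0)) {
      stop("zero-variance sample(s): ",
           paste(colnames(m)[v == 0], collapse = ", "))
    }
    r <- stats::cor(m)
  } else {
    nrm <- sqrt(colSums(m^2))
    if (any(nrm == 0)) {
      stop("all-zero sample(s): ",
           paste(colnames(m)[nrm == 0], collapse = ", "))
    }
    r <- crossprod(sweep(m, 2L, nrm, "/"))
  }
  d <- 1 - r
  d <- pmin(pmax(d, 0), 2)  # trim float spill outside [0, 2]
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Accept a plain matrix (genes x samples) or the TSV-shaped data frame.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    genes <- as.character(expr[[1L]])
    m <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(m) <- genes
  } else {
    m <- as.matrix(expr)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  m
}
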