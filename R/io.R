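#' Read and write the package's file formats
#'
#' Distance matrices are square labelled tables (TSV by default, CSV when
#' the file ends in `.csv`): first row and first column carry labels, the
#' body is numeric and symmetric with a zero diagonal. Expression tables
#' are genes x samples with gene labels in the first column and sample
#' labels in the header. Partitions are two-column TSVs (`label`,
#' `side`); their objective breakdown travels in a JSON sidecar.
#'
#' @param path File path.
#' @return `read_distance_matrix()` and `read_expression()` return a
#'   labelled numeric matrix; `read_partition()` a named integer vector.
#' @name ahcut-io
NULL

io_sep <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

#' @rdname ahcut-io
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

#' @rdname ahcut-io
#' @param m Labelled numeric matrix.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = io_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ahcut-io
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = io_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_expression_matrix(df)
}

#' @rdname ahcut-io
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = io_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ahcut-io
#' @param partition An `ah_partition`.
#' @param json_path Optional path for the JSON objective record.
#' @export
write_partition <- function(partition, path, json_path = NULL) {
  stopifnot(inherits(partition, "ah_partition"))
  utils::write.table(tidy(partition), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(partition$breakdown[c("cut_sum", "intra_recip",
                                               "value")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname ahcut-io
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$side), as.character(df$label))
}

#' Run configuration for the command-line interface
#'
#' Bundles every tunable of the clustering pipeline with documented
#' defaults. `read_run_config()` loads a JSON file; unknown keys are
#' rejected.
#'
#' @param metric Distance for expression input: `"centered"` or
#'   `"uncentered"` correlation distance.
#' @param weight_floor Lower bound on edge weights (see [ah_graph()]).
#' @param exact_threshold Largest instance solved exactly
#'   (see [bipartition_dispatch()]).
#' @param max_partitions Largest cluster count written by [run_cluster()].
#' @param rng_seed Master seed; all randomness derives from it.
#' @inheritParams memetic_config
#' @return A `run_config` list.
#' @export
run_config <- function(metric = c("centered", "uncentered"),
                       weight_floor = 1e-9, exact_threshold = 15L,
                       max_partitions = 10L,
                       depth = 3L, k_max = 3L, vns_samples = 100L,
                       stagnation_generations = 20L, max_generations = 200L,
                       rng_seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(weight_floor > 0, exact_threshold >= 2, max_partitions >= 2)
  structure(list(metric = metric, weight_floor = weight_floor,
                 exact_threshold = as.integer(exact_threshold),
                 max_partitions = as.integer(max_partitions),
                 depth = as.integer(depth), k_max = as.integer(k_max),
                 vns_samples = as.integer(vns_samples),
                 stagnation_generations = as.integer(stagnation_generations),
                 max_generations = as.integer(max_generations),
                 rng_seed = rng_seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file of config overrides.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

as_memetic_config <- function(config) {
  memetic_config(depth = config$depth, k_max = config$k_max,
                 vns_samples = config$vns_samples,
                 stagnation_generations = config$stagnation_generations,
                 max_generations = config$max_generations,
                 rng_seed = NULL)
}

load_input_graph <- function(input, kind, config) {
  if (!file.exists(input)) stop("no such file: ", input)
  if (kind == "expression") {
    expr <- read_expression(input)
    d <- correlation_distance(expr, method = config$metric)
  } else {
    d <- read_distance_matrix(input)
  }
  ah_graph(d, weight_floor = config$weight_floor)
}

#' Cluster a dataset from the command line (or programmatically)
#'
#' Reads a distance matrix or expression table, builds the dendrogram by
#' recursive bipartition, and writes `tree.nwk` (Newick with split-value
#' comments), `cut_k<K>.tsv` cluster assignments for `K = 2 ..
#' min(n, max_partitions)`, and `run_log.jsonl`. Outputs are byte-identical
#' across reruns with the same seed.
#'
#' @param input Input file path.
#' @param kind `"distance"` or `"expression"`.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_cluster <- function(input, kind = c("distance", "expression"),
                        config = run_config(), out_dir = ".") {
  kind <- match.arg(kind)
  graph <- load_input_graph(input, kind, config)
  if (graph$n < 2L) stop("need at least 2 objects to cluster")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mc <- as_memetic_config(config)
  mc$rng_seed <- config$rng_seed
  dend <- build_dendrogram(graph, exact_threshold = config$exact_threshold,
                           config = mc)
  write_newick(dend, file.path(out_dir, "tree.nwk"))
  for (k in 2:min(graph$n, config$max_partitions)) {
    utils::write.table(cluster_assignments(dend, k),
                       file.path(out_dir, sprintf("cut_k%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log_file <- file.path(out_dir, "run_log.jsonl")
  nodes <- tidy(dend)
  con <- file(log_file, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(nodes))) {
    if (nodes$leaf[i]) next
    writeLines(jsonlite::toJSON(list(event = "split", node = nodes$node[i],
                                     n_members = nodes$n_members[i],
                                     split_value = nodes$split_value[i]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(out_dir)
}

#' Bipartition a dataset once and write the result
#'
#' Writes `partition.tsv` (label, side) and `objective.json` (cut_sum,
#' intra_recip, value).
#'
#' @inheritParams run_cluster
#' @return The output directory, invisibly.
#' @export
run_bipartition <- function(input, kind = c("distance", "expression"),
                            config = run_config(), out_dir = ".") {
  kind <- match.arg(kind)
  graph <- load_input_graph(input, kind, config)
  if (graph$n < 2L) stop("need at least 2 objects to bipartition")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mc <- as_memetic_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  part <- bipartition_dispatch(graph, exact_threshold = config$exact_threshold,
                               config = mc)
  write_partition(part, file.path(out_dir, "partition.tsv"),
                  file.path(out_dir, "objective.json"))
  invisible(out_dir)
}

#' Generate synthetic expression data and write it to disk
#'
#' Writes `expression.tsv` (genes x samples) and `truth.tsv` (sample,
#' group).
#'
#' @param spec A [synthetic_spec()], or the path of a JSON file with
#'   `synthetic_spec()` arguments.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(spec = synthetic_spec(), out_dir = ".") {
  if (is.character(spec)) {
    if (!file.exists(spec)) stop("no such file: ", spec)
    vals <- jsonlite::read_json(spec, simplifyVector = TRUE)
    unknown <- setdiff(names(vals), names(formals(synthetic_spec)))
    if (length(unknown)) {
      stop("unknown spec key(s): ", paste(unknown, collapse = ", "))
    }
    spec <- do.call(synthetic_spec, vals)
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_expression(spec)
  write_expression(sim$expression, file.path(out_dir, "expression.tsv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
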