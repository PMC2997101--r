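test_that("dispatch routes by instance size and solves each regime", {
  g <- planted_k4()
  p <- bipartition_dispatch(g)
  expect_identical(p$breakdown$value, 80)

  two <- ah_graph(matrix(c(0, 3, 3, 0), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(bipartition_dispatch(two)$breakdown$value, 0)

  g1 <- ah_graph(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_error(bipartition_dispatch(g1), "n >= 2")
})

test_that("the memetic path recovers a large planted two-group split", {
  pp <- planted_partition_graph(c(20, 20), d_within = 1, d_between = 10,
                                noise = 0.05, rng_seed = 4)
  set.seed(4)
  p <- bipartition_dispatch(pp$graph,
                            config = memetic_config(max_generations = 50))
  side_of_a <- p$side[pp$truth$label[pp$truth$group == "A"]]
  side_of_b <- p$side[pp$truth$label[pp$truth$group == "B"]]
  expect_equal(length(unique(side_of_a)), 1L)
  expect_equal(length(unique(side_of_b)), 1L)
  expect_false(side_of_a[[1]] == side_of_b[[1]])
})

test_that("dendrograms have exact leaf sets and oracle-checked splits", {
  g1 <- ah_graph(matrix(0, 1, 1, dimnames = list("a", "a")))
  d1 <- build_dendrogram(g1)
  expect_equal(d1$root$members, "a")
  expect_null(d1$root$children)

  g <- planted_k4()
  d <- build_dendrogram(g)
  expect_identical(d$root$split_value, 80)
  expect_equal(d$root$children[[1]]$members, c("A1", "A2"))
  expect_equal(d$root$children[[2]]$members, c("B1", "B2"))
  nodes <- tidy(d)
  expect_setequal(nodes$label[nodes$leaf], g$labels)
})

test_that("three-group fixture splits A first, then B from C", {
  fx <- three_group_graph()
  d <- build_dendrogram(fx$graph)
  root_sides <- lapply(d$root$children, function(nd) nd$members)
  a_members <- fx$truth$label[fx$truth$group == "A"]
  expect_true(setequal(root_sides[[1]], a_members))
  # verify the root split against the enumeration oracle
  opt <- enumerate_optimum(fx$graph)
  expect_true(setequal(
    names(opt$best_partition$side)[opt$best_partition$side == 1L],
    a_members))
  expect_true(rel_equal(d$root$split_value, opt$best_value))
  # the B|C node splits exactly into the two planted groups,
  # again oracle-checked on its induced subgraph
  bc <- d$root$children[[2]]
  sub <- ahcut:::subgraph(fx$graph, bc$members)
  sub_opt <- enumerate_optimum(sub)
  expect_true(rel_equal(bc$split_value, sub_opt$best_value))
  expect_true(setequal(bc$children[[1]]$members,
                       fx$truth$label[fx$truth$group == "B"]))
  expect_true(setequal(bc$children[[2]]$members,
                       fx$truth$label[fx$truth$group == "C"]))
})

test_that("induced subgraphs keep the original weights", {
  g <- random_weighted_graph(10, 1, 10, rng_seed = 13)
  sub <- ahcut:::subgraph(g, c("v02", "v05", "v09"))
  expect_identical(sub$w["v02", "v09"], g$w["v02", "v09"])
  expect_identical(sub$w["v05", "v02"], g$w["v02", "v05"])
})

test_that("cut_tree walks from one cluster down to singletons", {
  fx <- three_group_graph()
  d <- build_dendrogram(fx$graph)
  expect_equal(cut_tree(d, 1), list(fx$graph$labels))
  singles <- cut_tree(d, 12)
  expect_equal(lengths(singles), rep(1L, 12))
  expect_setequal(unlist(singles), fx$graph$labels)

  three <- cut_tree(d, 3)
  got <- lapply(three, sort)
  want <- split(fx$truth$label, fx$truth$group)
  expect_true(all(vapply(want, function(w) {
    any(vapply(got, identical, TRUE, y = sort(w)))
  }, TRUE)))

  # consecutive cuts differ by expanding exactly one set
  for (k in 1:11) {
    a <- cut_tree(d, k)
    b <- cut_tree(d, k + 1)
    kept <- sum(vapply(a, function(s) {
      any(vapply(b, identical, TRUE, y = s))
    }, TRUE))
    expect_equal(kept, k - 1)
  }
  expect_error(cut_tree(d, 0), "between")
  expect_error(cut_tree(d, 13), "between")
})

test_that("Newick export is well-formed and round-trips through ape", {
  skip_if_not_installed("ape")
  g <- planted_k4()
  d <- build_dendrogram(g)
  s <- newick_string(d)
  expect_match(s, "^\\(.*\\)\\[80\\];$")
  plain <- newick_string(d, split_values = FALSE)
  expect_identical(plain, "((A1,A2),(B1,B2));")
  tr <- ape::read.tree(text = plain)
  expect_setequal(tr$tip.label, g$labels)

  # labels with reserved characters get quoted
  m <- matrix(c(0, 2, 2, 0), 2, 2,
              dimnames = list(c("x y", "a:b"), c("x y", "a:b")))
  dq <- build_dendrogram(ah_graph(m))
  expect_match(newick_string(dq, split_values = FALSE), "'x y'", fixed = TRUE)
})

test_that("dendrogram construction is deterministic given a seed", {
  pp <- planted_partition_graph(c(9, 9), 1, 10, noise = 0.2, rng_seed = 6)
  d1 <- build_dendrogram(pp$graph, exact_threshold = 8,
                         config = memetic_config(max_generations = 10,
                                                 rng_seed = 99))
  d2 <- build_dendrogram(pp$graph, exact_threshold = 8,
                         config = memetic_config(max_generations = 10,
                                                 rng_seed = 99))
  expect_identical(newick_string(d1), newick_string(d2))
})
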