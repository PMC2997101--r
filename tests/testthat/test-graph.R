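test_that("graphs build from distance matrices and enforce the contract", {
  m <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g <- ah_graph(m)
  expect_s3_class(g, "ah_graph")
  expect_equal(g$n, 2L)
  expect_equal(g$w["a", "b"], 3)
  expect_true(g$complete)

  # identity read-through of the planted K4
  g4 <- planted_k4()
  expect_equal(g4$w["A1", "A2"], 1)
  expect_equal(g4$w["B1", "B2"], 1)
  expect_equal(g4$w["A1", "B2"], 10)
  expect_equal(sum(!is.na(g4$w[upper.tri(g4$w)])), 6L)

  # off-diagonal zero is clamped to the weight floor with a warning
  mz <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(gz <- ah_graph(mz, weight_floor = 1e-6), "clamped")
  expect_equal(gz$w["a", "b"], 1e-6)

  # small asymmetries are averaged, large ones rejected with a location
  ma <- m; ma["a", "b"] <- 3 + 1e-10
  expect_equal(ah_graph(ma)$w["a", "b"], 3 + 5e-11)
  mb <- m; mb["a", "b"] <- 4
  expect_error(ah_graph(mb), "not symmetric.*(a|b)")

  expect_error(ah_graph(matrix(0, 2, 3)), "square")
  mneg <- m; mneg["a", "b"] <- mneg["b", "a"] <- -1
  expect_error(ah_graph(mneg), "negative")
  mdiag <- m; diag(mdiag) <- 0.5
  expect_error(ah_graph(mdiag), "diagonal")
  mdup <- m; rownames(mdup) <- colnames(mdup) <- c("a", "a")
  expect_error(ah_graph(mdup), "duplicate")
})

test_that("edge-list graphs support absent pairs and reject bad input", {
  edges <- data.frame(from = c("a", "c"), to = c("b", "d"),
                      weight = c(2, 5))
  g <- ah_graph_from_edges(edges)
  expect_false(g$complete)
  expect_true(is.na(g$w["a", "c"]))
  expect_equal(g$w["c", "d"], 5)
  expect_error(ah_graph_from_edges(data.frame(from = "a", to = "a",
                                              weight = 1)),
               "self-loop")
})

test_that("objective evaluation matches hand-enumerated worked examples", {
  u <- uniform_k4()
  br <- ah_evaluate(u, c(a = 1, b = 2, c = 2, d = 2))
  expect_equal(br$cut_sum, 3)
  expect_equal(br$intra_recip, 3)
  expect_equal(br$value, 9)

  g <- planted_k4()
  br <- ah_evaluate(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  expect_identical(br$cut_sum, 40)
  expect_identical(br$intra_recip, 2)
  expect_identical(br$value, 80)

  # a side of size <= 1 contributes nothing to the reciprocal term
  two <- ah_graph(matrix(c(0, 3, 3, 0), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(ah_evaluate(two, c(x = 1, y = 2))$value, 0)

  expect_error(ah_evaluate(g, c(A1 = 1, A2 = 1, B1 = 2, ZZ = 2)), "unknown")
  expect_error(ah_evaluate(g, c(A1 = 1, A2 = 1, B1 = 2)), "missing")
  expect_error(ah_evaluate(g, c(A1 = 1, A2 = 1, B1 = 1, B2 = 1)),
               "non-empty")
})

test_that("objective is symmetric under side swap and scale invariant", {
  for (seed in 1:10) {
    g <- random_weighted_graph(8, 1, 10, rng_seed = seed)
    set.seed(seed)
    s <- sample(1:2, 8, replace = TRUE)
    if (length(unique(s)) == 1L) s[1] <- 3L - s[1]
    names(s) <- g$labels
    a <- ah_evaluate(g, s)
    b <- ah_evaluate(g, stats::setNames(3L - s, names(s)))
    expect_identical(a$value, b$value)  # exact symmetry

    for (c_ in c(0.1, 1, 7.3)) {
      gs <- g
      gs$w <- g$w * c_
      sc <- ah_evaluate(gs, s)
      expect_true(rel_equal(sc$cut_sum, a$cut_sum * c_))
      expect_true(rel_equal(sc$intra_recip, a$intra_recip / c_))
      expect_true(rel_equal(sc$value, a$value))
    }
  }
})

test_that("incremental move evaluation agrees with full recomputation", {
  set.seed(11)
  for (rep in 1:250) {
    n <- sample(4:12, 1)
    g <- random_weighted_graph(n, 1, 10, rng_seed = 5000 + rep)
    s <- sample(1:2, n, replace = TRUE)
    if (length(unique(s)) == 1L) s[1] <- 3L - s[1]
    names(s) <- g$labels
    p <- ah_partition(g, s)
    movable <- names(s)[s %in% as.integer(names(table(s))[table(s) > 1])]
    v <- sample(movable, 1)
    inc <- move_delta(g, p, v)
    s2 <- s; s2[[v]] <- 3L - s2[[v]]
    full <- oracle_evaluate(g, s2)
    expect_true(rel_equal(inc$value, full$value))
    expect_true(rel_equal(inc$cut_sum, full$cut_sum))
    expect_true(rel_equal(inc$intra_recip, full$intra_recip))
  }
})

test_that("flipping a vertex twice restores the original breakdown", {
  g <- planted_k4()
  p <- ah_partition(g, c(A1 = 1, A2 = 2, B1 = 1, B2 = 2))
  # worked example: flip B1 from the mixed split
  expect_equal(p$breakdown$value, 4.4)
  expect_equal(move_delta(g, p, "B1")$value, 25.2)
  p2 <- ahcut:::apply_move(g, p, "B1")
  p3 <- ahcut:::apply_move(g, p2, "B1")
  expect_true(rel_equal(p3$breakdown$value, p$breakdown$value))
  expect_identical(p3$side, p$side)

  one_side <- ah_partition(g, c(A1 = 1, A2 = 2, B1 = 2, B2 = 2))
  expect_error(move_delta(g, one_side, "A1"), "degenerate")
})

test_that("increasing a cut edge raises cut_sum and leaves intra alone", {
  g <- random_weighted_graph(6, 1, 10, rng_seed = 3)
  s <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), g$labels)
  before <- ah_evaluate(g, s)
  g$w[1, 4] <- g$w[4, 1] <- g$w[1, 4] + 0.7
  after <- ah_evaluate(g, s)
  expect_gt(after$cut_sum, before$cut_sum)
  expect_identical(after$intra_recip, before$intra_recip)
})

test_that("decision targets compare as the rational k / l", {
  expect_true(meets_target(9, 9, 1))
  expect_false(meets_target(9, 10, 1))
  expect_false(meets_target(80, 161, 2))  # 80 < 80.5
  g <- planted_k4()
  br <- ah_evaluate(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  expect_true(meets_target(br, 160, 2))
  expect_error(meets_target(9, 0, 1))
})

test_that("partitions carry tidy and glance views", {
  g <- planted_k4()
  p <- ah_partition(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  td <- tidy(p)
  expect_equal(td$label, g$labels)
  expect_equal(td$side, c(1L, 1L, 2L, 2L))
  gl <- glance(p)
  expect_equal(gl$value, 80)
  expect_equal(gl$n_side1, 2L)
})
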