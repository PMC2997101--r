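test_that("crossover of identical parents is the identity", {
  g <- planted_k4()
  p <- ah_partition(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  set.seed(1)
  off <- crossover(p, p, g)
  expect_identical(off$side, p$side)
})

test_that("crossover aligns inverted orientations before recombining", {
  g <- random_weighted_graph(8, 1, 10, rng_seed = 2)
  set.seed(2)
  s <- stats::setNames(sample(1:2, 8, replace = TRUE), g$labels)
  s[1] <- 1L; s[2] <- 2L
  p <- ah_partition(g, s)
  q <- ah_partition(g, stats::setNames(3L - s, names(s)))
  off <- crossover(p, q, g)
  expect_identical(off$side, p$side)
})

test_that("crossover seeds with agreements and greedily re-fills the rest", {
  g <- planted_k4()
  parent <- ah_partition(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  child <- ah_partition(g, c(A1 = 1, A2 = 2, B1 = 2, B2 = 1))
  # agreements: A1 on side 1, B1 on side 2; A2/B2 re-assigned greedily,
  # which must rebuild the planted split (hand-checked, enumeration-optimal)
  for (seed in 1:5) {
    set.seed(seed)
    off <- crossover(parent, child, g)
    expect_identical(off$breakdown$value, 80)
    expect_identical(off$side, parent$side)
  }
})

test_that("crossover rejects mismatched vertex sets", {
  g <- planted_k4()
  h <- uniform_k4()
  p <- ah_partition(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  q <- ah_partition(h, c(a = 1, b = 1, c = 2, d = 2))
  expect_error(crossover(p, q, g), "unknown")
})

test_that("VNS keeps optima and climbs out of poor starts", {
  g <- planted_k4()
  cfg <- memetic_config(k_max = 2)
  opt <- ah_partition(g, c(A1 = 1, A2 = 1, B1 = 2, B2 = 2))
  set.seed(1)
  expect_identical(vns_search(opt, g, cfg)$breakdown$value, 80)

  mixed <- ah_partition(g, c(A1 = 1, B1 = 1, A2 = 2, B2 = 2))
  expect_equal(mixed$breakdown$value, 4.4)
  set.seed(1)
  expect_identical(vns_search(mixed, g, cfg)$breakdown$value, 80)

  u <- uniform_k4()
  start <- ah_partition(u, c(a = 1, b = 1, c = 2, d = 2))
  expect_equal(start$breakdown$value, 8)
  set.seed(1)
  expect_identical(vns_search(start, u, memetic_config())$breakdown$value, 9)
})

test_that("VNS never returns a worse partition", {
  for (rep in 1:20) {
    g <- random_weighted_graph(10, 1, 10, rng_seed = 400 + rep)
    set.seed(rep)
    s <- stats::setNames(sample(1:2, 10, replace = TRUE), g$labels)
    if (length(unique(s)) == 1L) s[1] <- 3L - s[1]
    start <- ah_partition(g, s)
    out <- vns_search(start, g, memetic_config())
    expect_gte(out$breakdown$value, start$breakdown$value)
    expect_true(all(table(out$side) >= 1))
  }
})

test_that("the memetic solver is exact on the planted K4", {
  g <- planted_k4()
  for (seed in c(1, 7, 42)) {
    fit <- evolve(g, memetic_config(max_generations = 10, rng_seed = seed))
    expect_identical(fit$partition$breakdown$value, 80)
  }
})

test_that("evolve is reproducible and its run log is monotone", {
  g <- random_weighted_graph(12, 1, 10, rng_seed = 8)
  cfg <- memetic_config(max_generations = 30, rng_seed = 123)
  a <- evolve(g, cfg)
  b <- evolve(g, cfg)
  expect_identical(a$log, b$log)
  expect_identical(a$partition$side, b$partition$side)
  expect_true(all(diff(a$log$best_value) >= 0))
  expect_equal(nrow(a$log), 30L)
})

test_that("population keeps pocket >= current and the tree hierarchy", {
  g <- random_weighted_graph(14, 1, 10, rng_seed = 9)
  fit <- evolve(g, memetic_config(max_generations = 15, rng_seed = 5),
                keep_population = TRUE)
  pop <- fit$population
  expect_equal(nrow(pop), 13L)
  expect_true(all(pop$pocket_value >= pop$current_value - 1e-9))
  inner <- pop[!is.na(pop$parent), ]
  expect_true(all(pop$pocket_value[inner$parent] >=
                    inner$pocket_value - 1e-9))
  # root pocket is the best pocket and is what evolve returns
  expect_equal(max(pop$pocket_value), pop$pocket_value[1])
  expect_equal(fit$partition$breakdown$value, pop$pocket_value[1])
})

test_that("evolve never falls below the deterministic greedy start", {
  for (rep in 1:10) {
    g <- random_weighted_graph(sample(6:12, 1), 1, 10, rng_seed = 600 + rep)
    gv <- greedy_partition(g)$partition$breakdown$value
    fit <- evolve(g, memetic_config(max_generations = 10,
                                    rng_seed = 700 + rep))
    expect_gte(fit$partition$breakdown$value, gv * (1 - 1e-12))
  }
})

test_that("evolve matches the enumeration optimum on small instances", {
  for (rep in 1:10) {
    g <- random_weighted_graph(sample(5:9, 1), 1, 10, rng_seed = 800 + rep)
    opt <- enumerate_optimum(g)$best_value
    fit <- evolve(g, memetic_config(rng_seed = 900 + rep))
    expect_true(rel_equal(fit$partition$breakdown$value, opt))
  }
})

test_that("evolve rejects degenerate instances and validates config", {
  two <- ah_graph(matrix(c(0, 3, 3, 0), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_error(evolve(two), "n >= 3")
  expect_error(memetic_config(k_max = 0))
  expect_error(memetic_config(depth = 0))
})
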