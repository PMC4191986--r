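test_that("generator configuration is validated", {
  expect_error(generator_config(n_events = 0), "n_events")
  expect_error(generator_config(n_trees = 5, n_events = 3), "n_trees")
  expect_error(generator_config(depth_cap = 0), "depth_cap")
  expect_error(generator_config(prob_range = c(0.9, 0.1)), "prob_range")
  expect_error(generator_config(prob_range = c(0, 0.9)), "prob_range")
  cfg <- generator_config()
  expect_identical(cfg$depth_cap, 5L)  # ceiling(log2(20))
})

test_that("random trees are reproducible, depth-capped and well formed", {
  cfg <- generator_config(n_events = 1, seed = 1)
  f1 <- random_tree(cfg)
  expect_identical(unname(f1$parent), ROOT)

  cfg2 <- generator_config(n_events = 15, seed = 99)
  fa <- random_tree(cfg2)
  fb <- random_tree(cfg2)
  expect_true(same_forest(fa, fb))
  expect_identical(fa$edge_prob, fb$edge_prob)

  # depth never exceeds the cap; edge probs in (0,1]; child rarer than parent
  set.seed(300)
  for (i in 1:400) {
    cfg3 <- generator_config(n_events = 20, depth_cap = 4)
    f <- random_tree(cfg3)
    expect_true(validate_forest(f) $root == ROOT)
    expect_lte(max(forest_depths(f)), 4L)
    expect_true(all(f$edge_prob > 0 & f$edge_prob <= 1))
    marg <- vapply(f$events, function(e)
      prod(f$edge_prob[c(e, forest_ancestors(f, e))]), numeric(1))
    expect_true(all(marg >= 0.05 - 1e-12 & marg <= 0.95 + 1e-12))
  }

  # forests get the requested number of components
  cfgf <- generator_config(n_events = 12, n_trees = 3, seed = 5)
  ff <- random_tree(cfgf)
  expect_identical(length(forest_children(ff, ROOT)), 3L)
})

test_that("sampling follows the exact tree-induced distribution", {
  set.seed(301)
  chain <- chain_forest(c(0.8, 0.5), labels = c("a", "b"))
  g <- sample_tree_distribution(chain, 100000)
  x <- unclass(g)
  emp <- c(none = mean(x[, "a"] == 0),
           a = mean(x[, "a"] == 1 & x[, "b"] == 0),
           ab = mean(x[, "a"] == 1 & x[, "b"] == 1))
  expect_equal(unname(emp), c(0.2, 0.4, 0.4), tolerance = 0.015)
  # impossible outcome: b without a never occurs
  expect_identical(sum(x[, "b"] == 1 & x[, "a"] == 0), 0L)

  # all edge probabilities one -> every event in every sample
  f1 <- chain_forest(c(1, 1))
  g1 <- sample_tree_distribution(f1, 50)
  expect_true(all(unclass(g1) == 1L))
})

test_that("star roots give independent children with their edge marginals", {
  set.seed(302)
  star <- progression_forest(c(a = ROOT, b = ROOT, c = ROOT),
                             edge_prob = c(a = 0.6, b = 0.3, c = 0.15))
  g <- sample_tree_distribution(star, 100000)
  x <- unclass(g)
  expect_equal(unname(colMeans(x)), c(0.6, 0.3, 0.15), tolerance = 0.01)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    pj <- mean(x[, pair[1]] & x[, pair[2]])
    expect_lt(abs(pj - mean(x[, pair[1]]) * mean(x[, pair[2]])), 0.01)
  }
})

test_that("child marginals never exceed parent marginals at large n", {
  set.seed(303)
  cfg <- generator_config(n_events = 12, seed = 17)
  f <- random_tree(cfg)
  g <- sample_tree_distribution(f, 100000)
  cm <- colMeans(unclass(g))
  for (e in f$events) {
    u <- f$parent[[e]]
    if (u != ROOT)
      expect_lte(cm[[e]], cm[[u]] + 0.01)
  }
})

test_that("uniform noise flips entries at rate nu/2 in both directions", {
  set.seed(304)
  g0 <- genotype_matrix(matrix(0L, 1000, 20))
  expect_identical(apply_noise(g0, noise_spec("uniform", nu = 0))[, ],
                   g0[, ])
  gn <- apply_noise(g0, noise_spec("uniform", nu = 0.1))
  ones <- sum(unclass(gn))
  # binomial(20000, 0.05): mean 1000, sd ~ 30.8; allow 3 sigma
  expect_lt(abs(ones - 1000), 3 * sqrt(20000 * 0.05 * 0.95))

  # asymmetric limits
  g1 <- genotype_matrix(matrix(1L, 50, 4))
  ga <- apply_noise(g1, noise_spec("asymmetric", eps_plus = 0, eps_minus = 1))
  expect_true(all(unclass(ga) == 0L))

  # uniform nu matches asymmetric eps = nu/2 in distribution: flip counts
  # in each direction agree with the common binomial law and between modes
  set.seed(305)
  half <- genotype_matrix(cbind(matrix(0L, 1000, 10), matrix(1L, 1000, 10)))
  flips <- function(noisy) {
    d <- unclass(noisy) - unclass(half)
    c(up = sum(d == 1L), down = sum(d == -1L))
  }
  fu <- flips(apply_noise(half, noise_spec("uniform", nu = 0.2)))
  fa <- flips(apply_noise(half, noise_spec("asymmetric", eps_plus = 0.1,
                                           eps_minus = 0.1)))
  sd_bin <- sqrt(10000 * 0.1 * 0.9)
  for (v in c(fu, fa))
    expect_lt(abs(v - 1000), 4.5 * sd_bin)
  tab <- rbind(c(fu[["up"]], 10000 - fu[["up"]], fu[["down"]], 10000 - fu[["down"]]),
               c(fa[["up"]], 10000 - fa[["up"]], fa[["down"]], 10000 - fa[["down"]]))
  expect_gt(stats::chisq.test(tab)$p.value, 1e-4)
})

test_that("validity-constrained sampling enforces the algebraic requirements", {
  set.seed(306)
  # an event with tiny marginal would usually be unobserved at n = 30
  f <- chain_forest(c(0.5, 0.08), labels = c("u", "v"))
  for (i in 1:20) {
    g <- sample_valid_dataset(f, 30)
    cs <- colSums(unclass(g))
    expect_true(all(cs > 0 & cs < 30))
    expect_identical(anyDuplicated(t(unclass(g))), 0L)
  }
})

test_that("simulation round-trips through the truth sidecar", {
  cfg <- generator_config(n_events = 6, n_samples = 40, seed = 8)
  sim <- simulate_dataset(cfg)
  pre <- withr::local_tempfile()
  write_simulation(sim, pre, seed = 8)
  g2 <- read_genotypes(paste0(pre, ".tsv"))
  expect_identical(unclass(g2)[, ], unclass(sim$genotypes)[, ])
  t2 <- read_simulation_truth(paste0(pre, ".truth.json"))
  expect_true(same_forest(sim$forest, t2))
  expect_equal(t2$edge_prob, sim$forest$edge_prob)
})
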