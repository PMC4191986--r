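test_that("empirical probabilities are exact count ratios on the toy data", {
  p <- toy_tables()
  expect_identical(p$m, 4L)
  expect_equal(p$marginal[["a"]], 0.75)
  expect_equal(p$marginal[["b"]], 0.5)
  expect_equal(p$joint["a", "b"], 0.5)
  # symmetry and diagonal identity
  expect_equal(p$joint["a", "b"], p$joint["b", "a"])
  expect_equal(p$joint["a", "a"], p$marginal[["a"]])
  # root bookkeeping
  expect_equal(p$marginal[[ROOT]], 1)
  expect_equal(p$joint[ROOT, "b"], p$marginal[["b"]])
  # Frechet bounds on random matrices
  set.seed(1)
  for (i in 1:20) {
    x <- matrix(rbinom(60, 1, runif(1, 0.2, 0.8)), nrow = 12)
    g <- try(genotype_matrix(x), silent = TRUE)
    pp <- try(estimate_probabilities(g), silent = TRUE)
    if (inherits(pp, "try-error")) next
    for (a in pp$events) for (b in pp$events) {
      lo <- max(0, pp$marginal[[a]] + pp$marginal[[b]] - 1)
      hi <- min(pp$marginal[[a]], pp$marginal[[b]])
      expect_gte(pp$joint[a, b], lo - 1e-12)
      expect_lte(pp$joint[a, b], hi + 1e-12)
    }
  }
})

test_that("conditional probabilities match direct counting", {
  p <- toy_tables()
  expect_equal(conditional_probability(p, "b", "a"), 2 / 3)
  expect_equal(conditional_probability(p, "b", "a", negated = TRUE), 0)
  expect_equal(conditional_probability(p, "a", "b"), 1)
  # independence: P(b|a) = P(b|~a)
  x <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), ncol = 2)
  pi <- estimate_probabilities(genotype_matrix(x, events = c("a", "b")))
  expect_equal(conditional_probability(pi, "b", "a"),
               conditional_probability(pi, "b", "a", negated = TRUE))
})

test_that("prima facie causation needs probability raising and priority", {
  p <- toy_tables()
  expect_true(prima_facie(p, "a", "b"))   # 2/3 > 0 and 0.75 > 0.5
  expect_false(prima_facie(p, "b", "a"))  # temporal priority fails
  # independent events fail the strict raising clause
  x <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), ncol = 2)
  pi <- estimate_probabilities(genotype_matrix(x, events = c("a", "b")))
  expect_false(prima_facie(pi, "a", "b"))
  expect_false(prima_facie(pi, "b", "a"))
  expect_error(prima_facie(p, "a", "a"), "equal events")
  expect_error(prima_facie(p, ROOT, "b"), "root")
})

test_that("alpha and beta reproduce the derived toy values and limits", {
  p <- toy_tables()
  expect_equal(pr_alpha(p, "a", "b"), 1)
  expect_equal(pr_alpha(p, "b", "a"), (1 - 0.5) / (1 + 0.5))
  expect_equal(pr_beta(p, "a", "b"), (0.5 - 0.375) / (0.5 + 0.375))
  expect_equal(pr_beta(p, "a", "b"), pr_beta(p, "b", "a"))
  # directionality consistent with P(a) > P(b)
  expect_gt(pr_alpha(p, "a", "b"), pr_alpha(p, "b", "a"))
  # independence -> both zero
  x <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), ncol = 2)
  pi <- estimate_probabilities(genotype_matrix(x, events = c("a", "b")))
  expect_equal(pr_alpha(pi, "a", "b"), 0)
  expect_equal(pr_beta(pi, "a", "b"), 0)
  # mutual exclusivity -> beta at its -1 limit
  x2 <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0), ncol = 2)
  pe <- estimate_probabilities(genotype_matrix(x2, events = c("a", "b")))
  expect_equal(pr_beta(pe, "a", "b"), -1)
})

test_that("the shrinkage-like estimator is the exact convex combination", {
  p <- toy_tables()
  est <- shrinkage_estimator(p, 0.5)
  expect_equal(est$m["a", "b"], 0.5 * 1 + 0.5 * (1 / 7))
  expect_identical(shrinkage_estimator(p, 0)$m, shrinkage_estimator(p, 0)$alpha)
  expect_identical(shrinkage_estimator(p, 1)$m, shrinkage_estimator(p, 1)$beta)
  expect_true(all(is.na(diag(est$m))))
  expect_error(shrinkage_estimator(p, 1.5), "lambda")
  expect_error(shrinkage_estimator(p, -0.1), "lambda")
  # affine in lambda
  l1 <- shrinkage_estimator(p, 0.2)$m["a", "b"]
  l2 <- shrinkage_estimator(p, 0.8)$m["a", "b"]
  lm <- shrinkage_estimator(p, 0.5)$m["a", "b"]
  expect_equal(lm, (l1 + l2) / 2)
})

test_that("matrix estimator agrees with scalar definitions to 1e-12", {
  set.seed(42)
  for (rep in 1:10) {
    x <- matrix(rbinom(10 * 6, 1, runif(6, 0.2, 0.8)), ncol = 6, byrow = TRUE)
    g <- try(drop_degenerate_events(genotype_matrix(x), quiet = TRUE),
             silent = TRUE)
    if (inherits(g, "try-error") || ncol(g) < 2L) next
    p <- estimate_probabilities(adjoin_root(g), root = ROOT)
    est <- shrinkage_estimator(p, 0.37)
    for (a in est$events) for (b in est$events) {
      if (a == b) next
      expect_equal(est$alpha[a, b], pr_alpha(p, a, b), tolerance = 1e-12)
      expect_equal(est$beta[a, b], pr_beta(p, a, b), tolerance = 1e-12)
      expect_equal(est$m[a, b],
                   0.63 * pr_alpha(p, a, b) + 0.37 * pr_beta(p, a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("oncotree weights match the closed form, root included", {
  p <- toy_tables()
  expect_equal(oncotree_weight(p, "a", "b"), log(0.6 * (4 / 3)))
  expect_equal(oncotree_weight(p, "a", "b"), log(0.8))
  # root -> b reduces to -log(1 + P(b))
  expect_equal(oncotree_weight(p, ROOT, "b"), -log(1 + 0.5))
  expect_equal(oncotree_weight(p, ROOT, "a"), -log(1 + 0.75))
  # symmetric independent pair: weight log(1/2)
  x <- matrix(c(1, 1, 0, 0, 1, 0, 1, 0), ncol = 2)
  pi <- estimate_probabilities(adjoin_root(genotype_matrix(x, events = c("a", "b"))),
                               root = ROOT)
  expect_equal(oncotree_weight(pi, "a", "b"), log(1 / 2))
  # zero joint -> -Inf sentinel
  x2 <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0), ncol = 2)
  pe <- estimate_probabilities(adjoin_root(genotype_matrix(x2, events = c("a", "b"))),
                               root = ROOT)
  expect_identical(oncotree_weight(pe, "a", "b"), -Inf)
  W <- oncotree_weight_matrix(p)
  expect_identical(rownames(W), c(ROOT, "a", "b"))
  expect_equal(W["a", "b"], log(0.8))
  expect_true(is.na(W["a", "a"]))
})

test_that("estimator matrices export as labelled TSV", {
  p <- toy_tables()
  est <- shrinkage_estimator(p, 0.5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_estimator(est, tf)
  df <- read.delim(tf, check.names = FALSE)
  expect_identical(df$cause, c("a", "b"))
  expect_equal(df[df$cause == "a", "b"], est$m["a", "b"])
})
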