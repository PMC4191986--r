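#' Configuration for the random progression-tree generator
#'
#' Defaults mirror the simulation study conditions used throughout the
#' package: 20 events per tree, a single progression path (`n_trees = 1`;
#' use more components for forests), depth capped at
#' `ceiling(log2(n_events))` (favouring paths over wide branches, which are
#' harder to reconstruct), and event observation probabilities drawn
#' uniformly from (0.05, 0.95).
#'
#' @param n_events number of events.
#' @param n_trees number of independent progression paths (children of the
#'   root).
#' @param depth_cap maximum depth of any event (edges from the root).
#' @param prob_range interval from which the events' observation (marginal)
#'   probabilities are drawn uniformly; must satisfy `0 < lo < hi <= 1`.
#'   Edge probabilities are the child/parent marginal ratios.
#' @param n_samples default number of samples for [simulate_dataset()].
#' @param seed optional integer seed applied by the generator functions.
#' @export
generator_config <- function(n_events = 20L, n_trees = 1L,
                             depth_cap = NULL,
                             prob_range = c(0.05, 0.95),
                             n_samples = 100L, seed = NULL) {
  n_events <- as.integer(n_events)
  n_trees <- as.integer(n_trees)
  if (is.null(depth_cap))
    depth_cap <- max(1L, ceiling(log2(n_events)))
  depth_cap <- as.integer(depth_cap)
  if (n_events < 1L) stop("n_events must be >= 1")
  if (n_trees < 1L || n_trees > n_events)
    stop("n_trees must be between 1 and n_events")
  if (depth_cap < 1L)
    stop("depth_cap too small: no tree over ", n_events,
         " events fits within depth ", depth_cap)
  lo <- prob_range[1L]; hi <- prob_range[2L]
  if (!(lo > 0 && lo < hi && hi <= 1))
    stop("prob_range must satisfy 0 < lo < hi <= 1")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  structure(list(n_events = n_events, n_trees = n_trees,
                 depth_cap = depth_cap, prob_range = c(lo, hi),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "generator_config")
}

#' Noise model specification
#'
#' Uniform noise replaces any matrix entry, with probability `nu`, by a
#' uniformly random binary value (so the effective flip rate is `nu/2` in
#' each direction). Asymmetric noise flips zeros to ones at the false
#' positive rate `eps_plus` and ones to zeros at the false negative rate
#' `eps_minus`.
#'
#' @param mode `"none"`, `"uniform"` or `"asymmetric"`.
#' @param nu uniform-mode replacement probability in `[0, 1)`.
#' @param eps_plus,eps_minus asymmetric-mode rates in `[0, 1)`
#'   (`eps_minus = 1` is tolerated as a degenerate all-zeros limit).
#' @export
noise_spec <- function(mode = c("none", "uniform", "asymmetric"),
                       nu = 0, eps_plus = 0, eps_minus = 0) {
  mode <- match.arg(mode)
  if (mode == "uniform" && (nu < 0 || nu >= 1))
    stop("nu must be in [0, 1)")
  if (mode == "asymmetric" &&
      (eps_plus < 0 || eps_plus >= 1 || eps_minus < 0 || eps_minus > 1))
    stop("asymmetric rates must be in [0, 1)")
  structure(list(mode = mode, nu = nu,
                 eps_plus = if (mode == "uniform") nu / 2 else eps_plus,
                 eps_minus = if (mode == "uniform") nu / 2 else eps_minus),
            class = "noise_spec")
}

#' Generate a random progression tree or forest
#'
#' The `n_events` event observation probabilities (theoretical marginals)
#' are drawn i.i.d. uniformly from `prob_range` and sorted in decreasing
#' order; events are then attached in that order, so every child is rarer
#' than its parent, as the tree-induced distribution requires. The first
#' `n_trees` events become children of the root, and each further event
#' picks a uniformly random parent among the event nodes whose depth is
#' strictly below `depth_cap`. Each edge probability is the ratio of the
#' child's to the parent's marginal, which reproduces the drawn marginals
#' exactly under the tree-induced distribution.
#'
#' @param cfg a [generator_config()].
#' @param labels optional event labels (default `e1..en`), assigned in
#'   decreasing order of marginal probability.
#' @param root_label root label.
#' @return a [progression_forest()] with edge probabilities.
#' @export
random_tree <- function(cfg, labels = NULL, root_label = DEFAULT_ROOT) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_events
  if (is.null(labels)) labels <- paste0("e", seq_len(n))
  stopifnot(length(labels) == n, !root_label %in% labels)
  marg <- sort(stats::runif(n, cfg$prob_range[1L], cfg$prob_range[2L]),
               decreasing = TRUE)
  parent <- character(n)
  depth <- integer(n)
  for (i in seq_len(n)) {
    if (i <= cfg$n_trees) {
      parent[i] <- root_label
      depth[i] <- 1L
    } else {
      ok <- which(depth[seq_len(i - 1L)] < cfg$depth_cap)
      if (!length(ok))
        stop("depth_cap too small: no eligible parent for event ", i)
      j <- ok[sample.int(length(ok), 1L)]
      parent[i] <- labels[j]
      depth[i] <- depth[j] + 1L
    }
  }
  ep <- ifelse(parent == root_label, marg,
               marg / marg[match(parent, labels)])
  progression_forest(stats::setNames(parent, labels), root = root_label,
                     edge_prob = stats::setNames(ep, labels))
}

#' Sample cross-sectional genotypes from a tree-induced distribution
#'
#' Each sample is generated top-down: the root is always present (and not
#' emitted as a column), and each event is present iff its parent is present
#' and an independent Bernoulli trial with the edge probability succeeds.
#' The induced distribution over alteration sets is the product, over the
#' edges connecting the root to the observed set, of the edge
#' probabilities, times the complement of every non-extended outgoing edge.
#'
#' @param f a [progression_forest()] whose every edge has a probability in
#'   (0, 1].
#' @param n_samples number of samples to draw.
#' @return a [genotype_matrix()] with columns in the forest's event order.
#' @export
sample_tree_distribution <- function(f, n_samples) {
  stopifnot(inherits(f, "progression_forest"), n_samples >= 1)
  if (anyNA(f$edge_prob) || any(f$edge_prob <= 0) || any(f$edge_prob > 1))
    stop("every edge needs a probability in (0, 1]")
  ev <- f$events
  X <- matrix(0L, n_samples, length(ev), dimnames = list(NULL, ev))
  for (v in forest_topological_order(f)) {
    u <- f$parent[[v]]
    on <- if (u == f$root) rep(1L, n_samples) else X[, u]
    X[, v] <- on * stats::rbinom(n_samples, 1L, f$edge_prob[[v]])
  }
  genotype_matrix(X, events = ev)
}

#' Corrupt a genotype matrix with observation noise
#'
#' @param g a [genotype_matrix()].
#' @param noise a [noise_spec()].
#' @return a [genotype_matrix()] of the same shape.
#' @export
apply_noise <- function(g, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  x <- unclass(g)
  if (noise$mode == "none" || (noise$mode == "uniform" && noise$nu == 0))
    return(g)
  if (noise$mode == "uniform") {
    hit <- stats::runif(length(x)) < noise$nu
    coin <- stats::rbinom(length(x), 1L, 0.5)
    x[hit] <- coin[hit]
  } else {
    u <- stats::runif(length(x))
    zeros <- x == 0L  # masks from the original matrix: flips do not cascade
    x[zeros & u < noise$eps_plus] <- 1L
    x[!zeros & u < noise$eps_minus] <- 0L
  }
  genotype_matrix(x, events = events_of(g), samples = rownames(g))
}

#' Draw a dataset satisfying the framework's algebraic requirements
#'
#' The reconstruction framework requires every event to be observed with
#' frequency strictly in (0, 1) and every pair of events to be
#' distinguishable (no two identical observation columns). This sampler
#' draws datasets from the tree-induced distribution (applying the noise
#' channel after each draw) until those requirements hold, giving the
#' standard simulation conditions under which reconstruction quality is
#' assessed. If no valid dataset is found within `max_tries` draws the last
#' draw is returned as-is (the fitting functions then fall back to dropping
#' and merging offending events).
#'
#' @param f a [progression_forest()] with edge probabilities.
#' @param n_samples samples per dataset.
#' @param noise a [noise_spec()].
#' @param max_tries maximum number of draws.
#' @return a [genotype_matrix()].
#' @export
sample_valid_dataset <- function(f, n_samples, noise = noise_spec("none"),
                                 max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    g <- apply_noise(sample_tree_distribution(f, n_samples), noise)
    cs <- colSums(unclass(g))
    if (any(cs == 0L | cs == nrow(g))) next
    if (anyDuplicated(t(unclass(g)))) next
    return(g)
  }
  g
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: draws a random generating forest, then samples
#' genotypes from its induced distribution through the noise channel with
#' [sample_valid_dataset()].
#'
#' @param cfg a [generator_config()].
#' @param noise a [noise_spec()].
#' @param root_label root label.
#' @return list with `genotypes` (noisy matrix) and `forest` (ground
#'   truth).
#' @export
simulate_dataset <- function(cfg, noise = noise_spec("none"),
                             root_label = DEFAULT_ROOT) {
  f <- random_tree(cfg, root_label = root_label)
  g <- sample_valid_dataset(f, cfg$n_samples, noise)
  list(genotypes = g, forest = f)
}

#' Write a simulated dataset with its ground-truth sidecar
#'
#' Emits `<prefix>.tsv` (the genotype matrix) and `<prefix>.truth.json`
#' (generating forest edge list with probabilities, plus the seed), so the
#' truth can be recovered for evaluation.
#'
#' @param sim a [simulate_dataset()] result.
#' @param prefix output path prefix.
#' @param seed seed to record in the sidecar (may be `NULL`).
#' @export
write_simulation <- function(sim, prefix, seed = NULL) {
  write_genotypes(sim$genotypes, paste0(prefix, ".tsv"))
  f <- sim$forest
  side <- list(root = f$root,
               edges = data.frame(child = f$events,
                                  parent = unname(f$parent),
                                  edge_prob = unname(f$edge_prob)),
               seed = seed)
  jsonlite::write_json(side, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read the ground-truth sidecar written by [write_simulation()]
#' @param path path to the `.truth.json` file.
#' @export
read_simulation_truth <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  progression_forest(stats::setNames(side$edges$parent, side$edges$child),
                     root = side$root,
                     edge_prob = stats::setNames(side$edges$edge_prob,
                                                 side$edges$child))
}
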