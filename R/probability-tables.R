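#' Empirical marginal and joint probabilities
#'
#' Computes exact empirical frequencies from a (possibly root-adjoined)
#' genotype matrix: `marginal[a] = count(a)/m` and
#' `joint[a,b] = count(a and b)/m`. All probabilities are exact integer-count
#' ratios represented in double precision; every strict comparison performed
#' downstream (probability raising, temporal priority, the independent
#' progressions filter) cross-multiplies the underlying integer counts so no
#' floating-point tie can flip a decision.
#'
#' Every non-root event must be observed with frequency strictly between 0
#' and 1; use [drop_degenerate_events()] first. The root column, when
#' present, is exempt (its marginal is 1 by construction).
#'
#' @param g a [genotype_matrix()], usually after [adjoin_root()].
#' @param root label of the root column in `g`, or `NULL` if none.
#' @return object of class `probability_tables`: list with `events`
#'   (including the root if present), `root`, `m`, `counts`, `joint_counts`,
#'   `marginal`, `joint`.
#' @export
estimate_probabilities <- function(g, root = NULL) {
  x <- unclass(g)
  ev <- colnames(x)
  if (!is.null(root)) {
    if (!root %in% ev)
      stop("root label '", root, "' not found among events")
    if (any(x[, root] != 1L))
      stop("root column must be 1 in every sample")
  }
  m <- nrow(x)
  counts <- colSums(x)
  non_root <- setdiff(ev, root)
  deg <- non_root[counts[non_root] == 0 | counts[non_root] == m]
  if (length(deg))
    stop("event(s) with degenerate frequency 0 or 1: ",
         paste(deg, collapse = ", "),
         " (drop or merge them before estimating probabilities)")
  joint_counts <- crossprod(x)
  structure(list(events = ev, root = root, m = m,
                 counts = counts, joint_counts = joint_counts,
                 marginal = counts / m, joint = joint_counts / m),
            class = "probability_tables")
}

#' @export
print.probability_tables <- function(x, ...) {
  cat(sprintf("probability_tables: %d events, m = %d samples\n",
              length(x$events), x$m))
  if (!is.null(x$root)) cat("root:", x$root, "\n")
  invisible(x)
}

.chk_events <- function(p, ..., allow_root = FALSE) {
  for (e in c(...)) {
    if (!e %in% p$events)
      stop("unknown event: ", e)
    if (!allow_root && !is.null(p$root) && e == p$root)
      stop("operation undefined for the root event '", e, "'")
  }
}

#' Conditional probability of one event given another
#'
#' Returns `P(b|a) = P(a,b)/P(a)` or, with `negated = TRUE`,
#' `P(b|not a) = (P(b) - P(a,b)) / (1 - P(a))`.
#'
#' @param p a [estimate_probabilities()] result.
#' @param b,given_a event labels.
#' @param negated condition on the absence of `given_a`.
#' @export
conditional_probability <- function(p, b, given_a, negated = FALSE) {
  .chk_events(p, b, allow_root = TRUE)
  .chk_events(p, given_a, allow_root = !negated)
  ca <- p$counts[[given_a]]
  cb <- p$counts[[b]]
  cab <- p$joint_counts[given_a, b]
  if (!negated) {
    if (ca == 0) stop("P(", given_a, ") = 0: conditional undefined")
    cab / ca
  } else {
    if (ca == p$m) stop("P(not ", given_a, ") = 0: conditional undefined")
    (cb - cab) / (p$m - ca)
  }
}

# Exact probability-raising test on integer counts:
# P(b|a) > P(b|~a)  <=>  cab*(m-ca) > (cb-cab)*ca
.raises <- function(p, a, b) {
  ca <- as.numeric(p$counts[[a]]); cb <- as.numeric(p$counts[[b]])
  cab <- as.numeric(p$joint_counts[a, b])
  cab * (p$m - ca) > (cb - cab) * ca
}

#' Prima facie causation test
#'
#' `a` is a prima facie cause of `b` when `a` raises the probability of `b`
#' (`P(b|a) > P(b|not a)`) and `a` occurs strictly more frequently than `b`
#' (temporal priority: in cross-sectional data, earlier events of a
#' cumulative process are more frequent). Both inequalities are evaluated
#' exactly on integer counts; equal-frequency pairs are indistinguishable in
#' terms of temporal priority and are never prima facie in either direction.
#'
#' @param p a [estimate_probabilities()] result.
#' @param a,b distinct non-root event labels.
#' @export
prima_facie <- function(p, a, b) {
  .chk_events(p, a, b)
  if (a == b) stop("prima facie is undefined for a pair of equal events")
  .raises(p, a, b) && p$counts[[a]] > p$counts[[b]]
}

#' Raw probability-raising estimator
#'
#' Monotonically normalized probability-raising ratio
#' `alpha(a -> b) = (P(b|a) - P(b|not a)) / (P(b|a) + P(b|not a))`,
#' ranging in `[-1, 1]`: -1 in the mutually-exclusive (anti-causation)
#' limit, 0 under independence, +1 when `b` never occurs without `a`.
#'
#' @inheritParams prima_facie
#' @export
pr_alpha <- function(p, a, b) {
  .chk_events(p, a, b)
  if (a == b) stop("alpha undefined on the diagonal")
  pba <- conditional_probability(p, b, a)
  pbna <- conditional_probability(p, b, a, negated = TRUE)
  if (pba + pbna == 0)
    stop("alpha undefined: P(b|a) + P(b|not a) = 0")
  (pba - pbna) / (pba + pbna)
}

#' Correlation-based correction factor
#'
#' `beta(a, b) = (P(a,b) - P(a)P(b)) / (P(a,b) + P(a)P(b))`, a symmetric
#' correlation-like measure of temporal distance in `[-1, 1]` sharing the
#' sign of the statistical dependency between the events: positive for
#' positively dependent pairs, 0 under independence, -1 for mutually
#' exclusive pairs.
#'
#' @inheritParams prima_facie
#' @export
pr_beta <- function(p, a, b) {
  .chk_events(p, a, b)
  if (a == b) stop("beta undefined on the diagonal")
  pab <- p$joint[a, b]
  pp <- p$marginal[[a]] * p$marginal[[b]]
  if (pab + pp == 0)
    stop("beta undefined: P(a,b) + P(a)P(b) = 0")
  (pab - pp) / (pab + pp)
}

#' Shrinkage-like estimator matrix
#'
#' Computes, for every ordered pair of non-root events, the shrinkage-like
#' confidence `m(a -> b) = (1 - lambda) * alpha(a -> b) + lambda * beta(a, b)`,
#' a convex combination of the raw probability-raising estimator and the
#' correlation-based correction factor. `lambda = 0` reduces to alpha
#' (sharpest, noise-sensitive), `lambda = 1` to beta (blunter, noise-robust);
#' `lambda = 1/2` averages the two and is the recommended setting for noisy
#' data, while a very small positive lambda (e.g. 0.01) suits noise-free
#' data.
#'
#' @param p a [estimate_probabilities()] result.
#' @param lambda shrinkage coefficient in `[0, 1]`.
#' @return object of class `estimator_matrix`: list with `events` (non-root),
#'   `lambda`, and `n x n` matrices `alpha` (directed, rows = cause),
#'   `beta` (symmetric) and `m` (the combination); diagonals are `NA`.
#' @export
shrinkage_estimator <- function(p, lambda = 0.5) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]")
  ev <- setdiff(p$events, p$root)
  n <- length(ev)
  cnt <- as.numeric(p$counts[ev])
  J <- p$joint_counts[ev, ev, drop = FALSE]
  m <- p$m
  # P(b|a) as matrix: rows a, cols b
  pba <- J / cnt
  pbna <- (matrix(cnt, n, n, byrow = TRUE) - J) / (m - cnt)
  alpha <- (pba - pbna) / (pba + pbna)
  pp <- outer(cnt / m, cnt / m)
  pj <- J / m
  beta <- (pj - pp) / (pj + pp)
  diag(alpha) <- NA_real_
  diag(beta) <- NA_real_
  mm <- (1 - lambda) * alpha + lambda * beta
  dimnames(alpha) <- dimnames(beta) <- dimnames(mm) <- list(ev, ev)
  structure(list(events = ev, lambda = lambda,
                 alpha = alpha, beta = beta, m = mm),
            class = "estimator_matrix")
}

#' @export
print.estimator_matrix <- function(x, ...) {
  cat(sprintf("estimator_matrix: %d events, lambda = %g\n",
              length(x$events), x$lambda))
  invisible(x)
}

#' Write an estimator matrix to labelled TSV
#'
#' Rows are causes, columns effects.
#' @param est a [shrinkage_estimator()] result.
#' @param path output file.
#' @param which which score matrix to export.
#' @export
write_estimator <- function(est, path, which = c("m", "alpha", "beta")) {
  which <- match.arg(which)
  x <- est[[which]]
  df <- data.frame(cause = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation/temporal-priority oncotree edge weight
#'
#' The classical oncotree weight for a directed edge `a -> b`:
#' `w(a -> b) = log( P(a)/(P(a)+P(b)) * P(a,b)/(P(a)P(b)) )` (natural log),
#' the product of an asymmetric temporal-priority term and a symmetric
#' likelihood-ratio term. Probabilities must come from the root-adjoined
#' matrix; the root has marginal 1 and joint `P(root, b) = P(b)`.
#' A zero joint probability yields `-Inf` (the edge can never enter a
#' maximum-weight arborescence).
#'
#' @param p a [estimate_probabilities()] result on root-adjoined data.
#' @param a cause label (may be the root).
#' @param b effect label (non-root).
#' @export
oncotree_weight <- function(p, a, b) {
  .chk_events(p, a, allow_root = TRUE)
  .chk_events(p, b)
  if (a == b) stop("oncotree weight undefined on the diagonal")
  pa <- p$marginal[[a]]; pb <- p$marginal[[b]]; pab <- p$joint[a, b]
  if (pab == 0) return(-Inf)
  log(pa / (pa + pb)) + log(pab / (pa * pb))
}

#' Full oncotree weight matrix
#'
#' @inheritParams oncotree_weight
#' @return matrix with rows = candidate parents (root first when present,
#'   then events), columns = non-root events; diagonal entries `NA`.
#' @export
oncotree_weight_matrix <- function(p) {
  ev <- setdiff(p$events, p$root)
  parents <- c(p$root, ev)
  W <- matrix(NA_real_, length(parents), length(ev),
              dimnames = list(parents, ev))
  for (a in parents)
    for (b in ev)
      if (a != b)
        W[a, b] <- oncotree_weight(p, a, b)
  W
}
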