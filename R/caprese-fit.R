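#' Reconstruct a progression forest with CAPRESE
#'
#' CAPRESE (CAncer PRogression Extraction with Single Edges) reconstructs a
#' tree/forest model of cumulative progression from cross-sectional binary
#' genotypes in four steps:
#'
#' 1. the root event is adjoined to every sample;
#' 2. the pairwise shrinkage-like estimator
#'    `m(a -> b) = (1 - lambda) alpha(a -> b) + lambda beta(a, b)` is
#'    computed from exact empirical frequencies;
#' 3. *(probability-raising causation)* every event `b` selects as parent
#'    the event `a` maximizing `m(a -> b)` among its prima facie causes
#'    (probability raiser of `b`, strictly more frequent than `b`) with
#'    `m(a -> b) > 0`; events with no such candidate attach to the root;
#' 4. *(independent progressions filter)* an edge `(a, b)` is replaced by
#'    `(root, b)` when the correlation-like weight of `b` with the root
#'    dominates its weight with every upstream prima facie cause (see
#'    [independent_progressions_filter()]), splitting independent
#'    progression paths into separate subtrees of the root.
#'
#' Ties between candidate parents with exactly equal `m` are broken in
#' favour of the more frequent parent, then the lexicographically smallest
#' label, so reconstruction is deterministic.
#'
#' @param g a [genotype_matrix()] (events only; the root is adjoined
#'   internally).
#' @param lambda shrinkage coefficient in `[0, 1]`; use a small value
#'   (e.g. 0.01) for noise-free data and 0.5 for noisy data.
#' @param root_label label for the adjoined root.
#' @param preprocess drop degenerate events (frequency 0 or 1) and merge
#'   indistinguishable (identical-column) events before fitting.
#' @param quiet suppress preprocessing warnings.
#' @return a [progression_forest()] with edge scores (`m` values; `NA` for
#'   root attachments made by the filter or by default) and estimated edge
#'   probabilities. Attributes `lambda`, `probabilities`, `estimator`,
#'   `merges` and `dropped` record the fit context.
#' @export
caprese_fit <- function(g, lambda = 0.5, root_label = DEFAULT_ROOT,
                        preprocess = TRUE, quiet = FALSE) {
  dropped <- character()
  merges <- list()
  if (preprocess) {
    n0 <- events_of(g)
    g <- drop_degenerate_events(g, quiet = quiet)
    dropped <- setdiff(n0, events_of(g))
    mg <- merge_indistinguishable(g)
    g <- mg$genotypes
    merges <- mg$merges
  }
  if (ncol(g) == 0L)
    stop("no non-degenerate events left to reconstruct from")
  ga <- adjoin_root(g, root_label)
  p <- estimate_probabilities(ga, root = root_label)
  est <- shrinkage_estimator(p, lambda)
  f <- .pr_causation_step(p, est, root_label)
  f <- independent_progressions_filter(f, p)
  f <- estimate_edge_probabilities(f, p)
  attr(f, "lambda") <- lambda
  attr(f, "probabilities") <- p
  attr(f, "estimator") <- est
  attr(f, "merges") <- merges
  attr(f, "dropped") <- dropped
  f
}

# Step 3 of the algorithm: best prima facie parent by m(lambda).
.pr_causation_step <- function(p, est, root_label) {
  ev <- est$events
  parent <- stats::setNames(rep(root_label, length(ev)), ev)
  scores <- stats::setNames(rep(NA_real_, length(ev)), ev)
  for (b in ev) {
    cand <- ev[vapply(ev, function(a)
      a != b && prima_facie(p, a, b) && est$m[a, b] > 0, logical(1L))]
    if (!length(cand)) next
    sc <- est$m[cand, b]
    o <- order(-sc, -p$counts[cand], cand, method = "radix")
    parent[[b]] <- cand[o[1L]]
    scores[[b]] <- sc[o[1L]]
  }
  progression_forest(parent, root = root_label, scores = scores)
}

#' Independent progressions filter
#'
#' Re-attaches an event to the root when its best prima facie cause is
#' judged spurious. The correlation-like weight between two nodes is
#' `w(a, b) = P(a, b) / (P(a) + P(b))`; for the omnipresent root
#' (`P(root) = 1`, `P(root, b) = P(b)`) it reduces to
#' `w(root, b) = P(b) / (1 + P(b))`. The edge `(a, b)` is replaced by
#' `(root, b)` when `w(root, b) > w(g, b)` for *every* upstream connected
#' prima facie cause `g` of `b` (its ancestors in the candidate tree that
#' are prima facie causes of `b`). Under exact tree-induced frequencies the
#' root weight never dominates a genuine ancestor, while for events on
#' independent progression paths it always does, so the filter separates
#' independent paths without breaking genuine chains. All comparisons are
#' exact on integer counts. The filter is a single pass: upstream sets are
#' taken in the candidate structure, and re-parenting is applied afterwards.
#'
#' @param f candidate forest from the probability-raising step.
#' @param p [estimate_probabilities()] tables from the root-adjoined matrix.
#' @return the filtered [progression_forest()].
#' @export
independent_progressions_filter <- function(f, p) {
  m <- p$m
  cnt <- p$counts
  jnt <- p$joint_counts
  move <- character()
  for (b in f$events) {
    if (f$parent[[b]] == f$root) next
    up <- forest_ancestors(f, b)
    up <- up[vapply(up, function(a) prima_facie(p, a, b), logical(1L))]
    if (!length(up)) { move <- c(move, b); next }
    # w(root,b) > w(g,b)  <=>  cb*(cg+cb) > cgb*(m+cb)  on exact counts
    cb <- as.numeric(cnt[[b]])
    dominates <- vapply(up, function(g)
      cb * (as.numeric(cnt[[g]]) + cb) >
        as.numeric(jnt[g, b]) * (m + cb), logical(1L))
    if (all(dominates)) move <- c(move, b)
  }
  if (length(move)) {
    f$parent[move] <- f$root
    f$scores[move] <- NA_real_
    validate_forest(f)
  }
  f
}

#' Estimate per-edge progression probabilities
#'
#' For each edge `(u, v)` of a reconstructed forest the conditional
#' frequency `P(u, v) / P(u)` estimates the probability that the alteration
#' is transmitted along the edge; root edges get the child's marginal
#' (`P(root) = 1`). Values are clipped into `(0, 1]`.
#'
#' @param f a [progression_forest()].
#' @param p [estimate_probabilities()] tables from the same data
#'   (root-adjoined).
#' @export
estimate_edge_probabilities <- function(f, p) {
  ep <- vapply(f$events, function(v) {
    u <- f$parent[[v]]
    if (u == f$root) p$marginal[[v]]
    else p$joint[u, v] / p$marginal[[u]]
  }, numeric(1L))
  f$edge_prob <- pmin(pmax(ep, .Machine$double.eps), 1)
  f
}
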