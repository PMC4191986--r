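# Shared fixtures and independent brute-force oracles used across the suite.

ROOT <- DEFAULT_ROOT

# The four-sample toy dataset: samples {a}, {a,b}, {a,b}, {}.
toy_matrix <- function() {
  genotype_matrix(matrix(c(1, 1, 1, 0,
                           0, 1, 1, 0), ncol = 2), events = c("a", "b"))
}

toy_tables <- function() {
  estimate_probabilities(adjoin_root(toy_matrix()), root = ROOT)
}

# Deterministic chain forest root -> e1 -> e2 -> ... with given edge probs.
chain_forest <- function(probs, labels = paste0("e", seq_along(probs))) {
  parent <- c(ROOT, labels[-length(labels)])
  progression_forest(stats::setNames(parent, labels),
                     edge_prob = stats::setNames(probs, labels))
}

# Random parent map over n events (arbitrary rooted forest), for metric fuzz.
random_forest_fixture <- function(n_events, p_root = 0.3) {
  labels <- paste0("x", seq_len(n_events))
  parent <- character(n_events)
  for (i in seq_len(n_events)) {
    if (i == 1L || stats::runif(1) < p_root) parent[i] <- ROOT
    else parent[i] <- labels[sample.int(i - 1L, 1L)]
  }
  progression_forest(stats::setNames(parent, labels))
}

# ---- Brute-force tree edit distance ---------------------------------------
# Minimum-cost valid mapping between the canonicalized ordered trees:
# one-to-one, order-preserving (postorder) and ancestorship-preserving.
# Cost = unmapped nodes on both sides + label mismatches among mapped pairs.
brute_force_ted <- function(t1, t2) {
  a <- caprese:::.canonical_postorder(t1)
  b <- caprese:::.canonical_postorder(t2)
  n1 <- length(a$labels); n2 <- length(b$labels)
  is_desc <- function(l, low, high) l[high] <= low  # low < high in postorder
  best <- n1 + n2
  rec <- function(i, pairs) {
    if (i > n1) {
      cost <- (n1 - nrow(pairs)) + (n2 - nrow(pairs)) +
        sum(a$labels[pairs[, 1L]] != b$labels[pairs[, 2L]])
      if (cost < best) best <<- cost
      return(invisible())
    }
    # option 1: leave i unmapped
    rec(i + 1L, pairs)
    # option 2: map i to some j greater than all used j
    jmin <- if (nrow(pairs)) max(pairs[, 2L]) + 1L else 1L
    for (j in seq.int(jmin, length.out = max(0L, n2 - jmin + 1L))) {
      ok <- TRUE
      if (nrow(pairs)) {
        for (k in seq_len(nrow(pairs))) {
          i0 <- pairs[k, 1L]; j0 <- pairs[k, 2L]
          if (is_desc(a$l, i0, i) != is_desc(b$l, j0, j)) { ok <- FALSE; break }
        }
      }
      if (ok) rec(i + 1L, rbind(pairs, c(i, j)))
    }
  }
  rec(1L, matrix(integer(), 0L, 2L))
  best
}

# ---- Brute-force maximum-weight arborescence ------------------------------
# Enumerates every acyclic parent map over the events and returns the best
# total weight (and one argmax parent map).
brute_force_arborescence <- function(W, root) {
  nodes <- rownames(W)
  ev <- setdiff(nodes, root)
  k <- length(ev)
  choices <- lapply(ev, function(v) setdiff(nodes, v))
  best_w <- -Inf
  best_parent <- NULL
  idx <- rep(1L, k)
  repeat {
    parent <- stats::setNames(
      vapply(seq_len(k), function(i) choices[[i]][idx[i]], ""), ev)
    acyclic <- !inherits(try(progression_forest(parent, root = root),
                             silent = TRUE), "try-error")
    if (acyclic) {
      w <- sum(W[cbind(parent, ev)])
      if (w > best_w) { best_w <- w; best_parent <- parent }
    }
    pos <- k
    while (pos >= 1L) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(choices[[pos]])) break
      idx[pos] <- 1L; pos <- pos - 1L
    }
    if (pos < 1L) break
  }
  list(weight = best_w, parent = best_parent)
}

# ---- Exact tree-induced distribution --------------------------------------
# Enumerates all root-closed alteration sets of a forest with their exact
# probabilities under the edge-transmission model.
exact_tree_distribution <- function(f) {
  ev <- f$events
  n <- length(ev)
  sets <- expand.grid(rep(list(c(0L, 1L)), n))
  names(sets) <- ev
  probs <- numeric(nrow(sets))
  for (r in seq_len(nrow(sets))) {
    s <- as.integer(sets[r, ])
    names(s) <- ev
    pr <- 1
    closed <- TRUE
    for (v in ev) {
      u <- f$parent[[v]]
      parent_on <- u == f$root || s[[u]] == 1L
      if (s[[v]] == 1L) {
        if (!parent_on) { closed <- FALSE; break }
        pr <- pr * f$edge_prob[[v]]
      } else if (parent_on) {
        pr <- pr * (1 - f$edge_prob[[v]])
      }
    }
    probs[r] <- if (closed) pr else 0
  }
  cbind(sets, prob = probs)
}

# Exact-count cross-multiplication checks used as the rational oracle.
exact_alpha_sign <- function(m, ca, cb, cab) {
  # sign of P(b|a) - P(b|~a) without division
  sign(cab * (m - ca) - (cb - cab) * ca)
}
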