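#' Maximum-weight rooted arborescence (Chu-Liu/Edmonds)
#'
#' Finds the spanning arborescence rooted at `root` that maximizes the sum
#' of edge weights, over the directed weighted graph given as a matrix
#' `W[parent, child]` (use `-Inf` for absent edges; diagonal and entries
#' into the root are ignored). Ties are broken deterministically by the row
#' order of `W`: among equal-weight incoming edges the earlier row wins, so
#' callers control the preference by ordering candidate parents.
#'
#' @param W square numeric matrix with identical row/column names; entry
#'   `W[u, v]` is the weight of edge `u -> v`.
#' @param root name of the root node.
#' @return named character vector mapping each non-root node to its parent.
#' @export
max_arborescence <- function(W, root) {
  stopifnot(is.matrix(W), !is.null(rownames(W)),
            identical(rownames(W), colnames(W)), root %in% rownames(W))
  n <- nrow(W)
  idx <- .chu_liu(unname(W), which(rownames(W) == root))
  stats::setNames(rownames(W)[idx[-which(rownames(W) == root)]],
                  rownames(W)[-which(rownames(W) == root)])
}

# Recursive Chu-Liu/Edmonds on an index matrix; returns parent index per
# node (NA for the root). Deterministic: first maximal row wins ties.
.chu_liu <- function(W, root) {
  n <- nrow(W)
  pi <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (v == root) next
    w <- W[, v]
    w[v] <- -Inf
    if (all(!is.finite(w)))
      stop("node ", v, " has no incoming edge of finite weight")
    pi[v] <- which.max(w)
  }
  cyc <- .find_cycle(pi)
  if (is.null(cyc))
    return(pi)
  # contract the cycle into a supernode (reuse index cyc[1])
  super <- cyc[1L]
  rest <- setdiff(seq_len(n), cyc)
  map <- integer(n)           # old index -> contracted index
  keep <- sort(c(rest, super))
  map[keep] <- seq_along(keep)
  map[cyc] <- map[super]
  W2 <- matrix(-Inf, length(keep), length(keep))
  enter_choice <- rep(NA_integer_, n)  # for u outside: best cycle entry
  exit_choice <- matrix(NA_integer_, n, 1L)
  exit_from <- rep(NA_integer_, n)     # for v outside: best cycle exit
  for (u in rest) {
    for (v in rest) {
      if (u != v) W2[map[u], map[v]] <- W[u, v]
    }
    # edge u -> supernode: max over cycle nodes of W[u,c] - W[pi[c],c]
    adj <- W[u, cyc] - W[cbind(pi[cyc], cyc)]
    if (any(is.finite(adj))) {
      k <- which.max(adj)
      W2[map[u], map[super]] <- adj[k]
      enter_choice[u] <- cyc[k]
    }
  }
  for (v in rest) {
    out <- W[cyc, v]
    if (any(is.finite(out))) {
      k <- which.max(out)
      w_old <- W2[map[super], map[v]]
      if (!is.finite(w_old) || out[k] > w_old) {
        W2[map[super], map[v]] <- out[k]
        exit_from[v] <- cyc[k]
      }
    }
  }
  pi2 <- .chu_liu(W2, map[root])
  # expand
  pi_out <- rep(NA_integer_, n)
  inv <- keep                  # contracted index -> old index
  for (v2 in seq_along(keep)) {
    if (v2 == map[root]) next
    u2 <- pi2[v2]
    v_old <- inv[v2]
    u_old <- inv[u2]
    if (v_old == super) {
      # edge entering the contracted cycle: break the cycle at the entry
      entry <- enter_choice[u_old]
      pi_out[entry] <- u_old
      for (c0 in cyc)
        if (c0 != entry) pi_out[c0] <- pi[c0]
    } else if (u_old == super) {
      pi_out[v_old] <- exit_from[v_old]
    } else {
      pi_out[v_old] <- u_old
    }
  }
  pi_out
}

.find_cycle <- function(pi) {
  n <- length(pi)
  color <- integer(n)  # 0 unseen, 1 in progress, 2 done
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    path <- integer()
    v <- s
    while (!is.na(v) && color[v] == 0L) {
      color[v] <- 1L
      path <- c(path, v)
      v <- pi[v]
    }
    if (!is.na(v) && color[v] == 1L) {
      # cycle: nodes from v onward in path
      return(path[which(path == v):length(path)])
    }
    color[path] <- 2L
  }
  NULL
}

#' Reconstruct a progression forest with the oncotree baseline
#'
#' The classical correlation-based oncotree: the root event is adjoined to
#' every sample, every directed edge between events (and from the root) is
#' weighted with [oncotree_weight()] (log product of temporal priority and
#' likelihood ratio), and the maximum-weight arborescence rooted at the root
#' is extracted with the Chu-Liu/Edmonds algorithm. Weight ties are broken
#' preferring the more frequent parent, then label order, mirroring the
#' CAPRESE policy.
#'
#' @inheritParams caprese_fit
#' @return a [progression_forest()] with edge scores (the log weights) and
#'   estimated edge probabilities.
#' @export
oncotree_fit <- function(g, root_label = DEFAULT_ROOT, preprocess = TRUE,
                         quiet = FALSE) {
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
  Wev <- oncotree_weight_matrix(p)        # parents (root + events) x events
  ev <- colnames(Wev)
  # order candidate parents root-first, then by decreasing frequency and
  # label, so which.max tie-breaking is the documented policy
  ord <- c(root_label, ev[order(-p$counts[ev], ev, method = "radix")])
  nodes <- ord
  W <- matrix(-Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  W[rownames(Wev), colnames(Wev)] <- Wev
  W[is.na(W)] <- -Inf
  # nodes with no finite incoming weight fall back to the root
  orphan <- ev[vapply(ev, function(v)
    all(!is.finite(W[setdiff(nodes, v), v])), logical(1L))]
  if (length(orphan)) {
    warning("event(s) with no finite incoming weight attached to root: ",
            paste(orphan, collapse = ", "), call. = FALSE)
    W[root_label, orphan] <- 0
  }
  parent <- max_arborescence(W, root_label)
  scores <- stats::setNames(Wev[cbind(parent[ev], ev)], ev)
  f <- progression_forest(parent[ev], root = root_label, scores = scores)
  f <- estimate_edge_probabilities(f, p)
  attr(f, "probabilities") <- p
  attr(f, "merges") <- merges
  attr(f, "dropped") <- dropped
  f
}
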