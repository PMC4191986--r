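#' Construct a rooted progression forest
#'
#' A progression forest is a rooted tree over the events plus the special
#' root node: every event has exactly one parent (possibly the root), the
#' root has no parent, and there are no cycles, so every event is reachable
#' from the root. Subtrees hanging directly off the root are independent
#' progression paths.
#'
#' @param parent named character vector mapping each event (name) to its
#'   parent label (another event or the root).
#' @param root root label.
#' @param edge_prob optional named numeric vector (per child) with the
#'   probability of the incoming edge, in (0, 1].
#' @param scores optional named numeric vector (per child) with the score of
#'   the selected incoming edge.
#' @return object of class `progression_forest`.
#' @export
progression_forest <- function(parent, root = DEFAULT_ROOT,
                               edge_prob = NULL, scores = NULL) {
  parent <- unlist(parent)
  ev <- names(parent)
  if (is.null(ev) || anyDuplicated(ev))
    stop("'parent' must be uniquely named by child event")
  if (root %in% ev)
    stop("the root cannot have a parent")
  if (!all(parent %in% c(ev, root)))
    stop("unknown parent label(s): ",
         paste(setdiff(parent, c(ev, root)), collapse = ", "))
  f <- structure(list(root = root, events = ev,
                      parent = parent,
                      edge_prob = .named_or_na(edge_prob, ev),
                      scores = .named_or_na(scores, ev)),
                 class = "progression_forest")
  validate_forest(f)
  f
}

.named_or_na <- function(x, ev) {
  out <- stats::setNames(rep(NA_real_, length(ev)), ev)
  if (!is.null(x)) out[names(x)] <- x
  out
}

#' Validate progression forest invariants
#'
#' Checks single parenthood, acyclicity, a parentless root, and that every
#' event reaches the root through its parent chain. Errors on violation,
#' returns the forest invisibly otherwise.
#' @param f a [progression_forest()].
#' @export
validate_forest <- function(f) {
  stopifnot(inherits(f, "progression_forest"))
  ev <- f$events
  if (length(f$parent) != length(ev) || !identical(names(f$parent), ev))
    stop("exactly one parent per event is required")
  if (f$root %in% ev)
    stop("root must not appear among the events")
  for (e in ev) {
    seen <- character()
    cur <- e
    while (cur != f$root) {
      if (cur %in% seen)
        stop("cycle detected through event '", e, "'")
      seen <- c(seen, cur)
      cur <- f$parent[[cur]]
    }
  }
  invisible(f)
}

#' @export
print.progression_forest <- function(x, ...) {
  cat(sprintf("progression_forest: %d events, root '%s', %d progression path(s)\n",
              length(x$events), x$root,
              sum(x$parent == x$root)))
  for (e in x$events) {
    sc <- if (is.na(x$scores[[e]])) "" else sprintf("  score=%.4f", x$scores[[e]])
    pr <- if (is.na(x$edge_prob[[e]])) "" else sprintf("  p=%.3f", x$edge_prob[[e]])
    cat(sprintf("  %s -> %s%s%s\n", x$parent[[e]], e, sc, pr))
  }
  invisible(x)
}

#' Children of a node
#' @param f a [progression_forest()].
#' @param node node label (event or root).
#' @export
forest_children <- function(f, node) {
  f$events[f$parent == node]
}

#' Ancestors of an event (excluding the root)
#'
#' Events on the path from `node` (exclusive) up to the root (exclusive),
#' nearest first.
#' @inheritParams forest_children
#' @export
forest_ancestors <- function(f, node) {
  out <- character()
  cur <- f$parent[[node]]
  while (cur != f$root) {
    out <- c(out, cur)
    cur <- f$parent[[cur]]
  }
  out
}

#' Depth of every event (edges from the root)
#' @param f a [progression_forest()].
#' @export
forest_depths <- function(f) {
  vapply(f$events, function(e) length(forest_ancestors(f, e)) + 1L,
         integer(1L))
}

#' Events in deterministic topological order (parents before children)
#' @param f a [progression_forest()].
#' @export
forest_topological_order <- function(f) {
  d <- forest_depths(f)
  f$events[order(d, f$events, method = "radix")]
}

#' Write a forest as an edge-list TSV
#'
#' Columns: child, parent, score, edge_prob. Read back with
#' [read_edge_list()].
#' @param f a [progression_forest()].
#' @param path output file.
#' @export
write_edge_list <- function(f, path) {
  df <- data.frame(child = f$events, parent = unname(f$parent),
                   score = unname(f$scores), edge_prob = unname(f$edge_prob))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a forest from an edge-list TSV
#'
#' @param path file written by [write_edge_list()] (or with at least
#'   `child` and `parent` columns).
#' @param root root label; defaults to the unique parent that is not itself
#'   a child.
#' @export
read_edge_list <- function(path, root = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(root)) {
    cand <- setdiff(unique(df$parent), df$child)
    if (length(cand) != 1L)
      stop("cannot infer the root label; pass 'root' explicitly")
    root <- cand
  }
  progression_forest(stats::setNames(df$parent, df$child), root = root,
                     edge_prob = if ("edge_prob" %in% names(df))
                       stats::setNames(df$edge_prob, df$child),
                     scores = if ("score" %in% names(df))
                       stats::setNames(df$score, df$child))
}

#' Write a forest in Graphviz DOT format
#'
#' Node statements follow `event_order` (default: the forest's event order)
#' so output is deterministic.
#' @param f a [progression_forest()].
#' @param path output file.
#' @param event_order optional character vector ordering the event nodes.
#' @export
write_dot <- function(f, path, event_order = NULL) {
  ev <- if (is.null(event_order)) f$events else event_order
  stopifnot(setequal(ev, f$events))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph progression {",
             paste0("  ", q(f$root), " [shape=diamond];"),
             paste0("  ", q(ev), ";"),
             vapply(ev, function(e) {
               lab <- if (is.na(f$scores[[e]])) ""
                      else sprintf(" [label=\"%.3f\"]", f$scores[[e]])
               paste0("  ", q(f$parent[[e]]), " -> ", q(e), lab, ";")
             }, character(1L)),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write a forest in Newick format
#'
#' Each progression path (subtree rooted at a child of the root) is emitted
#' as one Newick line; a single-tree forest yields a single line.
#' @param f a [progression_forest()].
#' @param path output file.
#' @export
write_newick <- function(f, path) {
  emit <- function(node) {
    kids <- sort(forest_children(f, node), method = "radix")
    lab <- gsub("[(),;:\\s]", "_", node, perl = TRUE)
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, emit, character(1L)), collapse = ","),
           ")", lab)
  }
  tops <- sort(forest_children(f, f$root), method = "radix")
  writeLines(paste0(vapply(tops, emit, character(1L)), ";"), path)
  invisible(path)
}

#' Exact structural equality of two forests
#'
#' Label-level equality of the (child, parent) maps after canonical
#' ordering; roots must match.
#' @param f1,f2 [progression_forest()] objects.
#' @export
same_forest <- function(f1, f2) {
  if (!identical(f1$root, f2$root)) return(FALSE)
  if (!setequal(f1$events, f2$events)) return(FALSE)
  o1 <- order(f1$events, method = "radix")
  o2 <- order(f2$events, method = "radix")
  identical(unname(f1$parent[o1]), unname(f2$parent[o2])) &&
    identical(f1$events[o1], f2$events[o2])
}
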