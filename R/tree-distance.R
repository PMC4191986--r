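# Flatten a progression forest (including its root node) to a canonically
# ordered tree in postorder. Children are sorted by label (radix/C-locale)
# so the ordered-tree edit distance is well defined on unordered
# progression trees. Returns list(labels, l) where l[i] is the postorder
# index of the leftmost leaf descendant of node i.
.canonical_postorder <- function(f) {
  labels <- character(0L)
  lml <- integer(0L)
  walk <- function(node) {
    kids <- sort(forest_children(f, node), method = "radix")
    first <- NA_integer_
    for (k in kids) {
      lk <- walk(k)
      if (is.na(first)) first <- lk
    }
    labels[length(labels) + 1L] <<- node
    me <- length(labels)
    lml[me] <<- if (is.na(first)) me else first
    lml[me]
  }
  walk(f$root)
  list(labels = labels, l = lml)
}

.keyroots <- function(l) {
  n <- length(l)
  which(vapply(seq_len(n), function(i)
    !any(l[seq_len(n) > i] == l[i]), logical(1L)))
}

#' Zhang-Shasha tree edit distance between progression forests
#'
#' The minimum number of node edit operations (relabel, delete, insert; all
#' unit cost) transforming one rooted tree into the other. Both forests are
#' compared as single rooted trees including their root node, with children
#' canonically sorted by label, so the result does not depend on any
#' incidental child ordering. Identical forests have distance 0 and the
#' function is a metric on canonicalized trees.
#'
#' @param t1,t2 [progression_forest()] objects sharing the same root label.
#' @return non-negative integer edit distance.
#' @export
tree_edit_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "progression_forest"),
            inherits(t2, "progression_forest"))
  if (!identical(t1$root, t2$root))
    stop("forests must share the same root label")
  a <- .canonical_postorder(t1)
  b <- .canonical_postorder(t2)
  n1 <- length(a$labels); n2 <- length(b$labels)
  TD <- matrix(0L, n1, n2)
  for (i in .keyroots(a$l)) {
    for (j in .keyroots(b$l)) {
      io <- a$l[i] - 1L; jo <- b$l[j] - 1L
      di <- i - io; dj <- j - jo
      fd <- matrix(0L, di + 1L, dj + 1L)
      for (x in seq_len(di)) fd[x + 1L, 1L] <- x
      for (y in seq_len(dj)) fd[1L, y + 1L] <- y
      for (x in seq_len(di)) {
        ii <- io + x
        for (y in seq_len(dj)) {
          jj <- jo + y
          if (a$l[ii] == a$l[i] && b$l[jj] == b$l[j]) {
            rc <- if (a$labels[ii] == b$labels[jj]) 0L else 1L
            fd[x + 1L, y + 1L] <- min(fd[x, y + 1L] + 1L,
                                      fd[x + 1L, y] + 1L,
                                      fd[x, y] + rc)
            TD[ii, jj] <- fd[x + 1L, y + 1L]
          } else {
            fd[x + 1L, y + 1L] <- min(fd[x, y + 1L] + 1L,
                                      fd[x + 1L, y] + 1L,
                                      fd[a$l[ii] - io, b$l[jj] - jo] +
                                        TD[ii, jj])
          }
        }
      }
    }
  }
  as.integer(TD[n1, n2])
}

#' Structural Hamming distance between progression forests
#'
#' Number of events whose (child, parent) assignment differs between the
#' two forests. Requires identical event sets (and root).
#'
#' @inheritParams tree_edit_distance
#' @export
structural_hamming <- function(t1, t2) {
  stopifnot(inherits(t1, "progression_forest"),
            inherits(t2, "progression_forest"))
  if (!identical(t1$root, t2$root))
    stop("forests must share the same root label")
  if (!setequal(t1$events, t2$events))
    stop("structural Hamming distance requires identical event sets")
  sum(vapply(t1$events, function(e)
    !identical(t1$parent[[e]], t2$parent[[e]]), logical(1L)))
}
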