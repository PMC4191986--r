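#' Default label for the synthetic root event
#'
#' The progression root is modelled as a special event adjoined to every
#' sample. The diamond glyph used for it in the literature is not file-safe,
#' so a plain ASCII label is used throughout and can be overridden in every
#' function that touches the root.
#' @export
DEFAULT_ROOT <- "DIAMOND_ROOT"

#' Construct a cross-sectional binary genotype matrix
#'
#' A genotype matrix records, for each of `m` samples (rows), which of `n`
#' genetic events (columns) were observed. Entries must be exactly 0 or 1;
#' missing values are not supported (the progression model assumes fully
#' observed binary data).
#'
#' @param data matrix coercible to integer 0/1; rows are samples, columns
#'   events.
#' @param events character vector of unique event labels (defaults to
#'   existing column names, else `e1..en`).
#' @param samples character vector of sample identifiers (defaults to
#'   existing row names, else `s1..sm`).
#' @return an integer matrix of class `genotype_matrix` with events as
#'   column names and samples as row names.
#' @export
genotype_matrix <- function(data, events = NULL, samples = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1L)
    stop("a genotype matrix needs at least one sample")
  if (is.logical(data))
    storage.mode(data) <- "integer"
  if (!is.numeric(data))
    stop("genotype entries must be numeric or logical 0/1")
  bad <- which(is.na(data) | !(data == 0L | data == 1L))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(data)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(data)) + 1L
    stop(sprintf("non-binary genotype cell at row %d, column %d: '%s'",
                 i, j, as.character(as.matrix(data)[i, j])))
  }
  storage.mode(data) <- "integer"
  if (is.null(events))
    events <- colnames(data)
  if (is.null(events))
    events <- if (ncol(data)) paste0("e", seq_len(ncol(data))) else character()
  events <- as.character(events)
  if (length(events) != ncol(data))
    stop("number of event labels must match number of columns")
  if (anyDuplicated(events))
    stop("duplicate event label(s): ",
         paste(unique(events[duplicated(events)]), collapse = ", "))
  if (is.null(samples))
    samples <- rownames(data)
  if (is.null(samples))
    samples <- paste0("s", seq_len(nrow(data)))
  dimnames(data) <- list(as.character(samples), events)
  class(data) <- c("genotype_matrix", class(data))
  data
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d events\n", nrow(x), ncol(x)))
  if (ncol(x)) {
    f <- colMeans(unclass(x))
    cat("event frequencies:\n")
    print(round(f, 3))
  }
  invisible(x)
}

events_of <- function(g) colnames(g)

#' Read a genotype matrix from a delimited text file
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param header logical; when `FALSE`, events are auto-named `e1..en`.
#' @param sample_col logical; when `TRUE` the first column holds sample
#'   identifiers rather than data.
#' @param logical_ok accept `TRUE`/`FALSE` cells in addition to 0/1.
#' @return a [genotype_matrix()]. Column order is preserved from the file.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "csv"), header = TRUE,
                           sample_col = FALSE, logical_ok = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("no such file: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  samples <- NULL
  if (sample_col) {
    samples <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  x <- as.matrix(df)
  parse_cell <- function(v) {
    v <- trimws(v)
    out <- rep(NA_integer_, length(v))
    out[v == "0"] <- 0L
    out[v == "1"] <- 1L
    if (logical_ok) {
      out[toupper(v) %in% c("TRUE", "T")] <- 1L
      out[toupper(v) %in% c("FALSE", "F")] <- 0L
    }
    out
  }
  xi <- matrix(parse_cell(x), nrow = nrow(x))
  if (anyNA(xi)) {
    bad <- which(is.na(xi))[1L]
    i <- ((bad - 1L) %% nrow(xi)) + 1L
    j <- ((bad - 1L) %/% nrow(xi)) + 1L
    lab <- if (header) colnames(df)[j] else paste0("e", j)
    stop(sprintf("cannot parse cell at data row %d, column '%s': '%s'",
                 i, lab, x[i, j]))
  }
  ev <- if (header) colnames(df) else NULL
  genotype_matrix(xi, events = ev, samples = samples)
}

#' Write a genotype matrix to a delimited text file
#'
#' Inverse of [read_genotypes()]: round-trips bit-exactly.
#' @inheritParams read_genotypes
#' @param g a [genotype_matrix()].
#' @export
write_genotypes <- function(g, path, dialect = c("tsv", "csv"),
                            sample_col = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  x <- unclass(g)
  df <- as.data.frame(x, check.names = FALSE)
  if (sample_col)
    df <- cbind(sample = rownames(x), df)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Adjoin the root event to every sample
#'
#' Adds one all-ones column for the special root event, which by construction
#' is present in every sample. Original columns are unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param root_label label for the root column; must not collide with an
#'   existing event.
#' @export
adjoin_root <- function(g, root_label = DEFAULT_ROOT) {
  if (root_label %in% events_of(g))
    stop("root label '", root_label, "' collides with an existing event")
  x <- cbind(unclass(g), rep(1L, nrow(g)))
  genotype_matrix(x, events = c(events_of(g), root_label),
                  samples = rownames(g))
}

#' Merge indistinguishable events
#'
#' Events whose observation columns are identical cannot be separated by any
#' probability-raising or correlation score and are collapsed into a single
#' composite event, labelled by concatenating the original labels.
#'
#' @param g a [genotype_matrix()].
#' @param sep separator for composite labels.
#' @return a list with elements `genotypes` (the merged matrix) and `merges`
#'   (a list of character vectors, one per composite event created; empty if
#'   all columns were distinct).
#' @export
merge_indistinguishable <- function(g, sep = "+") {
  if (ncol(g) == 0L)
    return(list(genotypes = g, merges = list()))
  key <- apply(unclass(g), 2L, paste0, collapse = "")
  grp <- split(seq_len(ncol(g)), factor(key, levels = unique(key)))
  merges <- list()
  keep <- integer()
  labels <- character()
  for (idx in grp) {
    keep <- c(keep, idx[1L])
    labs <- events_of(g)[idx]
    if (length(idx) > 1L)
      merges[[length(merges) + 1L]] <- labs
    labels <- c(labels, paste(labs, collapse = sep))
  }
  o <- order(keep)
  keep <- keep[o]
  labels <- labels[o]
  gm <- genotype_matrix(unclass(g)[, keep, drop = FALSE], events = labels,
                        samples = rownames(g))
  list(genotypes = gm, merges = merges)
}

#' Drop events observed in none or all samples
#'
#' Probability raising is undefined for events whose observed frequency is 0
#' or 1, so such columns are removed (default) or rejected (`strict = TRUE`).
#'
#' @param g a [genotype_matrix()].
#' @param strict error instead of dropping.
#' @param quiet suppress the warning listing dropped events.
#' @export
drop_degenerate_events <- function(g, strict = FALSE, quiet = FALSE) {
  cs <- colSums(unclass(g))
  bad <- which(cs == 0L | cs == nrow(g))
  if (!length(bad))
    return(g)
  labs <- events_of(g)[bad]
  if (strict)
    stop("event(s) observed in 0 or all samples: ",
         paste(labs, collapse = ", "))
  if (!quiet)
    warning("dropping event(s) observed in 0 or all samples: ",
            paste(labs, collapse = ", "), call. = FALSE)
  genotype_matrix(unclass(g)[, -bad, drop = FALSE],
                  events = events_of(g)[-bad], samples = rownames(g))
}
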