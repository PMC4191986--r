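.refit <- function(g, method, lambda, root_label) {
  if (method == "caprese")
    caprese_fit(g, lambda = lambda, root_label = root_label, quiet = TRUE)
  else
    oncotree_fit(g, root_label = root_label, quiet = TRUE)
}

.tally_bootstrap <- function(reference, fits, mode, error_rates = NULL) {
  n <- length(fits)
  exact <- 0L
  edge_counts <- list()
  for (f in fits) {
    if (is.null(f)) next  # refit failed: counts as non-match everywhere
    if (same_forest(reference, f)) exact <- exact + 1L
    for (e in f$events) {
      key <- paste0(f$parent[[e]], "\r", e)
      edge_counts[[key]] <- (edge_counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- names(edge_counts)
  # ensure every edge of the reference structure is reported, even at 0
  ref_keys <- paste0(reference$parent, "\r", reference$events)
  for (k in setdiff(ref_keys, keys)) edge_counts[[k]] <- 0L
  keys <- names(edge_counts)
  sp <- strsplit(keys, "\r", fixed = TRUE)
  ec <- data.frame(parent = vapply(sp, `[`, "", 1L),
                   child = vapply(sp, `[`, "", 2L),
                   count = unlist(edge_counts, use.names = FALSE))
  ec$confidence <- ec$count / n
  ec <- ec[order(ec$child, ec$parent, method = "radix"), , drop = FALSE]
  rownames(ec) <- NULL
  structure(list(mode = mode, n_resamples = n,
                 overall_confidence = exact / n,
                 edge_confidence = ec,
                 error_rates = error_rates,
                 fit = reference),
            class = "bootstrap_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%s bootstrap, %d resamples\n", x$mode, x$n_resamples))
  cat(sprintf("overall confidence (exact tree): %.3f\n",
              x$overall_confidence))
  invisible(x)
}

#' Non-parametric bootstrap confidence for a reconstruction
#'
#' Refits the chosen reconstruction method on `n_resamples` datasets drawn
#' by resampling the rows of `g` with replacement, and reports the fraction
#' of resamples reproducing the original tree exactly (overall confidence)
#' together with per-edge occurrence frequencies. Resamples with degenerate
#' or indistinguishable events are refit after the usual drop/merge
#' preprocessing; edges involving dropped events simply never match. A
#' resample on which the refit fails outright counts as a non-match for
#' every edge.
#'
#' @param g a [genotype_matrix()].
#' @param method `"caprese"` or `"oncotree"`.
#' @param lambda shrinkage coefficient (CAPRESE only).
#' @param n_resamples number of bootstrap resamples.
#' @param root_label root label.
#' @return object of class `bootstrap_result`: `overall_confidence`,
#'   `edge_confidence` (data frame parent/child/count/confidence; exact
#'   count ratios), `n_resamples`, `mode`, and the original `fit`.
#' @export
nonparametric_bootstrap <- function(g, method = c("caprese", "oncotree"),
                                    lambda = 0.5, n_resamples = 1000L,
                                    root_label = DEFAULT_ROOT) {
  method <- match.arg(method)
  stopifnot(n_resamples >= 1L)
  fit0 <- .refit(g, method, lambda, root_label)
  m <- nrow(g)
  fits <- vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(m, m, replace = TRUE)
    gr <- genotype_matrix(unclass(g)[idx, , drop = FALSE],
                          events = events_of(g))
    fits[[r]] <- tryCatch(.refit(gr, method, lambda, root_label),
                          error = function(e) NULL)
  }
  .tally_bootstrap(fit0, fits, "nonparametric")
}

#' Parametric bootstrap confidence for a progression forest
#'
#' Draws `n_resamples` synthetic datasets of `m` genotypes from the
#' tree-induced distribution of `f` (which must carry edge probabilities,
#' e.g. from [estimate_edge_probabilities()]), corrupts each with the
#' asymmetric noise channel at the given false positive/negative rates,
#' refits, and tallies exact-tree matches and per-edge occurrences against
#' `f`.
#'
#' @param f a [progression_forest()] with edge probabilities.
#' @param m number of genotypes per resample.
#' @param error_rates length-2 numeric `c(eps_plus, eps_minus)`.
#' @inheritParams nonparametric_bootstrap
#' @export
parametric_bootstrap <- function(f, m, error_rates = c(0, 0),
                                 method = c("caprese", "oncotree"),
                                 lambda = 0.5, n_resamples = 1000L) {
  method <- match.arg(method)
  stopifnot(n_resamples >= 1L, m >= 1L, length(error_rates) == 2L)
  noise <- if (all(error_rates == 0)) noise_spec("none")
           else noise_spec("asymmetric", eps_plus = error_rates[1L],
                           eps_minus = error_rates[2L])
  fits <- vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    gr <- apply_noise(sample_tree_distribution(f, m), noise)
    fits[[r]] <- tryCatch(.refit(gr, method, lambda, f$root),
                          error = function(e) NULL)
  }
  .tally_bootstrap(f, fits, "parametric", error_rates = error_rates)
}

#' Serialize a bootstrap result to JSON
#' @param b a `bootstrap_result`.
#' @param path output file.
#' @export
write_bootstrap_json <- function(b, path) {
  jsonlite::write_json(list(mode = b$mode, n_resamples = b$n_resamples,
                            overall_confidence = b$overall_confidence,
                            error_rates = b$error_rates,
                            edges = b$edge_confidence),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a parents-by-children edge-confidence table
#'
#' TSV matrix with one row per observed parent (the root included) and one
#' column per child; cells are bootstrap edge confidences (0 where the pair
#' never occurred).
#' @param b a `bootstrap_result`.
#' @param path output file.
#' @export
write_confidence_table <- function(b, path) {
  ec <- b$edge_confidence
  parents <- unique(c(b$fit$root, sort(unique(ec$parent), method = "radix")))
  children <- sort(unique(c(ec$child, b$fit$events)), method = "radix")
  M <- matrix(0, length(parents), length(children),
              dimnames = list(parents, children))
  M[cbind(ec$parent, ec$child)] <- ec$confidence
  df <- data.frame(parent = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
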