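#' Configuration for a simulation performance sweep
#'
#' Describes a factorial simulation study: random generating trees (or
#' forests), a grid of sample sizes, uniform-noise levels and shrinkage
#' coefficients, and the reconstruction methods to compare on identical
#' datasets. Defaults mirror the package's reference study: 100 generating
#' trees of 20 events, sample sizes 50 to 250 in steps of 50, and 10
#' replicate datasets per setting.
#'
#' @param sample_sizes integer vector of dataset sizes.
#' @param noise_levels numeric vector of uniform-noise rates `nu`.
#' @param lambdas numeric vector of shrinkage coefficients (CAPRESE).
#' @param n_trees_gen number of random generating trees.
#' @param n_events events per generating tree.
#' @param forest_components independent progression paths per generating
#'   tree (1 = trees, >1 = forests).
#' @param n_replicates independent datasets per (tree, size, noise)
#'   setting.
#' @param methods subset of `c("caprese", "oncotree")`.
#' @param seed master seed; all tree and dataset seeds derive from it.
#' @param prob_range,depth_cap forwarded to [generator_config()].
#' @export
sweep_config <- function(sample_sizes = seq(50L, 250L, 50L),
                         noise_levels = 0,
                         lambdas = 0.5,
                         n_trees_gen = 100L,
                         n_events = 20L,
                         forest_components = 1L,
                         n_replicates = 10L,
                         methods = c("caprese", "oncotree"),
                         seed = 1L,
                         prob_range = c(0.05, 0.95),
                         depth_cap = NULL) {
  stopifnot(length(sample_sizes) >= 1L, all(sample_sizes >= 1L),
            length(noise_levels) >= 1L, all(noise_levels >= 0),
            all(noise_levels < 1), length(lambdas) >= 1L,
            all(lambdas >= 0), all(lambdas <= 1),
            n_trees_gen >= 1L, n_replicates >= 1L,
            all(methods %in% c("caprese", "oncotree")),
            length(methods) >= 1L)
  structure(list(sample_sizes = as.integer(sample_sizes),
                 noise_levels = noise_levels, lambdas = lambdas,
                 n_trees_gen = as.integer(n_trees_gen),
                 n_events = as.integer(n_events),
                 forest_components = as.integer(forest_components),
                 n_replicates = as.integer(n_replicates),
                 methods = methods, seed = as.integer(seed),
                 prob_range = prob_range,
                 depth_cap = depth_cap),
            class = "sweep_config")
}

.cell_key <- function(tree, n, nu, rep, lambda, method) {
  sprintf("%d|%d|%g|%d|%g|%s", tree, n, nu, rep, lambda, method)
}

#' Run a full factorial reconstruction performance sweep
#'
#' For every generating tree, sample size, noise level and replicate, one
#' dataset is drawn with [sample_valid_dataset()] (tree-induced
#' distribution, uniform noise channel, algebraic requirements enforced by
#' redrawing); every requested method (and, for CAPRESE, every lambda)
#' is then fit on that same dataset and scored against the generating tree
#' with the tree edit distance and, when the event sets coincide, the
#' structural Hamming distance. All randomness derives from `cfg$seed`
#' through pre-drawn per-tree and per-dataset seeds, so results are
#' reproducible and, when `output` is given, the sweep is resumable: rows
#' already present in the output TSV are not recomputed.
#'
#' @param cfg a [sweep_config()].
#' @param output optional path to a TSV that is appended per dataset cell.
#' @param progress print a progress line per generating tree.
#' @return data frame with columns tree, n_samples, nu, lambda, method,
#'   replicate, ted, hamming, exact.
#' @export
performance_sweep <- function(cfg, output = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  set.seed(cfg$seed)
  tree_seeds <- sample.int(2147483646L, cfg$n_trees_gen)
  n_cells <- cfg$n_trees_gen * length(cfg$sample_sizes) *
    length(cfg$noise_levels) * cfg$n_replicates
  ds_seeds <- array(sample.int(2147483646L, n_cells),
                    dim = c(cfg$n_trees_gen, length(cfg$sample_sizes),
                            length(cfg$noise_levels), cfg$n_replicates))
  done <- character()
  prev <- NULL
  if (!is.null(output) && file.exists(output)) {
    prev <- utils::read.table(output, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    done <- with(prev, .cell_key(tree, n_samples, nu, replicate, lambda,
                                 method))
  }
  cols <- c("tree", "n_samples", "nu", "lambda", "method", "replicate",
            "ted", "hamming", "exact")
  rows <- list()
  for (t in seq_len(cfg$n_trees_gen)) {
    gcfg <- generator_config(n_events = cfg$n_events,
                             n_trees = cfg$forest_components,
                             depth_cap = cfg$depth_cap,
                             prob_range = cfg$prob_range,
                             n_samples = cfg$sample_sizes[1L],
                             seed = tree_seeds[t])
    truth <- random_tree(gcfg)
    for (si in seq_along(cfg$sample_sizes)) {
      n <- cfg$sample_sizes[si]
      for (vi in seq_along(cfg$noise_levels)) {
        nu <- cfg$noise_levels[vi]
        for (rep in seq_len(cfg$n_replicates)) {
          runs <- list()
          for (method in cfg$methods) {
            lams <- if (method == "caprese") cfg$lambdas else NA_real_
            for (lam in lams)
              if (!.cell_key(t, n, nu, rep, lam, method) %in% done)
                runs[[length(runs) + 1L]] <- list(method = method,
                                                  lambda = lam)
          }
          if (!length(runs)) next
          set.seed(ds_seeds[t, si, vi, rep])
          noise <- if (nu > 0) noise_spec("uniform", nu = nu)
                   else noise_spec("none")
          g <- sample_valid_dataset(truth, n, noise)
          for (run in runs) {
            fit <- tryCatch(
              if (run$method == "caprese")
                caprese_fit(g, lambda = run$lambda, quiet = TRUE)
              else oncotree_fit(g, quiet = TRUE),
              error = function(e) NULL)
            row <- data.frame(tree = t, n_samples = n, nu = nu,
                              lambda = run$lambda, method = run$method,
                              replicate = rep, ted = NA_integer_,
                              hamming = NA_integer_, exact = NA)
            if (!is.null(fit)) {
              row$ted <- tree_edit_distance(truth, fit)
              row$exact <- same_forest(truth, fit)
              if (setequal(truth$events, fit$events))
                row$hamming <- structural_hamming(truth, fit)
            }
            rows[[length(rows) + 1L]] <- row
            if (!is.null(output))
              utils::write.table(row, output, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = file.exists(output),
                                 col.names = !file.exists(output))
          }
        }
      }
    }
    if (progress)
      message(sprintf("sweep: tree %d/%d done", t, cfg$n_trees_gen))
  }
  new <- if (length(rows)) do.call(rbind, rows)
         else stats::setNames(data.frame(matrix(ncol = length(cols),
                                                nrow = 0L)), cols)
  if (!is.null(prev)) rbind(prev[cols], new) else new
}

#' Summarize a performance sweep
#'
#' Mean and standard deviation of the tree edit distance (and Hamming
#' distance where defined) per (sample size, noise, lambda, method) cell.
#'
#' @param df a [performance_sweep()] result.
#' @export
summarize_sweep <- function(df) {
  key <- list(n_samples = df$n_samples, nu = df$nu, lambda = df$lambda,
              method = df$method)
  key$lambda[is.na(key$lambda)] <- -1  # keep oncotree rows in one group
  agg <- stats::aggregate(
    data.frame(ted = df$ted, hamming = df$hamming),
    by = key,
    FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                        sd = stats::sd(x, na.rm = TRUE)))
  out <- data.frame(agg[c("n_samples", "nu", "lambda", "method")],
                    ted_mean = agg$ted[, "mean"], ted_sd = agg$ted[, "sd"],
                    hamming_mean = agg$hamming[, "mean"],
                    hamming_sd = agg$hamming[, "sd"])
  out$lambda[out$lambda < 0] <- NA_real_
  out[order(out$method, out$nu, out$lambda, out$n_samples), , drop = FALSE]
}
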