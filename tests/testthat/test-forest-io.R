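test_that("forest invariants are enforced by the constructor", {
  expect_error(progression_forest(c(a = "b", b = "a")), "cycle")
  expect_error(progression_forest(c(a = ROOT, b = "zz")), "unknown parent")
  expect_error(progression_forest(stats::setNames(c("x", ROOT), NULL)),
               "named")
  f <- progression_forest(c(a = ROOT, b = "a", c = "a"))
  expect_identical(sort(forest_children(f, "a")), c("b", "c"))
  expect_identical(forest_ancestors(f, "b"), "a")
  expect_identical(unname(forest_depths(f)), c(1L, 2L, 2L))
  expect_identical(forest_topological_order(f)[1], "a")
})

test_that("edge-list TSV round-trips a fitted forest", {
  fit <- caprese_fit(toy_matrix(), lambda = 0.5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(fit, tf)
  back <- read_edge_list(tf)
  expect_true(same_forest(fit, back))
  expect_equal(back$edge_prob, fit$edge_prob)
})

test_that("DOT output is deterministic and ordered by input events", {
  f <- progression_forest(c(b = ROOT, a = "b"))
  tf <- withr::local_tempfile(fileext = ".dot")
  write_dot(f, tf, event_order = c("b", "a"))
  lines <- readLines(tf)
  expect_identical(lines[1], "digraph progression {")
  expect_true(any(grepl("\"b\" -> \"a\"", lines)))
  # node statements follow the requested order
  node_lines <- grep("^  \"[ab]\";$", lines)
  expect_identical(lines[node_lines], c("  \"b\";", "  \"a\";"))
})

test_that("Newick output parses with ape and one line per progression path", {
  f <- progression_forest(c(a = ROOT, b = "a", c = "a", d = ROOT))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(f, tf)
  lines <- readLines(tf)
  expect_length(lines, 2L)  # two root children -> two trees
  tr <- ape::read.tree(text = lines[1])
  expect_setequal(c(tr$tip.label, tr$node.label), c("a", "b", "c"))
})

test_that("the command-line tool reconstructs, simulates and compares", {
  rscript <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("cli", "caprese.R", package = "caprese")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  toy <- file.path(dir, "toy.tsv")
  write_genotypes(toy_matrix(), toy)

  out <- file.path(dir, "fit")
  st <- system2(rscript, c(cli, "reconstruct", "--input", toy,
                           "--method", "caprese", "--lambda", "0.5",
                           "--output-prefix", out),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(paste0(out, ".edges.tsv")))
  fit <- read_edge_list(paste0(out, ".edges.tsv"))
  expect_identical(fit$parent[["a"]], ROOT)
  expect_identical(fit$parent[["b"]], "a")
  manifest <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_equal(manifest$lambda, 0.5)

  # invalid lambda is a usage error with non-zero exit
  st2 <- suppressWarnings(
    system2(rscript, c(cli, "reconstruct", "--input", toy,
                       "--lambda", "1.5"), stdout = TRUE, stderr = TRUE))
  expect_false(is.null(attr(st2, "status")))

  # simulate with a fixed seed is reproducible and truth round-trips
  sim1 <- file.path(dir, "s1"); sim2 <- file.path(dir, "s2")
  for (pre in c(sim1, sim2))
    system2(rscript, c(cli, "simulate", "--events", "6", "--samples", "30",
                       "--seed", "11", "--output-prefix", pre),
            stdout = FALSE, stderr = FALSE)
  expect_identical(readLines(paste0(sim1, ".tsv")),
                   readLines(paste0(sim2, ".tsv")))
  truth <- read_simulation_truth(paste0(sim1, ".truth.json"))
  expect_s3_class(truth, "progression_forest")

  # compare a forest with itself: both distances zero
  cmp <- system2(rscript, c(cli, "compare", paste0(out, ".edges.tsv"),
                            paste0(out, ".edges.tsv")),
                 stdout = TRUE, stderr = FALSE)
  expect_true(any(grepl("^ted\t0", cmp)))
  expect_true(any(grepl("^hamming\t0", cmp)))
})

test_that("the oncotree method is reachable from the command line", {
  rscript <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("cli", "caprese.R", package = "caprese")
  dir <- withr::local_tempdir()
  toy <- file.path(dir, "toy.tsv")
  write_genotypes(toy_matrix(), toy)
  out <- file.path(dir, "onco")
  system2(rscript, c(cli, "reconstruct", "--input", toy,
                     "--method", "oncotree", "--output-prefix", out),
          stdout = FALSE, stderr = FALSE)
  fit <- read_edge_list(paste0(out, ".edges.tsv"))
  expect_s3_class(validate_forest(fit), "progression_forest")
})
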