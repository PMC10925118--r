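# synthetic-data generators: ground truth, determinism, planted structure

test_that("make_network: heavy tails, module density, determinism", {
  spec <- synthetic_spec(n_genes = 500, module_size = 30, density_multiplier = 10,
                         attachment = 3, rng_seed = 1)
  tr <- make_network(spec)
  net <- tr$network
  expect_length(net$nodes, 500L)
  expect_length(tr$module, 30L)
  expect_gt(max(net$degree), 5 * stats::median(net$degree))  # heavy tail

  A <- adjacency_matrix(net)
  mod <- tr$module
  internal_mean <- mean(Matrix::rowSums(A[mod, mod]))
  # background within-group mean degree for random same-size sets
  set.seed(9)
  bg <- replicate(50, {
    s <- sample(net$nodes, 30)
    mean(Matrix::rowSums(A[s, s]))
  })
  expect_gte(internal_mean, 5 * mean(bg))

  tr2 <- make_network(spec)
  expect_identical(tr2$network, net)
  expect_identical(tr2$module, mod)

  expect_error(make_network(synthetic_spec(n_genes = 200, module_size = 20,
                                           density_multiplier = 1e6,
                                           rng_seed = 1)),
               "infeasible")
})

test_that("multiplier 1 plants nothing detectable", {
  spec <- synthetic_spec(n_genes = 400, module_size = 30, density_multiplier = 1,
                         rng_seed = 2)
  tr <- make_network(spec)
  A <- adjacency_matrix(tr$network)
  obs <- sum(A[tr$module, tr$module]) / 2
  set.seed(3)
  null_counts <- replicate(100, {
    s <- sample(tr$network$nodes, 30)
    sum(A[s, s]) / 2
  })
  band <- quantile(null_counts, c(0.005, 0.995))
  expect_gte(obs, band[1])
  expect_lte(obs, band[2])
})

test_that("seed tables: selection recovers exactly the planted sets", {
  spec <- synthetic_spec(n_genes = 600, module_size = 40, seeds_per_source = 15,
                         overlap = 1, rng_seed = 4)
  tr <- make_network(spec)
  tabs <- make_seed_tables(spec, tr)
  expect_setequal(select_common_seeds(tabs$common)$genes, tabs$seeds_common)
  expect_setequal(select_rare_seeds(tabs$rare, "lenient")$genes, tabs$seeds_rare)
  expect_true(all(tabs$seeds_common %in% tr$module))
  expect_true(all(tabs$seeds_rare %in% tr$module))

  # overlap 0: planted seeds disjoint from the module
  spec0 <- synthetic_spec(n_genes = 600, module_size = 40, seeds_per_source = 15,
                          overlap = 0, rng_seed = 5)
  tr0 <- make_network(spec0)
  tabs0 <- make_seed_tables(spec0, tr0)
  expect_length(intersect(tabs0$seeds_common, tr0$module), 0L)

  # determinism
  tabs2 <- make_seed_tables(spec, tr)
  expect_identical(tabs$common, tabs2$common)
  expect_identical(tabs$rare, tabs2$rare)

  expect_error(make_seed_tables(synthetic_spec(n_genes = 600, module_size = 10,
                                               seeds_per_source = 15,
                                               overlap = 1, rng_seed = 1),
                                tr),
               "more seeds than module")
})

test_that("lenient selection contains stringent on generated instances", {
  for (s in 1:20) {
    spec <- synthetic_spec(n_genes = 300, module_size = 25, seeds_per_source = 10,
                           rng_seed = s)
    tr <- make_network(spec)
    tabs <- make_seed_tables(spec, tr)
    len <- select_rare_seeds(tabs$rare, "lenient")$genes
    str <- tryCatch(select_rare_seeds(tabs$rare, "stringent")$genes,
                    error = function(e) character(0))
    expect_true(all(str %in% len))
  }
})

test_that("make_expression: planted recovery at lfc 2, empty at lfc 0, determinism", {
  genes <- sprintf("G%03d", 1:50)
  planted <- genes[1:12]
  truth <- c(list(t1 = planted),
             setNames(replicate(5, character(0), simplify = FALSE),
                      paste0("t", 2:6)))
  # 20 samples/label: per-gene Welch power at lfc 2, sd 1, Bonferroni/50 is
  # 0.99997 (noncentral t), so >= 95% recall is a real property; at 10/label
  # power is only ~0.89 and the assertion would be a coin flip
  ex <- make_expression(genes, truth, lfc = 2, n_per_label = 20, rng_seed = 6)
  deg <- call_deg(ex$expr)
  recall <- length(intersect(deg$t1$all, planted)) / length(planted)
  expect_gte(recall, 0.95)

  ex0 <- make_expression(genes[1:20], list(t1 = genes[1:5], t2 = character(0)),
                         lfc = 0, n_per_label = 10, rng_seed = 7)
  deg0 <- call_deg(ex0$expr)
  expect_equal(sum(lengths(lapply(deg0, `[[`, "all"))), 0L)

  ex2 <- make_expression(genes, truth, lfc = 2, n_per_label = 20, rng_seed = 6)
  expect_identical(ex$expr$values, ex2$expr$values)
  expect_error(make_expression(genes, truth, n_per_label = 1, rng_seed = 1),
               ">= 2")
})

test_that("simulate_fixture writes a complete, readable fixture directory", {
  dir <- file.path(tempdir(), "fixture_test")
  spec <- synthetic_spec(n_genes = 300, module_size = 25, seeds_per_source = 10,
                         rng_seed = 8)
  truth <- simulate_fixture(spec, dir, rng_seed = 8)
  files <- c("network.tsv", "scores_common.tsv", "scores_rare.tsv",
             "catalog.gmt", "expr.tsv", "labels.tsv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  net <- read_edge_list(file.path(dir, "network.tsv"), quiet = TRUE)
  expect_length(net$nodes, 300L)
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(tj$module, truth$module)
  cat_ <- read_gmt(file.path(dir, "catalog.gmt"))
  expect_setequal(cat_$sets$planted_module, truth$module)
  em <- read_expression(file.path(dir, "expr.tsv"), file.path(dir, "labels.tsv"))
  expect_equal(length(unique(em$labels)), 3L)
})
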