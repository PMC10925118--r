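# degree binning, null ensembles, NPS

test_that("degree binning follows the greedy >= min_bin_size rule", {
  net25 <- random_net(25, seed = 1)
  b <- degree_bins(net25, min_bin_size = 10)
  expect_equal(lengths(b$bins), c(10L, 15L))  # 10, 10, 5 -> merge -> 10, 15
  expect_setequal(unlist(b$bins), net25$nodes)

  net9 <- random_net(9, seed = 2)
  expect_equal(lengths(degree_bins(net9, 10)$bins), 9L)

  # bins are contiguous in sorted-degree order
  net <- random_net(63, seed = 3)
  b2 <- degree_bins(net, 10)
  maxdeg <- vapply(b2$bins, function(g) max(net$degree[g]), numeric(1))
  mindeg <- vapply(b2$bins, function(g) min(net$degree[g]), numeric(1))
  expect_true(all(head(maxdeg, -1) <= tail(mindeg, -1)))

  # regular graph: one degree class, arbitrary but valid split
  ring <- gene_network(cbind(sprintf("n%02d", 1:24), sprintf("n%02d", c(2:24, 1))),
                       quiet = TRUE)
  br <- degree_bins(ring, 10)
  expect_true(all(lengths(br$bins) >= 10))
})

test_that("null ensembles preserve size and bin membership, reproducibly", {
  net <- star_plus_ring()
  b <- degree_bins(net, 10)
  set.seed(1)
  seeds <- sample(net$nodes, 5)
  ens <- sample_null_seed_sets(net, seeds, b, R = 3, rng_seed = 11)
  expect_length(ens$sets, 3L)
  for (s in ens$sets) {
    expect_length(s, 5L)
    expect_length(unique(s), 5L)  # without replacement within a set
    # bin multiset matches the seeds' bin multiset
    expect_equal(sort(unname(b$bin_index[s])), sort(unname(b$bin_index[seeds])))
  }
  ens2 <- sample_null_seed_sets(net, seeds, b, R = 3, rng_seed = 11)
  expect_identical(ens$sets, ens2$sets)
  ens3 <- sample_null_seed_sets(net, seeds, b, R = 3, rng_seed = 12)
  expect_false(identical(ens$sets, ens3$sets))

  expect_error(sample_null_seed_sets(net, "nope", b, R = 2, rng_seed = 1),
               "not in network")
  # more seeds from one bin than the bin holds -> helpful error
  bi <- setNames(c(1L, 1L, 1L, rep(2L, length(net$nodes) - 3L)), net$nodes)
  tiny <- structure(list(bins = list(net$nodes[1:2], net$nodes[-(1:3)]),
                         bin_index = bi, min_bin_size = 2L),
                    class = "degree_binning")
  expect_error(sample_null_seed_sets(net, net$nodes[1:3], tiny,
                                     R = 2, rng_seed = 1),
               "larger")
})

test_that("z-score identities hold on controlled heats", {
  nz <- rwrcoloc:::.nps_from_heats
  obs <- c(a = 0.1, b = 0.2, c = 0.0)
  nullH <- rbind(c(0.1, 0.1, 0.1, 0.1),      # sd 0 at observed mean
                 c(0.1, 0.2, 0.3, 0.4),
                 c(0.5, 0.5, 0.5, 0.5))      # disconnected obs, constant null
  rownames(nullH) <- names(obs)
  expect_warning(z <- nz(obs, nullH), "zero null variance")
  expect_equal(unname(z["a"]), 0)        # equals null mean, but sd 0 -> 0
  expect_equal(unname(z["c"]), 0)        # zero-variance path

  # exact z = 2: observed log-heat = null mean + 2 * null sd
  lh <- c(-3, -2, -4, -1)
  mu <- mean(lh); sdv <- sd(lh)
  obs2 <- c(g = exp(mu + 2 * sdv))
  z2 <- nz(obs2, matrix(exp(lh), nrow = 1, dimnames = list("g", NULL)))
  expect_equal(unname(z2), 2, tolerance = 1e-12)

  expect_error(compute_nps(triangle_net(), "A", R = 1, rng_seed = 1), ">= 2")
})

test_that("compute_nps is deterministic under a fixed rng_seed", {
  net <- random_net(120, p = 4 / 120, seed = 5)
  set.seed(5)
  seeds <- sample(net$nodes, 8)
  z1 <- compute_nps(net, seeds, R = 30, rng_seed = 77)
  z2 <- compute_nps(net, seeds, R = 30, rng_seed = 77)
  expect_identical(z1, z2)
  expect_named(z1, net$nodes)
})

test_that("combine_nps: product, symmetry, universe checks", {
  a <- c(g1 = 2, g2 = -1, g3 = 0)
  b <- c(g1 = 1.5, g2 = 3, g3 = 7)
  tab <- combine_nps(a, b)
  expect_equal(tab$nps_combined, c(3, -3, 0))
  expect_equal(tab$nps_combined, tab$nps_common * tab$nps_rare)
  tab2 <- combine_nps(b, a)
  expect_equal(tab2$nps_combined, tab$nps_combined)
  expect_error(combine_nps(a, b[1:2]), "mismatch")
  expect_error(combine_nps(unname(a), b), "named")
})

test_that("consensus: bypass branch is exact, percentile and dominance behave", {
  net <- random_net(100, p = 4 / 100, seed = 6)
  set.seed(6)
  genes <- sample(net$nodes, 10)
  s <- seed_gene_set(genes, pvalues = setNames(rep(1e-8, 10), genes))
  z_direct <- compute_nps(net, s, R = 25, rng_seed = 3)
  z_cons <- consensus_nps(net, s, R = 25,
                          ccfg = consensus_config(max_seeds = 500),
                          rng_seed = 3)
  expect_equal(unname(z_cons[net$nodes]), unname(z_direct[net$nodes]))

  # subsampling branch: dominant -log10(p) weight appears in every subsample
  genes2 <- net$nodes[1:30]
  pv <- setNames(rep(0.5, 30), genes2)
  pv[genes2[1]] <- 1e-300
  s2 <- seed_gene_set(genes2, pvalues = pv)
  ccfg <- consensus_config(max_seeds = 5, n_subsamples = 6)
  z_sub <- consensus_nps(net, s2, R = 20, ccfg = ccfg, rng_seed = 4)
  expect_length(z_sub, length(net$nodes))
  # the dominant seed gene should carry a top consensus score
  expect_gt(z_sub[genes2[1]], quantile(z_sub, 0.95))

  # all weights zero -> error
  s3 <- seed_gene_set(genes2, pvalues = setNames(rep(1, 30), genes2))
  expect_error(consensus_nps(net, s3, R = 20, ccfg = ccfg, rng_seed = 4),
               "zero")
  # constant across repetitions -> percentile equals the constant
  expect_equal(unname(quantile(rep(1.23, 100), 0.75)), 1.23)
})

test_that("null calibration: random seed set scores near standard normal", {
  net <- random_net(300, p = 5 / 300, seed = 8)
  b <- degree_bins(net)
  ens <- sample_null_seed_sets(net, sample_null_seed_sets(
    net, net$nodes[1:10], b, R = 1, rng_seed = 1)$sets[[1]],
    b, R = 1, rng_seed = 2)
  obs_set <- ens$sets[[1]]
  z <- compute_nps(net, obs_set, R = 500, rng_seed = 21)
  expect_lt(abs(mean(z)), 0.2)
})
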