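# network extraction and permutation significance

make_npst <- function(c_, r_, genes = sprintf("g%02d", seq_along(c_))) {
  combine_nps(setNames(c_, genes), setNames(r_, genes))
}

test_that("threshold extraction: strict AND over the three rules", {
  # (2, 2): product 4 -> in; (4, 1): fails rare; (1.6, 1.6): product 2.56 -> out
  npst <- make_npst(c(2, 4, 1.6), c(2, 1, 1.6), genes = c("A", "B", "C"))
  net <- triangle_net()
  ext <- extract_network(npst, net)
  expect_equal(ext$genes, "A")
  expect_equal(ext$subgraph$nodes, "A")
  expect_equal(nrow(ext$subgraph$edges), 0L)

  # empty selection is a size-0 result, not an error
  npst0 <- make_npst(c(0, 0, 0), c(0, 0, 0), genes = c("A", "B", "C"))
  ext0 <- extract_network(npst0, net)
  expect_length(ext0$genes, 0L)
  expect_null(ext0$subgraph)

  # induced edges are network edges
  nps_all <- make_npst(c(3, 3, 3), c(3, 3, 3), genes = c("A", "B", "C"))
  ext_all <- extract_network(nps_all, net)
  expect_equal(nrow(ext_all$subgraph$edges), 3L)

  expect_error(extract_network(make_npst(1, 1, genes = "A"), net), "cover")
})

test_that("Z-test identities and the degenerate sd = 0 path", {
  zt <- rwrcoloc:::.ztest_upper
  r <- zt(5, c(4, 5, 6))
  expect_equal(r$z, 0)
  expect_equal(r$p, 0.5)
  expect_warning(r0 <- zt(1, c(2, 2, 2)), "sd.*0")
  expect_true(is.na(r0$p))

  # constant NPS vectors: every permutation identical -> NA path (both the
  # size and the mean statistic warn)
  npst <- make_npst(rep(2, 6), rep(2, 6))
  w <- capture_warnings(
    res <- permutation_test(npst, cfg = coloc_config(n_permutations = 200,
                                                     rng_seed = 1)))
  expect_true(any(grepl("sd", w)))
  expect_true(is.na(res$size_p))
  expect_true(is.na(res$mean_p))
})

# exhaustive oracle over all label pairings of both vectors
perm_oracle <- function(c_, r_, cfg) {
  n <- length(c_)
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], Recall(v[-i])))
    out
  }
  P <- perms(seq_len(n))
  sizes <- numeric(nrow(P)^2); means <- numeric(nrow(P)^2)
  k <- 0L
  for (i in seq_len(nrow(P))) {
    cp <- c_[P[i, ]]
    for (j in seq_len(nrow(P))) {
      rp <- r_[P[j, ]]
      k <- k + 1L
      sizes[k] <- sum(cp * rp > cfg$combined_min & cp > cfg$common_min &
                        rp > cfg$rare_min)
      means[k] <- mean(cp * rp)
    }
  }
  list(sizes = sizes, means = means)
}

test_that("sampled permutation null matches exhaustive enumeration (n <= 6)", {
  for (n in c(3L, 5L, 6L)) {
    set.seed(n)
    c_ <- round(rnorm(n, 1, 1.5), 2)
    r_ <- round(rnorm(n, 1, 1.5), 2)
    npst <- make_npst(c_, r_)
    cfg <- coloc_config(n_permutations = 4000, rng_seed = 100 + n)
    # tiny universes can have a degenerate (all-equal) size null; the sd
    # warning is expected there and not under test
    res <- suppressWarnings(permutation_test(npst, cfg = cfg))
    orc <- perm_oracle(c_, r_, cfg)
    mc_tol_size <- 4 * sd(orc$sizes) / sqrt(cfg$n_permutations)
    mc_tol_mean <- 4 * sd(orc$means) / sqrt(cfg$n_permutations)
    expect_lt(abs(res$size_null_mean - mean(orc$sizes)), max(mc_tol_size, 1e-9))
    expect_lt(abs(res$mean_null_mean - mean(orc$means)), max(mc_tol_mean, 1e-9))
    expect_lt(abs(res$size_null_sd - sd(orc$sizes)), 0.15 * max(sd(orc$sizes), 0.1))
    expect_lt(abs(res$mean_null_sd - sd(orc$means)), 0.15 * max(sd(orc$means), 0.01))
  }
})

test_that("shared genes are permuted strictly within their stratum", {
  # 2 shared genes with huge scores; 4 non-shared with small ones. If strata
  # are respected, the shared values never land on non-shared genes, so the
  # null size never drops below the always-passing shared pair.
  c_ <- c(10, 10, 0.1, 0.2, 0.1, 0.2)
  r_ <- c(10, 10, 0.1, 0.1, 0.2, 0.2)
  npst <- make_npst(c_, r_)
  shared <- npst$gene[npst$nps_common == 10]
  res <- suppressWarnings(  # constant null size -> expected sd warning
    permutation_test(npst, shared_genes = shared,
                     cfg = coloc_config(n_permutations = 500, rng_seed = 3)))
  expect_true(all(res$null_sizes == 2L))
  # whereas without the stratum the shared scores scatter
  res2 <- permutation_test(npst, cfg = coloc_config(n_permutations = 500,
                                                    rng_seed = 3))
  expect_true(any(res2$null_sizes < 2L))
  expect_error(permutation_test(npst, shared_genes = "nope",
                                cfg = coloc_config(rng_seed = 1)),
               "not in NPS table")
})

test_that("permutation test is reproducible and reports ratio machinery", {
  set.seed(42)
  npst <- make_npst(rnorm(40, 1, 1.2), rnorm(40, 1, 1.2))
  cfg <- coloc_config(n_permutations = 300, rng_seed = 5)
  a <- permutation_test(npst, cfg = cfg)
  b <- permutation_test(npst, cfg = cfg)
  expect_identical(a, b)
  expect_equal(a$ratio, a$size / mean(a$null_sizes))
  expect_equal(a$ratio_ci,
               unname(quantile(a$null_sizes, c(0.025, 0.975)) /
                        mean(a$null_sizes)))
  expect_true(a$size_p > 0 && a$size_p < 1)
})
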