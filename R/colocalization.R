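# Colocalized-network extraction and permutation significance.
#
# A gene is in the colocalized network iff it clears all three thresholds
# (strict >): nps_combined > combined_min, nps_common > common_min,
# nps_rare > rare_min. Seed genes receive no exemption. Significance of
# the network size and of the mean combined score is assessed by label
# permutation: each permutation re-assigns the nps_common values among
# genes and, independently, the nps_rare values, and the observed
# statistics are compared with the permutation distribution by a Z-test
# (one-sided, upper tail — the hypothesis is colocalization excess).
# Genes that were seeds in BOTH inputs are permuted strictly within their
# own stratum, preserving the higher score distribution expected there.

#' Colocalization configuration
#'
#' @param combined_min threshold on `nps_combined` (default 3).
#' @param common_min threshold on `nps_common` (default 1.5).
#' @param rare_min threshold on `nps_rare` (default 1.5).
#' @param n_permutations label permutations for the null (default 10000).
#' @param rng_seed integer RNG seed for the permutations.
#' @return list of class `coloc_config`.
#' @export
coloc_config <- function(combined_min = 3, common_min = 1.5, rare_min = 1.5,
                         n_permutations = 10000L, rng_seed = NULL) {
  stopifnot(is.finite(combined_min), is.finite(common_min), is.finite(rare_min),
            n_permutations >= 100)
  structure(list(combined_min = combined_min, common_min = common_min,
                 rare_min = rare_min,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = rng_seed),
            class = "coloc_config")
}

.coloc_pass <- function(c_, r_, cfg) {
  (c_ * r_) > cfg$combined_min & c_ > cfg$common_min & r_ > cfg$rare_min
}

#' Extract the colocalized network
#'
#' @param npst an `nps_table` from [combine_nps()]; must cover the network
#'   genes.
#' @param network a [gene_network()].
#' @param cfg a [coloc_config()].
#' @return list with `genes` (selected symbols, possibly empty — an empty
#'   selection is a valid size-0 result, not an error) and `subgraph`
#'   (the induced [gene_network()], or NULL when empty).
#' @export
extract_network <- function(npst, network, cfg = coloc_config()) {
  stopifnot(inherits(npst, "nps_table"), inherits(network, "gene_network"))
  missing <- setdiff(network$nodes, npst$gene)
  if (length(missing))
    stop("NPS table does not cover ", length(missing), " network gene(s)")
  pass <- .coloc_pass(npst$nps_common, npst$nps_rare, cfg)
  genes <- intersect(npst$gene[pass], network$nodes)
  sub <- if (length(genes)) induced_subgraph(network, genes) else NULL
  list(genes = genes, subgraph = sub)
}

# One-sided upper-tail Z-test of an observed statistic against a null
# sample. Returns list(z, p); sd 0 -> NA with warning.
.ztest_upper <- function(observed, null_values, what = "statistic") {
  mu <- mean(null_values); sdv <- sd(null_values)
  if (!is.finite(sdv) || sdv == 0) {
    warning(sprintf("null sd of %s is 0; p reported as NA", what))
    return(list(z = NA_real_, p = NA_real_, null_mean = mu, null_sd = sdv))
  }
  z <- (observed - mu) / sdv
  list(z = z, p = pnorm(z, lower.tail = FALSE), null_mean = mu, null_sd = sdv)
}

#' Permutation test of colocalized-network size and mean score
#'
#' Each of `n_permutations` permutations independently shuffles the
#' assignment of `nps_common` values among non-shared genes and, in a
#' separate stratum, among `shared_genes` (and likewise, independently,
#' for `nps_rare`); the network size (genes passing all thresholds) and
#' the mean `nps_common * nps_rare` across all genes are recomputed each
#' time. A stratum of size 1 is left fixed by every permutation.
#'
#' @param npst an `nps_table`.
#' @param shared_genes genes that were seeds in both inputs (permuted
#'   within their own stratum); may be empty.
#' @param cfg a [coloc_config()] (its `rng_seed` drives the permutations
#'   and is required).
#' @return object of class `coloc_result`: list with observed `size` and
#'   `mean_score`, per-statistic null mean/sd, `size_z`, `size_p`,
#'   `mean_z`, `mean_p` (one-sided upper tail), the observed-to-expected
#'   size `ratio`, its 95% interval `ratio_ci` (2.5th/97.5th percentiles
#'   of the null size distribution divided by the null mean size), and the
#'   vector of null sizes.
#' @export
permutation_test <- function(npst, shared_genes = character(0),
                             cfg = coloc_config()) {
  stopifnot(inherits(npst, "nps_table"))
  if (is.null(cfg$rng_seed)) stop("cfg$rng_seed is required for the permutation test")
  unknown <- setdiff(shared_genes, npst$gene)
  if (length(unknown))
    stop("shared_genes not in NPS table: ", paste(head(unknown, 5L), collapse = ", "))
  n <- nrow(npst)
  is_shared <- npst$gene %in% shared_genes
  idx_sh <- which(is_shared); idx_ns <- which(!is_shared)
  c_ <- npst$nps_common; r_ <- npst$nps_rare

  obs_size <- sum(.coloc_pass(c_, r_, cfg))
  obs_mean <- mean(c_ * r_)

  set.seed(as.integer(cfg$rng_seed))
  B <- cfg$n_permutations
  null_size <- integer(B); null_mean <- numeric(B)
  perm_within <- function(values, i1, i2) {
    out <- values
    if (length(i1) > 1L) out[i1] <- values[i1[sample.int(length(i1))]]
    if (length(i2) > 1L) out[i2] <- values[i2[sample.int(length(i2))]]
    out
  }
  for (b in seq_len(B)) {
    cp <- perm_within(c_, idx_ns, idx_sh)
    rp <- perm_within(r_, idx_ns, idx_sh)
    null_size[b] <- sum(.coloc_pass(cp, rp, cfg))
    null_mean[b] <- mean(cp * rp)
  }
  zs <- .ztest_upper(obs_size, null_size, "network size")
  zm <- .ztest_upper(obs_mean, null_mean, "mean score")
  mu_size <- mean(null_size)
  ratio <- if (mu_size > 0) obs_size / mu_size else NA_real_
  ratio_ci <- if (mu_size > 0)
    unname(quantile(null_size, c(0.025, 0.975)) / mu_size) else c(NA_real_, NA_real_)
  structure(list(size = obs_size, mean_score = obs_mean,
                 size_null_mean = zs$null_mean, size_null_sd = zs$null_sd,
                 mean_null_mean = zm$null_mean, mean_null_sd = zm$null_sd,
                 size_z = zs$z, size_p = zs$p,
                 mean_z = zm$z, mean_p = zm$p,
                 ratio = ratio, ratio_ci = ratio_ci,
                 null_sizes = null_size,
                 n_permutations = B, rng_seed = as.integer(cfg$rng_seed)),
            class = "coloc_result")
}

#' @method print coloc_result
#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization: size %d (null %.2f +/- %.2f, z = %.2f, p = %.3g)\n",
              x$size, x$size_null_mean, x$size_null_sd, x$size_z, x$size_p))
  cat(sprintf("  mean score %.4f (null %.4f +/- %.4f, z = %.2f, p = %.3g)\n",
              x$mean_score, x$mean_null_mean, x$mean_null_sd, x$mean_z, x$mean_p))
  cat(sprintf("  observed/expected size ratio %.2f [%.2f, %.2f]\n",
              x$ratio, x$ratio_ci[1], x$ratio_ci[2]))
  invisible(x)
}
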