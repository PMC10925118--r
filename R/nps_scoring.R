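# Network proximity scores (NPS).
#
# The observed heat at each gene is compared with a null distribution of
# heats from degree-matched random seed sets: genes are binned by degree
# (>= 10 nodes per bin), each null set replaces every seed by a uniform
# draw from that seed's bin, and the NPS is the z-score of the observed
# log-heat against the null log-heats at the same gene. Log transformation
# makes the heavily right-skewed heat distributions approximately normal;
# heats are clamped at a small positive floor before the log so that
# disconnected genes (heat exactly 0) remain finite.

.HEAT_FLOOR <- 1e-12

#' Bin network genes by degree
#'
#' Nodes are sorted by degree (ties broken by symbol for determinism) and
#' greedily grouped into consecutive bins of `min_bin_size`; a final
#' undersized bin is merged into its predecessor. Networks smaller than
#' `min_bin_size` form a single bin. Equal-degree nodes may straddle a bin
#' boundary; within a degree class the assignment is arbitrary but fixed,
#' and sampling within the class is then effectively uniform.
#'
#' @param network a [gene_network()].
#' @param min_bin_size minimum genes per bin (default 10).
#' @return object of class `degree_binning`: list with `bins` (list of
#'   character vectors partitioning the nodes) and `bin_index` (named
#'   integer vector, gene -> bin).
#' @export
degree_bins <- function(network, min_bin_size = 10L) {
  stopifnot(inherits(network, "gene_network"), min_bin_size >= 1)
  nodes <- network$nodes[order(network$degree, network$nodes, method = "radix")]
  n <- length(nodes)
  n_bins <- max(1L, n %/% min_bin_size)
  sizes <- rep(min_bin_size, n_bins)
  sizes[n_bins] <- n - min_bin_size * (n_bins - 1L)  # remainder merged into last
  idx <- rep(seq_len(n_bins), times = sizes)
  bins <- split(nodes, idx)
  names(bins) <- NULL
  bin_index <- setNames(rep(seq_len(n_bins), times = sizes), nodes)
  structure(list(bins = bins, bin_index = bin_index[network$nodes],
                 min_bin_size = as.integer(min_bin_size)),
            class = "degree_binning")
}

#' Sample degree-matched null seed sets
#'
#' Draws `R` random seed sets that preserve the size and degree distribution
#' of the original set: each original seed is replaced by a uniform draw
#' from its own degree bin, without replacement within one null set. Null
#' sets may overlap the original seeds (no exclusion).
#'
#' @param network a [gene_network()].
#' @param seeds a [seed_gene_set()] or character vector, subset of network
#'   nodes.
#' @param binning a [degree_bins()] result for `network`.
#' @param R number of null sets (default 1000).
#' @param rng_seed integer RNG seed; required for reproducibility.
#' @return object of class `null_ensemble`: list with `sets` (list of R
#'   character vectors), `seed_bins` (bin index of each original seed),
#'   `R`, `rng_seed`.
#' @export
sample_null_seed_sets <- function(network, seeds, binning = degree_bins(network),
                                  R = 1000L, rng_seed) {
  stopifnot(inherits(network, "gene_network"), inherits(binning, "degree_binning"))
  seed_genes <- if (inherits(seeds, "seed_gene_set")) seeds$genes else as.character(seeds)
  if (!all(seed_genes %in% network$nodes))
    stop("seeds not in network: ",
         paste(head(setdiff(seed_genes, network$nodes), 5L), collapse = ", "))
  if (missing(rng_seed) || is.null(rng_seed)) stop("rng_seed is required")
  sb <- binning$bin_index[seed_genes]
  counts <- table(sb)
  short <- names(counts)[counts > lengths(binning$bins)[as.integer(names(counts))]]
  if (length(short))
    stop("degree bin(s) ", paste(short, collapse = ", "),
         " are smaller than the number of seeds they must supply; ",
         "use a larger min_bin_size")
  set.seed(as.integer(rng_seed))
  bin_of <- as.integer(names(counts))
  need <- as.integer(counts)
  sets <- vector("list", R)
  for (r in seq_len(R)) {
    drawn <- character(0)
    for (k in seq_along(bin_of)) {
      pool <- binning$bins[[bin_of[k]]]
      drawn <- c(drawn, pool[sample.int(length(pool), need[k])])
    }
    sets[[r]] <- drawn
  }
  structure(list(sets = sets, seed_bins = sb, R = as.integer(R),
                 rng_seed = as.integer(rng_seed)),
            class = "null_ensemble")
}

# z-scores of observed log-heats against per-gene null log-heat moments.
# obs: named heat vector; null_heats: genes x R matrix. Exposed for direct
# testing of the z identities.
.nps_from_heats <- function(obs, null_heats, floor = .HEAT_FLOOR) {
  stopifnot(length(obs) == nrow(null_heats))
  lo <- log(pmax(as.numeric(obs), floor))
  L <- log(pmax(null_heats, floor))
  mu <- rowMeans(L)
  R <- ncol(L)
  if (R < 2L) stop("need at least 2 null propagations for a variance")
  sdv <- sqrt(rowSums((L - mu)^2) / (R - 1L))
  z <- (lo - mu) / sdv
  degen <- sdv == 0
  if (any(degen)) {
    warning(sprintf("%d gene(s) with zero null variance: NPS set to 0", sum(degen)))
    z[degen] <- 0
  }
  setNames(z, names(obs))
}

#' Compute network proximity scores for a seed set
#'
#' Propagates the observed seed set and `R` degree-matched null sets, then
#' scores each gene as
#' `NPS_g = (log h_g - mean_r log h_g^(r)) / sd_r(log h_g^(r))`
#' with the sample standard deviation (R - 1 denominator). Heats below
#' `1e-12` are clamped before the log. Genes whose null heats are constant
#' (zero variance, e.g. genes disconnected from every null set) get NPS 0
#' with a warning.
#'
#' @param network a [gene_network()].
#' @param seeds a [seed_gene_set()] or character vector.
#' @param R number of null seed sets (default 1000).
#' @param cfg a [propagation_config()].
#' @param rng_seed integer RNG seed (required).
#' @param binning optional precomputed [degree_bins()].
#' @return named numeric vector of NPS over all network genes, with
#'   attributes `R`, `rng_seed`, `alpha`.
#' @export
compute_nps <- function(network, seeds, R = 1000L, cfg = propagation_config(),
                        rng_seed, binning = NULL) {
  if (R < 2L) stop("R must be >= 2 (null variance undefined otherwise)")
  if (is.null(binning)) binning <- degree_bins(network)
  ens <- sample_null_seed_sets(network, seeds, binning, R = R, rng_seed = rng_seed)
  obs <- propagate(network, seeds, cfg)
  H <- .propagate_many(network, ens$sets, cfg)
  z <- .nps_from_heats(unclass(obs), H)
  attr(z, "R") <- as.integer(R)
  attr(z, "rng_seed") <- as.integer(rng_seed)
  attr(z, "alpha") <- cfg$alpha
  z
}

#' Combine common and rare NPS vectors into an NPS table
#'
#' The combined score is the elementwise product
#' `nps_combined = nps_common * nps_rare`; negative products are possible
#' and retained (a gene anti-proximal to one source is not colocalized).
#'
#' @param nps_common,nps_rare named numeric vectors over the same gene
#'   universe (any order).
#' @return data frame of class `nps_table` with columns `gene`,
#'   `nps_common`, `nps_rare`, `nps_combined`.
#' @export
combine_nps <- function(nps_common, nps_rare) {
  gc <- names(nps_common); gr <- names(nps_rare)
  if (is.null(gc) || is.null(gr)) stop("NPS vectors must be named by gene")
  if (length(setdiff(gc, gr)) || length(setdiff(gr, gc)))
    stop(sprintf("gene universe mismatch: %d genes only in common, %d only in rare",
                 length(setdiff(gc, gr)), length(setdiff(gr, gc))))
  genes <- sort(gc, method = "radix")
  c_ <- as.numeric(nps_common[genes]); r_ <- as.numeric(nps_rare[genes])
  out <- data.frame(gene = genes, nps_common = c_, nps_rare = r_,
                    nps_combined = c_ * r_, stringsAsFactors = FALSE)
  class(out) <- c("nps_table", "data.frame")
  out
}

#' Consensus configuration for oversized seed sets
#'
#' Propagation nulls are calibrated for moderate seed counts relative to
#' the network (~500 seeds against an ~18,000-gene interactome); larger
#' significant-gene sets are handled by repeated weighted subsampling.
#'
#' @param max_seeds largest seed set propagated directly (default 500).
#' @param n_subsamples number of weighted subsamples (default 100).
#' @param percentile per-gene percentile of the subsample NPS distribution
#'   reported as the consensus (default 75), linear interpolation.
#' @return list of class `consensus_config`.
#' @export
consensus_config <- function(max_seeds = 500L, n_subsamples = 100L,
                             percentile = 75) {
  stopifnot(percentile > 0, percentile < 100, max_seeds >= 1, n_subsamples >= 1)
  structure(list(max_seeds = as.integer(max_seeds),
                 n_subsamples = as.integer(n_subsamples),
                 percentile = percentile),
            class = "consensus_config")
}

#' Consensus NPS by weighted seed subsampling
#'
#' If the significant-gene set has at most `max_seeds` members the result
#' is exactly [compute_nps()] on the full set. Otherwise `n_subsamples`
#' subsets of `max_seeds` genes are drawn without replacement with
#' probability proportional to `-log10(p)`, NPS is computed for each, and
#' the per-gene consensus is the `percentile` value across subsamples.
#'
#' @param network a [gene_network()].
#' @param seeds a [seed_gene_set()] carrying per-gene p-values (required
#'   when subsampling is triggered).
#' @param R null sets per NPS computation.
#' @param cfg a [propagation_config()].
#' @param ccfg a [consensus_config()].
#' @param rng_seed integer RNG seed (required).
#' @return named numeric NPS vector over all network genes.
#' @export
consensus_nps <- function(network, seeds, R = 1000L, cfg = propagation_config(),
                          ccfg = consensus_config(), rng_seed) {
  stopifnot(inherits(seeds, "seed_gene_set"))
  if (length(seeds$genes) <= ccfg$max_seeds)
    return(compute_nps(network, seeds, R = R, cfg = cfg, rng_seed = rng_seed))
  if (is.null(seeds$pvalues))
    stop("consensus subsampling needs per-gene p-values for -log10(p) weights")
  w <- -log10(seeds$pvalues[seeds$genes])
  if (all(w == 0)) stop("all subsampling weights are zero (all p = 1)")
  binning <- degree_bins(network)
  Z <- matrix(NA_real_, nrow = length(network$nodes), ncol = ccfg$n_subsamples,
              dimnames = list(network$nodes, NULL))
  base_seed <- as.integer(rng_seed)
  for (s in seq_len(ccfg$n_subsamples)) {
    sub_seed <- (base_seed + 7919L * s) %% .Machine$integer.max
    set.seed(sub_seed)
    pick <- sample(seeds$genes, ccfg$max_seeds, replace = FALSE, prob = w)
    Z[, s] <- compute_nps(network, pick, R = R, cfg = cfg,
                          rng_seed = (sub_seed + 1L) %% .Machine$integer.max,
                          binning = binning)
  }
  q <- apply(Z, 1L, quantile, probs = ccfg$percentile / 100, names = FALSE,
             type = 7)
  out <- setNames(q, network$nodes)
  attr(out, "n_subsamples") <- ccfg$n_subsamples
  attr(out, "percentile") <- ccfg$percentile
  out
}
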