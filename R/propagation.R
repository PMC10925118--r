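# Random walk with restart over the gene network.
#
# Fixed point of  F = (1 - alpha) * F0 + alpha * W %*% F  with
#   W = A D^-1  (column-stochastic: each node splits its heat equally
#                among its neighbors)
#   F0 = uniform indicator over the seeds, total mass 1 (1/|S| per seed).
# The walk conserves probability, so heats sum to 1 whenever every node
# reachable from the seeds has degree >= 1. Degree-0 nodes are excluded
# from the transition system: valid non-seed genes with heat exactly 0,
# invalid as seeds.

#' Propagation configuration
#'
#' @param alpha mixing weight in (0, 1): the fraction of heat that follows
#'   network edges each step; `1 - alpha` restarts at the seeds. Default 0.5.
#' @param tol convergence tolerance on the maximum absolute change between
#'   iterations (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return list of class `propagation_config`. The transition normalization
#'   is fixed to the degree-normalized column-stochastic convention; the
#'   symmetric-normalized variant is deliberately not offered, to avoid
#'   silent convention drift.
#' @export
propagation_config <- function(alpha = 0.5, tol = 1e-10, max_iter = 10000L) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 normalization = "degree-column-stochastic"),
            class = "propagation_config")
}

# Build the column-stochastic transition operator restricted to
# degree-positive nodes. Returns list(W, active_idx, nodes).
.transition_operator <- function(network) {
  deg <- network$degree
  active <- which(deg > 0L)
  A <- adjacency_matrix(network)[active, active, drop = FALSE]
  W <- A %*% Matrix::Diagonal(x = 1 / deg[active])
  list(W = W, active = active)
}

.seed_vector <- function(network, seed_genes, active) {
  n <- length(network$nodes)
  idx <- match(seed_genes, network$nodes)
  if (anyNA(idx))
    stop("seed gene(s) not in network: ",
         paste(head(seed_genes[is.na(idx)], 5L), collapse = ", "))
  deg0 <- seed_genes[network$degree[idx] == 0L]
  if (length(deg0))
    stop("degree-0 seed gene(s) have no outgoing transitions: ",
         paste(head(deg0, 5L), collapse = ", "))
  f0 <- numeric(n)
  f0[idx] <- 1 / length(idx)
  f0
}

# Core fixed-point iteration on a matrix of restart distributions
# (one column per seed set), restricted to active nodes. Jacobi-style
# updates from F0; deterministic.
.rwr_iterate <- function(W, F0, alpha, tol, max_iter) {
  Fk <- F0
  base <- (1 - alpha) * F0
  for (it in seq_len(max_iter)) {
    Fn <- base + alpha * as.matrix(W %*% Fk)
    if (max(abs(Fn - Fk)) < tol) return(Fn)
    Fk <- Fn
  }
  warning(sprintf("RWR did not reach tol %g in %d iterations", tol, max_iter))
  Fk
}

#' Network propagation by random walk with restart
#'
#' Iteratively solves the RWR fixed point from a seed set. Heat measures
#' network proximity to the seeds: seeds retain at least `(1 - alpha)/|S|`
#' mass, and genes disconnected from all seeds receive exactly 0.
#'
#' @param network a [gene_network()].
#' @param seeds a [seed_gene_set()] or character vector of seed symbols;
#'   all must be network nodes with degree >= 1.
#' @param cfg a [propagation_config()].
#' @return object of class `heat_vector`: named numeric vector of heats over
#'   all network nodes with attributes `seed_name` and `config`.
#' @seealso [propagate_exact()] for the dense linear-solve oracle.
#' @export
propagate <- function(network, seeds, cfg = propagation_config()) {
  stopifnot(inherits(network, "gene_network"))
  seed_genes <- if (inherits(seeds, "seed_gene_set")) seeds$genes else as.character(seeds)
  if (length(seed_genes) == 0L) stop("no seed genes")
  op <- .transition_operator(network)
  f0 <- .seed_vector(network, seed_genes, op$active)
  Fa <- .rwr_iterate(op$W, matrix(f0[op$active], ncol = 1L),
                     cfg$alpha, cfg$tol, cfg$max_iter)
  heat <- setNames(numeric(length(network$nodes)), network$nodes)
  heat[op$active] <- Fa[, 1L]
  structure(heat,
            seed_name = if (inherits(seeds, "seed_gene_set")) seeds$name else "seeds",
            config = cfg, class = "heat_vector")
}

#' Exact RWR by direct linear solve (small-graph oracle)
#'
#' Solves `F = (1 - alpha) (I - alpha W)^{-1} F0` densely. Intended as an
#' independent check of [propagate()] on graphs small enough for a dense
#' solve; the system is never singular for alpha < 1 with a (sub)stochastic
#' transition matrix.
#'
#' @inheritParams propagate
#' @param max_nodes guard against accidentally densifying a large network.
#' @return a `heat_vector`, same contract as [propagate()].
#' @export
propagate_exact <- function(network, seeds, cfg = propagation_config(),
                            max_nodes = 2000L) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$nodes) > max_nodes)
    stop("network too large for dense solve (", length(network$nodes), " nodes)")
  seed_genes <- if (inherits(seeds, "seed_gene_set")) seeds$genes else as.character(seeds)
  if (length(seed_genes) == 0L) stop("no seed genes")
  op <- .transition_operator(network)
  f0 <- .seed_vector(network, seed_genes, op$active)
  na <- length(op$active)
  M <- diag(na) - cfg$alpha * as.matrix(op$W)
  sol <- solve(M, (1 - cfg$alpha) * f0[op$active])
  heat <- setNames(numeric(length(network$nodes)), network$nodes)
  heat[op$active] <- sol
  structure(heat,
            seed_name = if (inherits(seeds, "seed_gene_set")) seeds$name else "seeds",
            config = cfg, class = "heat_vector")
}

# Propagate many seed sets at once (columns of a seed-indicator matrix).
# Used by the NPS null ensemble: one iterative solve for all R null sets.
# seed_sets: list of character vectors. Returns nodes x R matrix of heats.
.propagate_many <- function(network, seed_sets, cfg = propagation_config()) {
  op <- .transition_operator(network)
  n <- length(network$nodes)
  R <- length(seed_sets)
  F0 <- matrix(0, nrow = n, ncol = R)
  for (r in seq_len(R)) {
    F0[, r] <- .seed_vector(network, seed_sets[[r]], op$active)
  }
  Fa <- .rwr_iterate(op$W, F0[op$active, , drop = FALSE],
                     cfg$alpha, cfg$tol, cfg$max_iter)
  H <- matrix(0, nrow = n, ncol = R, dimnames = list(network$nodes, NULL))
  H[op$active, ] <- Fa
  H
}

#' @method print heat_vector
#' @export
print.heat_vector <- function(x, ...) {
  cat(sprintf("heat_vector over %d genes (seed set '%s'); top genes:\n",
              length(x), attr(x, "seed_name")))
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(5L, length(x)))]
  print(round(top, 5))
  invisible(x)
}
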