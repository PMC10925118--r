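# Shared in-code fixtures. Everything is generated programmatically; no
# binary files.

triangle_net <- function() {
  gene_network(cbind(c("A", "B", "A"), c("B", "C", "C")), quiet = TRUE)
}

path_net <- function() {
  gene_network(cbind(c("A", "B"), c("B", "C")), quiet = TRUE)
}

# Erdos-Renyi-ish random connected-ish graph over n nodes; guarantees
# degree >= 1 by chaining a backbone path.
random_net <- function(n, p = 3 / n, seed = 1) {
  set.seed(seed)
  syms <- sprintf("N%03d", seq_len(n))
  backbone <- cbind(syms[-n], syms[-1])
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  pick <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  extra <- cbind(syms[pick[, 1]], syms[pick[, 2]])
  gene_network(rbind(backbone, extra), quiet = TRUE)
}

# small degree-heterogeneous graph for binning/null tests
star_plus_ring <- function(k_ring = 30, k_star = 8) {
  ring <- sprintf("R%02d", seq_len(k_ring))
  ring_edges <- cbind(ring, ring[c(2:k_ring, 1)])
  hub <- "HUB"
  star_edges <- cbind(hub, sprintf("S%02d", seq_len(k_star)))
  cross <- cbind(hub, ring[1])
  gene_network(rbind(ring_edges, star_edges, cross), quiet = TRUE)
}

tiny_scores_common <- function() {
  gene_score_table(data.frame(
    gene = c("A", "B", "C"),
    p_common = c(1e-7, 1e-5, 0.03)))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# brute-force BH step-up: q_i = min_{j>=i} p_(j)*n/j, in input order
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(sort(p)[i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# brute-force hypergeometric upper tail by term summation
hyper_bruteforce <- function(q, k, N, ov) {
  terms <- vapply(ov:min(q, k), function(x)
    choose(k, x) * choose(N - k, q - x), numeric(1))
  sum(terms) / choose(N, q)
}
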