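# Synthetic data with known ground truth.
#
# The generators emulate the statistical structure the analysis assumes:
# a degree-heterogeneous (heavy-tailed) interaction network like PCNet, a
# planted densely connected module representing shared biology, two seed
# score tables whose significant genes overlap that module, and an
# expression matrix with planted per-tissue differential expression.
# Every generator is a pure function of (spec, rng_seed).

#' Specification for synthetic fixtures
#'
#' @param n_genes number of network genes (default 2000).
#' @param graph_model `"preferential-attachment"` (Barabasi-Albert) or
#'   `"powerlaw-fitness"` (static fitness model with power-law expected
#'   degrees, giving control over the degree exponent).
#' @param attachment edges added per new node under preferential attachment
#'   (default 4, average degree ~8).
#' @param degree_exponent power-law exponent for the fitness model
#'   (default 2.5).
#' @param module_size planted module size `m` (default 50).
#' @param density_multiplier within-module edge density as a multiple of
#'   the background edge density (default 10; 1 = no planting).
#' @param seeds_per_source significant genes per source (default 20).
#' @param overlap fraction of each source's seeds drawn from the module,
#'   in `[0, 1]` (default 1).
#' @param noise_seeds extra significant background genes appended per
#'   source beyond `seeds_per_source` (default 0).
#' @param rng_seed integer RNG seed (required at generation time if not
#'   set here).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           graph_model = c("preferential-attachment",
                                           "powerlaw-fitness"),
                           attachment = 4L, degree_exponent = 2.5,
                           module_size = 50L, density_multiplier = 10,
                           seeds_per_source = 20L, overlap = 1,
                           noise_seeds = 0L, rng_seed = NULL) {
  graph_model <- match.arg(graph_model)
  stopifnot(module_size < n_genes, overlap >= 0, overlap <= 1,
            density_multiplier >= 1, seeds_per_source >= 1)
  structure(list(n_genes = as.integer(n_genes), graph_model = graph_model,
                 attachment = as.integer(attachment),
                 degree_exponent = degree_exponent,
                 module_size = as.integer(module_size),
                 density_multiplier = density_multiplier,
                 seeds_per_source = as.integer(seeds_per_source),
                 overlap = overlap, noise_seeds = as.integer(noise_seeds),
                 rng_seed = rng_seed),
            class = "synthetic_spec")
}

.sym <- function(i) sprintf("G%06d", i)

#' Generate a synthetic network with a planted module
#'
#' Draws a heavy-tailed random graph, then plants a module: a random set of
#' `module_size` genes whose within-module edge density is raised to
#' `density_multiplier` times the background density by adding edges among
#' random non-adjacent module pairs. `density_multiplier = 1` adds nothing,
#' leaving the "module" statistically indistinguishable.
#'
#' @param spec a [synthetic_spec()].
#' @param rng_seed integer seed; overrides `spec$rng_seed`.
#' @return list with `network` (a [gene_network()]), `module` (character
#'   vector of planted genes) and `spec`.
#' @export
make_network <- function(spec, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(rng_seed)) stop("rng_seed is required")
  set.seed(as.integer(rng_seed))
  n <- spec$n_genes
  g <- if (spec$graph_model == "preferential-attachment") {
    igraph::sample_pa(n, power = 1, m = spec$attachment, directed = FALSE)
  } else {
    n_edges <- as.integer(round(n * spec$attachment))
    igraph::sample_fitness_pl(n, n_edges, exponent.out = spec$degree_exponent)
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(.sym(el[, 1L]), .sym(el[, 2L]))
  nodes <- .sym(seq_len(n))

  module <- sort(sample(nodes, spec$module_size))
  m <- spec$module_size
  bg_density <- nrow(el) * 2 / (n * (n - 1))
  target_density <- spec$density_multiplier * bg_density
  n_pairs <- m * (m - 1) / 2
  want <- round(target_density * n_pairs)
  if (want > n_pairs)
    stop(sprintf(
      "infeasible module density: need %d of %d pairs; max multiplier %.1f",
      want, n_pairs, n_pairs / (bg_density * n_pairs)))
  # current within-module edges
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  in_mod <- edges[, 1L] %in% module & edges[, 2L] %in% module
  have_keys <- pair_key(edges[in_mod, 1L], edges[in_mod, 2L])
  add <- want - length(have_keys)
  if (add > 0L) {
    comb <- t(utils::combn(module, 2L))
    keys <- pair_key(comb[, 1L], comb[, 2L])
    free <- which(!(keys %in% have_keys))
    pick <- free[sample.int(length(free), add)]
    edges <- rbind(edges, comb[pick, , drop = FALSE])
  }
  net <- gene_network(edges, nodes = nodes, quiet = TRUE)
  list(network = net, module = module, spec = spec)
}

# Draw a source's significant genes: round(overlap * k) from the module,
# the rest (plus noise_seeds) uniformly from the background.
.draw_planted <- function(truth, k, overlap, noise) {
  module <- truth$module
  background <- setdiff(truth$network$nodes, module)
  k_mod <- round(overlap * k)
  k_bg <- k - k_mod + noise
  c(if (k_mod > 0L) sample(module, k_mod),
    if (k_bg > 0L) sample(background, k_bg))
}

#' Generate common- and rare-style gene score tables
#'
#' Every network gene gets a row in each table. Planted significant genes
#' receive p-values far below the selection thresholds
#' (common: `10^-Uniform(8, 30)`; rare: a shared per-gene base exponent
#' `Uniform(5, 12)` perturbed independently per test column, giving three
#' correlated columns, clamped so Benjamini-Hochberg selection at
#' FDR < 0.25 is deterministic). Background p-values are uniform but
#' truncated away from the thresholds (common: `Uniform(0.001, 1)`; rare:
#' `Uniform(0.26, 1)`) so that the seed-selection rules recover exactly
#' the planted genes — no boundary flakiness.
#'
#' @param spec a [synthetic_spec()].
#' @param truth result of [make_network()].
#' @param rng_seed integer seed; overrides `spec$rng_seed` (offset so the
#'   tables are not correlated with the graph draw).
#' @return list with `common` and `rare` [gene_score_table()]s and the
#'   planted truth sets `seeds_common`, `seeds_rare`.
#' @export
make_seed_tables <- function(spec, truth, rng_seed = spec$rng_seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(rng_seed)) stop("rng_seed is required")
  if (spec$seeds_per_source > spec$module_size && spec$overlap >= 1)
    stop("more seeds than module genes at overlap 1")
  set.seed((as.integer(rng_seed) + 104729L) %% .Machine$integer.max)
  genes <- truth$network$nodes
  n <- length(genes)

  seeds_common <- sort(.draw_planted(truth, spec$seeds_per_source,
                                     spec$overlap, spec$noise_seeds))
  seeds_rare <- sort(.draw_planted(truth, spec$seeds_per_source,
                                   spec$overlap, spec$noise_seeds))

  p_common <- runif(n, min = 1e-3, max = 1)
  idx_c <- match(seeds_common, genes)
  p_common[idx_c] <- 10^(-runif(length(idx_c), 8, 30))
  common <- gene_score_table(data.frame(gene = genes, p_common = p_common,
                                        stringsAsFactors = FALSE))

  idx_r <- match(seeds_rare, genes)
  base_exp <- runif(length(idx_r), 5, 12)
  # clamp keeps every planted q below 0.05 << 0.25 regardless of noise
  p_cap <- min(1e-4, 0.05 * length(idx_r) / n)
  rare_col <- function() {
    p <- runif(n, min = 0.26, max = 1)
    p[idx_r] <- pmin(p_cap, 10^(-(base_exp + rnorm(length(idx_r), 0, 0.3))))
    p
  }
  rare <- gene_score_table(data.frame(
    gene = genes,
    p_burden = rare_col(), p_skato = rare_col(), p_skat = rare_col(),
    annotation_class = sample(c("pLoF", "missense", "synonymous"), n,
                              replace = TRUE, prob = c(0.51, 0.40, 0.09)),
    stringsAsFactors = FALSE))
  list(common = common, rare = rare,
       seeds_common = seeds_common, seeds_rare = seeds_rare)
}

#' Generate a labeled expression matrix with planted DEGs
#'
#' Baseline log-scale expression is Normal(5, 1); each planted gene is
#' shifted by `+lfc` in its label's samples. Labels are balanced with
#' `n_per_label` samples each.
#'
#' @param genes character vector of gene symbols (rows).
#' @param deg_truth named list: label -> character vector of planted DEGs
#'   (subsets of `genes`).
#' @param lfc planted log-fold-change (>= 0).
#' @param n_per_label samples per label (>= 2).
#' @param rng_seed integer seed.
#' @return list with `expr` (an [expression_matrix()]) and `deg_truth`.
#' @export
make_expression <- function(genes, deg_truth, lfc = 2, n_per_label = 10L,
                            rng_seed) {
  stopifnot(lfc >= 0, length(deg_truth) >= 2, !is.null(names(deg_truth)))
  if (n_per_label < 2L) stop("n_per_label must be >= 2")
  if (missing(rng_seed) || is.null(rng_seed)) stop("rng_seed is required")
  set.seed(as.integer(rng_seed))
  labels <- rep(names(deg_truth), each = n_per_label)
  n_s <- length(labels)
  M <- matrix(rnorm(length(genes) * n_s, mean = 5, sd = 1),
              nrow = length(genes),
              dimnames = list(genes, paste0("S", seq_len(n_s))))
  for (lb in names(deg_truth)) {
    planted <- intersect(deg_truth[[lb]], genes)
    M[planted, labels == lb] <- M[planted, labels == lb] + lfc
  }
  list(expr = expression_matrix(M, labels), deg_truth = deg_truth)
}

#' Write an annotation catalog as a GMT file
#'
#' @param catalog an [annotation_catalog()].
#' @param path output path.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  lines <- vapply(names(catalog$sets), function(nm)
    paste(c(nm, "synthetic", catalog$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic fixture directory
#'
#' Generates and writes `network.tsv`, `scores_common.tsv`,
#' `scores_rare.tsv`, `catalog.gmt` (one category per planted truth set
#' plus the module itself, universe = network nodes), `expr.tsv`,
#' `labels.tsv`, and `truth.json` recording all ground truth and
#' parameters, so downstream recall/precision can be computed without
#' re-deriving anything.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @param rng_seed integer seed; overrides `spec$rng_seed`.
#' @return invisibly, the truth list.
#' @export
simulate_fixture <- function(spec, out_dir, rng_seed = spec$rng_seed) {
  if (is.null(rng_seed)) stop("rng_seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_network(spec, rng_seed = rng_seed)
  tabs <- make_seed_tables(spec, truth, rng_seed = rng_seed)
  write_edge_list(truth$network, file.path(out_dir, "network.tsv"))
  write_gene_scores(tabs$common, file.path(out_dir, "scores_common.tsv"))
  write_gene_scores(tabs$rare, file.path(out_dir, "scores_rare.tsv"))
  catalog <- annotation_catalog(
    list(planted_module = truth$module,
         planted_seeds_common = tabs$seeds_common,
         planted_seeds_rare = tabs$seeds_rare),
    universe = truth$network$nodes)
  write_gmt(catalog, file.path(out_dir, "catalog.gmt"))
  deg_truth <- list(tissueA = truth$module[seq_len(min(20L, length(truth$module)))],
                    tissueB = character(0), tissueC = character(0))
  ex <- make_expression(truth$network$nodes[seq_len(min(200L, spec$n_genes))],
                        deg_truth, lfc = 2, n_per_label = 10L,
                        rng_seed = (as.integer(rng_seed) + 31L) %% .Machine$integer.max)
  em <- ex$expr
  write.table(data.frame(gene = rownames(em$values), em$values,
                         check.names = FALSE),
              file.path(out_dir, "expr.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = names(em$labels), label = unname(em$labels)),
              file.path(out_dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth_out <- list(module = truth$module,
                    seeds_common = tabs$seeds_common,
                    seeds_rare = tabs$seeds_rare,
                    deg_truth = deg_truth,
                    rng_seed = as.integer(rng_seed),
                    spec = unclass(spec)[setdiff(names(spec), "rng_seed")])
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(truth_out)
}
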