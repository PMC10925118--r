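# End-to-end pipeline: seeds -> propagate -> nps -> coloc -> enrich.
# All artifacts are plain-text TSV/JSON; a machine-readable manifest
# records every parameter and RNG seed so a run is exactly repeatable.

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are
#' returned as character and coerced by the consumer. (A deliberately tiny
#' format: no YAML dependency is available offline.)
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- .read_lines_checked(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), character(1))
  out
}

.cfg_get <- function(config, key, default = NULL, as = identity) {
  if (!is.null(config[[key]])) as(config[[key]]) else default
}

#' Run the full colocalization pipeline
#'
#' Executes, in order: seed selection from the two score tables,
#' network mapping, propagation + NPS for each source, colocalized-network
#' extraction with permutation significance, and (if a catalog is supplied)
#' hypergeometric enrichment of the extracted genes. Each stage prechecks
#' its inputs and aborts naming the stage on failure. Artifacts written to
#' `out_dir`: `seeds_common.txt`, `seeds_rare.txt`, `selection_report.tsv`,
#' `nps_table.tsv`, `nps_meta.json`, `coloc_genes.txt`, `coloc_edges.tsv`,
#' `coloc_stats.json`, optionally `enrichment.tsv`, and `manifest.json`.
#'
#' @param config named list (or path to a [read_config()] file) with keys:
#'   `network` (edge-list path), `scores_common`, `scores_rare` (TSV paths),
#'   `out_dir`; optional `rare_mode` ("lenient"/"stringent"), `alpha`,
#'   `null_reps`, `n_permutations`, `rng_seed`, `combined_min`,
#'   `common_min`, `rare_min`, `min_seeds`, `catalog` (GMT path),
#'   `universe` ("network" or a file of symbols).
#' @return list with the in-memory results of every stage and
#'   `manifest` (also written as JSON).
#' @export
run_colocalization_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  stopifnot(is.list(config))
  need <- c("network", "scores_common", "scores_rare", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing required key(s): ",
                         paste(miss, collapse = ", "))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rng_seed <- .cfg_get(config, "rng_seed", 1L, as.integer)
  alpha <- .cfg_get(config, "alpha", 0.5, as.numeric)
  null_reps <- .cfg_get(config, "null_reps", 1000L, as.integer)
  n_perm <- .cfg_get(config, "n_permutations", 10000L, as.integer)
  rare_mode <- .cfg_get(config, "rare_mode", "lenient")
  scfg <- seed_selection_config(
    min_seeds = .cfg_get(config, "min_seeds", 6L, as.integer))
  pcfg <- propagation_config(alpha = alpha)
  ccfg <- coloc_config(
    combined_min = .cfg_get(config, "combined_min", 3, as.numeric),
    common_min = .cfg_get(config, "common_min", 1.5, as.numeric),
    rare_min = .cfg_get(config, "rare_min", 1.5, as.numeric),
    n_permutations = n_perm,
    rng_seed = (rng_seed + 811L) %% .Machine$integer.max)
  stages <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }

  # -- seeds ---------------------------------------------------------------
  res_seeds <- stage("seeds", {
    for (k in c("scores_common", "scores_rare"))
      if (!file.exists(config[[k]])) stop("missing input file: ", config[[k]])
    tc <- read_gene_scores(config$scores_common)
    tr <- read_gene_scores(config$scores_rare)
    list(common = select_common_seeds(tc, scfg),
         rare = select_rare_seeds(tr, mode = rare_mode, cfg = scfg),
         table_common = tc, table_rare = tr)
  })
  stages <- c(stages, "seeds")

  # -- propagate (network load + seed mapping precheck) --------------------
  res_net <- stage("propagate", {
    if (!file.exists(config$network)) stop("missing network file: ", config$network)
    network <- read_edge_list(config$network, quiet = TRUE)
    list(network = network,
         common = map_seeds_to_network(res_seeds$common, network, scfg, quiet = TRUE),
         rare = map_seeds_to_network(res_seeds$rare, network, scfg, quiet = TRUE))
  })
  stages <- c(stages, "propagate")
  writeLines(res_net$common$genes, file.path(out_dir, "seeds_common.txt"))
  writeLines(res_net$rare$genes, file.path(out_dir, "seeds_rare.txt"))
  report <- rbind(
    data.frame(gene = res_seeds$common$genes, source = "common",
               p = unname(res_seeds$common$pvalues),
               mapped = res_seeds$common$genes %in% res_net$network$nodes),
    data.frame(gene = res_seeds$rare$genes, source = "rare",
               p = unname(res_seeds$rare$pvalues),
               mapped = res_seeds$rare$genes %in% res_net$network$nodes))
  write.table(report, file.path(out_dir, "selection_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- nps -----------------------------------------------------------------
  res_nps <- stage("nps", {
    network <- res_net$network
    ccfg2 <- consensus_config()
    z_c <- consensus_nps(network, res_net$common, R = null_reps, cfg = pcfg,
                         ccfg = ccfg2, rng_seed = rng_seed)
    z_r <- consensus_nps(network, res_net$rare, R = null_reps, cfg = pcfg,
                         ccfg = ccfg2,
                         rng_seed = (rng_seed + 104729L) %% .Machine$integer.max)
    combine_nps(z_c, z_r)
  })
  stages <- c(stages, "nps")
  write.table(format(res_nps, digits = 10),
              file.path(out_dir, "nps_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(R = null_reps, rng_seed = rng_seed, alpha = alpha,
                            heat_floor = .HEAT_FLOOR),
                       file.path(out_dir, "nps_meta.json"), auto_unbox = TRUE)

  # -- coloc ---------------------------------------------------------------
  res_coloc <- stage("coloc", {
    shared <- intersect(res_net$common$genes, res_net$rare$genes)
    ext <- extract_network(res_nps, res_net$network, ccfg)
    stats <- permutation_test(res_nps, shared_genes = shared, cfg = ccfg)
    list(extraction = ext, stats = stats, shared = shared)
  })
  stages <- c(stages, "coloc")
  writeLines(res_coloc$extraction$genes, file.path(out_dir, "coloc_genes.txt"))
  ed <- if (is.null(res_coloc$extraction$subgraph))
    matrix(character(0), ncol = 2L) else res_coloc$extraction$subgraph$edges
  write.table(as.data.frame(ed), file.path(out_dir, "coloc_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("gene1", "gene2"))
  st <- res_coloc$stats
  jsonlite::write_json(
    list(size = st$size, size_z = st$size_z, size_p = st$size_p,
         mean_score = st$mean_score, mean_z = st$mean_z, mean_p = st$mean_p,
         ratio = st$ratio, ratio_ci = st$ratio_ci,
         n_permutations = st$n_permutations),
    file.path(out_dir, "coloc_stats.json"), auto_unbox = TRUE, digits = 10)

  # -- enrich --------------------------------------------------------------
  res_enrich <- NULL
  if (!is.null(config$catalog)) {
    res_enrich <- stage("enrich", {
      if (!file.exists(config$catalog)) stop("missing catalog: ", config$catalog)
      uni <- .cfg_get(config, "universe", "network")
      universe <- if (identical(uni, "network")) res_net$network$nodes
                  else .read_lines_checked(uni)
      catalog <- read_gmt(config$catalog, universe = universe)
      if (length(res_coloc$extraction$genes) == 0L) NULL
      else annotate_catalog(res_coloc$extraction$genes, catalog, quiet = TRUE)
    })
    stages <- c(stages, "enrich")
    if (!is.null(res_enrich))
      write.table(format(res_enrich, digits = 10),
                  file.path(out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "rwrcoloc",
    version = as.character(utils::packageVersion("rwrcoloc")),
    stages = stages,
    parameters = list(alpha = alpha, null_reps = null_reps,
                      n_permutations = n_perm, rng_seed = rng_seed,
                      rare_mode = rare_mode,
                      thresholds = list(combined_min = ccfg$combined_min,
                                        common_min = ccfg$common_min,
                                        rare_min = ccfg$rare_min),
                      min_seeds = scfg$min_seeds,
                      normalization = pcfg$normalization,
                      tol = pcfg$tol,
                      one_sided = TRUE,
                      null_excludes_observed_seeds = FALSE),
    inputs = config[intersect(names(config),
                              c("network", "scores_common", "scores_rare",
                                "catalog", "universe"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(seeds = res_seeds, network = res_net, nps = res_nps,
                 coloc = res_coloc, enrichment = res_enrich,
                 manifest = manifest))
}
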