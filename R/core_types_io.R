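#' @importFrom stats pnorm phyper quantile sd setNames rnorm runif
#' @importFrom utils read.table write.table head
NULL

# ---------------------------------------------------------------------------
# GeneNetwork: an undirected simple graph over gene symbols.
# Stored canonically (sorted nodes, lexicographically sorted unordered edge
# pairs) so that two networks built from the same edges in any order are
# `identical()`.
# ---------------------------------------------------------------------------

#' Construct a gene network from an edge table
#'
#' Builds an undirected simple graph over gene symbols. Self-loops and
#' duplicate edges are dropped (their counts are reported via [message()]),
#' matching the convention of consensus interaction networks such as PCNet,
#' which are simple graphs. Gene identity is the symbol string, matched
#' case-sensitively after trimming surrounding whitespace; no alias
#' resolution is attempted.
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes; endpoints of `edges` are always included.
#' @param quiet suppress the dropped self-loop/duplicate messages.
#' @return An object of class `gene_network` with components `nodes` (sorted
#'   character vector), `edges` (m x 2 character matrix, each row an
#'   unordered pair stored with the lexicographically smaller symbol first,
#'   rows sorted), and `degree` (named integer vector over all nodes).
#' @export
gene_network <- function(edges, nodes = NULL, quiet = FALSE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L)
    stop("`edges` must be a two-column matrix or data frame")
  edges <- matrix(trimws(as.character(edges[, 1:2, drop = FALSE])), ncol = 2L)
  nodes <- trimws(as.character(nodes))

  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  # self-loop endpoints are retained as isolated nodes
  nodes <- c(nodes, edges[self, 1L])
  edges <- edges[!self, , drop = FALSE]

  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  ord <- order(a, b, method = "radix")
  em <- cbind(a[ord], b[ord])
  colnames(em) <- NULL

  all_nodes <- sort(unique(c(nodes, em)), method = "radix")
  if (length(all_nodes) == 0L) stop("empty graph: no nodes")
  deg <- setNames(integer(length(all_nodes)), all_nodes)
  if (nrow(em) > 0L) {
    tab <- table(factor(c(em[, 1L], em[, 2L]), levels = all_nodes))
    deg[] <- as.integer(tab)
  }
  if (!quiet && (n_self > 0L || n_dup > 0L))
    message(sprintf("gene_network: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  structure(list(nodes = all_nodes, edges = em, degree = deg),
            class = "gene_network")
}

#' @method print gene_network
#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (degree range %d-%d)\n",
              length(x$nodes), nrow(x$edges),
              if (length(x$degree)) min(x$degree) else 0L,
              if (length(x$degree)) max(x$degree) else 0L))
  invisible(x)
}

#' Sparse adjacency matrix of a gene network
#'
#' @param network a [gene_network()].
#' @return symmetric sparse 0/1 `dgCMatrix` with dimnames = node symbols.
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  i <- match(network$edges[, 1L], network$nodes)
  j <- match(network$edges[, 2L], network$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(n, n),
                       dimnames = list(network$nodes, network$nodes))
}

#' Subgraph induced on a gene set
#'
#' @param network a [gene_network()].
#' @param genes character vector of node symbols (symbols absent from the
#'   network are ignored).
#' @return a `gene_network` on `genes` with all edges of `network` whose
#'   two endpoints both lie in `genes` (isolated members retained).
#' @export
induced_subgraph <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  genes <- intersect(genes, network$nodes)
  keep <- network$edges[, 1L] %in% genes & network$edges[, 2L] %in% genes
  gene_network(network$edges[keep, , drop = FALSE], nodes = genes, quiet = TRUE)
}

#' @rdname gene_network
#' @param x object to test.
#' @export
is.gene_network <- function(x) inherits(x, "gene_network")

# ---------------------------------------------------------------------------
# SeedGeneSet
# ---------------------------------------------------------------------------

#' Construct a seed gene set
#'
#' A named set of genes used as the restart distribution of the random walk,
#' optionally carrying per-gene p-values (needed by the weighted-subsampling
#' consensus for oversized sets) and a source tag.
#'
#' @param genes character vector, non-empty after de-duplication.
#' @param name descriptive name.
#' @param source one of `"common"`, `"rare"`, `"other"`.
#' @param pvalues optional named numeric vector of p-values in (0, 1]; names
#'   must cover `genes`.
#' @param allow_empty permit a zero-gene set (used by selection functions,
#'   whose filters may legitimately select nothing; such a set is not valid
#'   for propagation).
#' @return object of class `seed_gene_set` with fields `name`, `source`,
#'   `genes` (sorted unique), `pvalues`.
#' @export
seed_gene_set <- function(genes, name = "seeds", source = c("common", "rare", "other"),
                          pvalues = NULL, allow_empty = FALSE) {
  source <- match.arg(source)
  genes <- sort(unique(trimws(as.character(genes))), method = "radix")
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L && !allow_empty) stop("seed gene set must be non-empty")
  if (!is.null(pvalues)) {
    if (is.null(names(pvalues))) stop("`pvalues` must be named by gene symbol")
    .check_pvalues(pvalues)
    missing <- setdiff(genes, names(pvalues))
    if (length(missing))
      stop("pvalues missing for genes: ", paste(head(missing, 5L), collapse = ", "))
    pvalues <- pvalues[genes]
  }
  structure(list(name = name, source = source, genes = genes, pvalues = pvalues),
            class = "seed_gene_set")
}

#' @method print seed_gene_set
#' @export
print.seed_gene_set <- function(x, ...) {
  cat(sprintf("seed_gene_set '%s' (%s): %d genes\n", x$name, x$source,
              length(x$genes)))
  invisible(x)
}

.check_pvalues <- function(p, what = "p-value") {
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1))
    stop(sprintf("%ss must lie in (0, 1]; offending values: %s", what,
                 paste(head(format(p[p <= 0 | p > 1]), 3L), collapse = ", ")))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# GeneScoreTable
# ---------------------------------------------------------------------------

.RARE_COLS <- c("p_burden", "p_skato", "p_skat")

#' Construct a gene score table
#'
#' Gene-level association results: a MAGMA-style common-variant column
#' (`p_common`) and/or rare-variant gene-test columns (`p_burden`,
#' `p_skato`, `p_skat`), plus an optional functional `annotation_class`
#' (for example pLoF / missense / synonymous).
#'
#' @param df data frame with a `gene` column and at least one p-value column.
#' @return data frame of class `gene_score_table`; gene symbols unique,
#'   all p-values validated in (0, 1].
#' @export
gene_score_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"gene" %in% names(df)) stop("score table needs a 'gene' column")
  pcols <- intersect(c("p_common", .RARE_COLS), names(df))
  if (length(pcols) == 0L)
    stop("score table needs at least one p-value column among: p_common, ",
         paste(.RARE_COLS, collapse = ", "))
  df$gene <- trimws(as.character(df$gene))
  dups <- unique(df$gene[duplicated(df$gene)])
  if (length(dups))
    stop("duplicate gene symbol(s) in score table: ",
         paste(head(dups, 5L), collapse = ", "))
  for (cl in pcols) {
    df[[cl]] <- as.numeric(df[[cl]])
    .check_pvalues(df[[cl]], what = paste0(cl, " value"))
  }
  rownames(df) <- NULL
  class(df) <- c("gene_score_table", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# AnnotationCatalog
# ---------------------------------------------------------------------------

#' Construct an annotation catalog
#'
#' A map from category names (trait groups, tissues, pathways) to gene sets,
#' together with the background universe used for hypergeometric enrichment.
#' The universe is deliberately explicit: enrichment p-values are meaningless
#' without a stated background, so it is never defaulted implicitly at test
#' time — only here, to the union of all category sets, when constructing a
#' standalone catalog.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of background symbols; defaults to the
#'   union of all sets. Every category must be a subset of the universe.
#' @return object of class `annotation_catalog` with `sets` and `universe`.
#' @export
annotation_catalog <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(g) sort(unique(trimws(as.character(g))), method = "radix"))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)), method = "radix")
  universe <- sort(unique(trimws(as.character(universe))), method = "radix")
  bad <- names(sets)[!vapply(sets, function(g) all(g %in% universe), logical(1))]
  if (length(bad))
    stop("category set(s) not contained in universe: ",
         paste(head(bad, 5L), collapse = ", "))
  structure(list(sets = sets, universe = universe), class = "annotation_catalog")
}

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Construct a labeled expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, already
#'   on log scale (so fold-change gates apply to mean differences).
#' @param labels character vector of tissue/group labels, one per sample
#'   (recycled names from `colnames(values)` if named).
#' @return object of class `expression_matrix` with `values` and `labels`.
#' @export
expression_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("expression matrix needs gene rownames")
  if (is.null(colnames(values))) colnames(values) <- paste0("S", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("need exactly one label per sample")
  if (anyNA(labels) || any(!nzchar(labels))) stop("missing sample labels")
  structure(list(values = values, labels = setNames(labels, colnames(values))),
            class = "expression_matrix")
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

#' Read a network edge list
#'
#' Supports two plain-text dialects: `tsv` (two or more whitespace-separated
#' columns; first two are the endpoints, extra columns ignored) and `sif`
#' (Cytoscape simple interaction format: source, interaction type, one or
#' more targets). Comment lines starting with `#` and blank lines are
#' skipped. Duplicate edges and self-loops are dropped with a reported count.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @param quiet suppress drop-count messages.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), quiet = FALSE) {
  format <- match.arg(format)
  lines <- .read_lines_checked(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("empty graph: no edges in ", path)
  from <- character(0); to <- character(0)
  for (ln in keep) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (format == "tsv") {
      if (length(f) < 2L)
        stop(sprintf("parse error at line %d of %s: need >= 2 columns", ln, path))
      from <- c(from, f[1L]); to <- c(to, f[2L])
    } else {
      if (length(f) < 3L)
        stop(sprintf("parse error at line %d of %s: SIF needs source, type, target",
                     ln, path))
      tg <- f[-(1:2)]
      from <- c(from, rep(f[1L], length(tg))); to <- c(to, tg)
    }
  }
  gene_network(cbind(from, to), quiet = quiet)
}

#' Write a network as a two-column TSV edge list
#'
#' Round-trips with [read_edge_list()]: writing then reading reproduces the
#' identical `gene_network` (isolated nodes excepted, since an edge list
#' cannot carry them; they are written as a commented header for reference).
#'
#' @param network a [gene_network()].
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  con <- file(path, "w"); on.exit(close(con))
  iso <- network$nodes[network$degree == 0L]
  if (length(iso))
    writeLines(paste0("# isolated: ", paste(iso, collapse = " ")), con)
  if (nrow(network$edges))
    writeLines(paste(network$edges[, 1L], network$edges[, 2L], sep = "\t"), con)
  invisible(path)
}

#' Read a gene-level score table
#'
#' Tab-separated with a header; requires a `gene` column plus at least one
#' of `p_common`, `p_burden`, `p_skato`, `p_skat`. An optional
#' `annotation_class` column is carried through.
#'
#' @param path file path.
#' @return a [gene_score_table()].
#' @export
read_gene_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  gene_score_table(df)
}

#' Write a gene score table as TSV
#' @param table a [gene_score_table()] (or plain data frame).
#' @param path output path.
#' @export
write_gene_scores <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: each line is `name <TAB> description <TAB> gene1 <TAB> ...`.
#' Repeated genes within a set are de-duplicated.
#'
#' @param path file path.
#' @param universe optional explicit background; defaults to the union of
#'   all sets.
#' @return an [annotation_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- .read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("parse error at line %d of %s: GMT needs >= 3 fields", ln, path))
    sets[[f[1L]]] <- unique(f[-(1:2)])
  }
  annotation_catalog(sets, universe = universe)
}

#' Read an expression matrix with sample labels
#'
#' @param expr_path TSV: first column gene symbol, remaining columns samples
#'   (header row of sample ids).
#' @param labels_path TSV with columns `sample` and `label`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(expr_path, labels_path) {
  em <- read.table(expr_path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  lab <- read.table(labels_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "label") %in% names(lab)))
    stop("labels file needs 'sample' and 'label' columns")
  m <- as.matrix(em)
  idx <- match(colnames(m), lab$sample)
  if (anyNA(idx)) stop("labels missing for sample(s): ",
                       paste(head(colnames(m)[is.na(idx)], 5L), collapse = ", "))
  expression_matrix(m, lab$label[idx])
}
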