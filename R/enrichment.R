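# Hypergeometric catalog enrichment and a generic tissue differential-
# expression enrichment.

#' Hypergeometric upper-tail overlap p-value
#'
#' `P[X >= overlap]` for `X ~ Hypergeometric(universe, |category|, |query|)`:
#' the probability of drawing at least the observed overlap when `query`
#' genes are drawn from a universe containing `category`.
#'
#' @param query_size,category_size,universe_size,overlap integer counts.
#' @return p-value in (0, 1].
#' @export
hypergeom_overlap <- function(query_size, category_size, universe_size, overlap) {
  stopifnot(length(query_size) == 1L, length(overlap) == 1L)
  if (universe_size < max(query_size, category_size) ||
      overlap > min(query_size, category_size) ||
      overlap < max(0L, query_size + category_size - universe_size) ||
      any(c(query_size, category_size, universe_size, overlap) < 0))
    stop(sprintf(
      "inconsistent counts: universe %d, category %d, query %d, overlap %d",
      universe_size, category_size, query_size, overlap))
  phyper(overlap - 1L, category_size, universe_size - category_size,
         query_size, lower.tail = FALSE)
}

#' Catalog enrichment of a query gene set
#'
#' Hypergeometric upper-tail enrichment of the query against every category
#' of the catalog, using the catalog's universe as background. Query genes
#' outside the universe are dropped (with a reported count) before testing:
#' a gene that could never have been drawn cannot count as an overlap.
#' Category p-values are BH-adjusted across categories.
#'
#' @param query character vector of gene symbols.
#' @param catalog an [annotation_catalog()].
#' @param quiet suppress the dropped-gene message.
#' @return data frame of class `enrichment_result`, one row per category:
#'   `category`, `overlap`, `category_size`, `query_size`, `universe_size`,
#'   `p`, `p_adjusted`, `overlap_genes` (comma-separated), sorted by `p`.
#' @export
annotate_catalog <- function(query, catalog, quiet = FALSE) {
  stopifnot(inherits(catalog, "annotation_catalog"))
  if (length(catalog$universe) == 0L) stop("empty enrichment universe")
  query <- unique(trimws(as.character(query)))
  if (length(query) == 0L) stop("empty query gene set")
  inside <- query %in% catalog$universe
  if (!quiet && any(!inside))
    message(sprintf("annotate_catalog: dropped %d query gene(s) outside universe",
                    sum(!inside)))
  query <- query[inside]
  if (length(query) == 0L) stop("no query genes inside the universe")
  N <- length(catalog$universe); q <- length(query)
  rows <- lapply(names(catalog$sets), function(nm) {
    cat_genes <- catalog$sets[[nm]]
    ov <- intersect(query, cat_genes)
    data.frame(category = nm, overlap = length(ov),
               category_size = length(cat_genes), query_size = q,
               universe_size = N,
               p = hypergeom_overlap(q, length(cat_genes), N, length(ov)),
               overlap_genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_fdr(out$p)
  out <- out[order(out$p, out$category), c("category", "overlap", "category_size",
                                           "query_size", "universe_size", "p",
                                           "p_adjusted", "overlap_genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Differential-expression configuration
#'
#' @param bonferroni_alpha family-wise level for the per-label gene tests
#'   (default 0.05; Bonferroni across genes within each label).
#' @param lfc_min minimum absolute log fold change (default 0.58, i.e.
#'   ~1.5-fold on log2-scale data).
#' @return list of class `deg_config`. The test is a two-sided Welch
#'   (unequal-variance) t-test of one label's samples against all remaining
#'   samples; groups of different tissues differ in size and variance, so
#'   the pooled-variance form is not used.
#' @export
deg_config <- function(bonferroni_alpha = 0.05, lfc_min = 0.58) {
  stopifnot(bonferroni_alpha > 0, bonferroni_alpha < 1, lfc_min >= 0)
  structure(list(bonferroni_alpha = bonferroni_alpha, lfc_min = lfc_min),
            class = "deg_config")
}

# Vectorized per-gene Welch t-test of columns `in_idx` vs the rest.
# Returns data.frame(p, lfc). Expression values are assumed log-scale, so
# the fold change is the difference of group means.
.welch_rows <- function(M, in_idx) {
  out_idx <- setdiff(seq_len(ncol(M)), in_idx)
  n1 <- length(in_idx); n2 <- length(out_idx)
  X1 <- M[, in_idx, drop = FALSE]; X2 <- M[, out_idx, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant gene: no evidence either way
  data.frame(p = p, lfc = m1 - m2)
}

#' Call differentially expressed genes per tissue label
#'
#' For each label, every gene is tested by a two-sided Welch t-test of that
#' label's samples against all remaining samples; p-values are Bonferroni-
#' corrected across genes within the label, and a gene is a DEG iff the
#' adjusted p is below `bonferroni_alpha` and `|logFC| >= lfc_min`. Signed
#' sets split DEGs by direction of change.
#'
#' @param expr an [expression_matrix()] (log-scale values).
#' @param cfg a [deg_config()].
#' @return named list (one element per label), each a list with `up`,
#'   `down`, and `all` (their union) character vectors, plus attribute
#'   `n_genes` (the per-label multiplicity).
#' @export
call_deg <- function(expr, cfg = deg_config()) {
  stopifnot(inherits(expr, "expression_matrix"))
  M <- expr$values
  labels <- expr$labels
  tab <- table(labels)
  if (any(tab < 2L))
    stop("label(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  if (length(tab) < 2L) stop("need at least 2 distinct labels")
  n_genes <- nrow(M)
  out <- lapply(names(tab), function(lb) {
    res <- .welch_rows(M, which(labels == lb))
    p_adj <- pmin(1, res$p * n_genes)
    deg <- p_adj < cfg$bonferroni_alpha & abs(res$lfc) >= cfg$lfc_min
    list(up = rownames(M)[deg & res$lfc > 0],
         down = rownames(M)[deg & res$lfc < 0],
         all = rownames(M)[deg])
  })
  names(out) <- names(tab)
  attr(out, "n_genes") <- n_genes
  out
}

#' Tissue enrichment of a gene set against DEG sets
#'
#' Hypergeometric enrichment of the query against each label's DEG set
#' (direction `"all"`, `"up"` or `"down"`), with an explicit background
#' universe — enrichment backgrounds are never defaulted implicitly.
#'
#' @param query character vector of gene symbols (non-empty).
#' @param deg_sets result of [call_deg()].
#' @param universe character vector of background gene symbols.
#' @param direction which DEG set per label to test.
#' @return an `enrichment_result` data frame as from [annotate_catalog()],
#'   with tissue labels as categories.
#' @export
deg_enrichment <- function(query, deg_sets, universe,
                           direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  if (length(query) == 0L) stop("empty query gene set")
  sets <- lapply(deg_sets, function(s) intersect(s[[direction]], universe))
  catalog <- annotation_catalog(sets, universe = universe)
  annotate_catalog(query, catalog, quiet = TRUE)
}
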