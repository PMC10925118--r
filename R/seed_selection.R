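# Seed selection: fixed significance rules turning gene-level association
# tables into seed gene sets. All threshold comparisons are strict (<);
# boundary ties are excluded.

#' Seed-selection configuration
#'
#' @param common_p_threshold genome-wide gene-based significance cutoff for
#'   the common-variant column (default 2.6e-6, the usual ~0.05/19,000
#'   gene-based Bonferroni level).
#' @param rare_lenient_q Benjamini-Hochberg FDR level for lenient
#'   rare-variant selection (default 0.25).
#' @param rare_stringent_alpha family-wise level for stringent rare-variant
#'   selection; Bonferroni is applied within each test column (default 0.05).
#' @param min_seeds minimum number of network-mapped seeds required for
#'   propagation; fewer is an error (default 6, i.e. n > 5).
#' @param variant_mac_min minor-allele-count filter: variants with
#'   MAC > `variant_mac_min` are retained (default 2).
#' @return list of class `seed_selection_config`.
#' @export
seed_selection_config <- function(common_p_threshold = 2.6e-6,
                                  rare_lenient_q = 0.25,
                                  rare_stringent_alpha = 0.05,
                                  min_seeds = 6L,
                                  variant_mac_min = 2L) {
  stopifnot(common_p_threshold > 0, common_p_threshold < 1,
            rare_lenient_q > 0, rare_lenient_q < 1,
            rare_stringent_alpha > 0, rare_stringent_alpha < 1,
            min_seeds >= 1, variant_mac_min >= 0)
  structure(list(common_p_threshold = common_p_threshold,
                 rare_lenient_q = rare_lenient_q,
                 rare_stringent_alpha = rare_stringent_alpha,
                 min_seeds = as.integer(min_seeds),
                 variant_mac_min = as.integer(variant_mac_min)),
            class = "seed_selection_config")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with order statistics p_(1) <= ... <= p_(n),
#' q_(i) = min_{j >= i} p_(j) * n / j, capped at 1, returned in the input
#' order. NA entries are excluded from the multiplicity count and returned
#' as NA.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("bh_fdr: empty p-value vector")
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  .check_pvalues(p)
  n <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (n > 0L) {
    o <- order(p)
    qs <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
    qo <- numeric(n); qo[o] <- qs
    q[ok] <- qo
  }
  q
}

#' Select common-variant seed genes
#'
#' Genes with `p_common` strictly below the gene-based significance
#' threshold.
#'
#' @param table a [gene_score_table()] with a `p_common` column.
#' @param cfg a [seed_selection_config()].
#' @param name name for the resulting set.
#' @return a [seed_gene_set()] with `source = "common"`, carrying p-values.
#' @export
select_common_seeds <- function(table, cfg = seed_selection_config(),
                                name = "common_seeds") {
  if (!is.data.frame(table) || nrow(table) == 0L) stop("empty score table")
  if (!"p_common" %in% names(table)) stop("table has no p_common column")
  hit <- !is.na(table$p_common) & table$p_common < cfg$common_p_threshold
  seed_gene_set(table$gene[hit], name = name, source = "common",
                pvalues = setNames(table$p_common[hit], table$gene[hit]),
                allow_empty = TRUE)
}

#' Select rare-variant seed genes
#'
#' Union-over-tests ("any test") selection from the burden / SKAT-O / SKAT
#' columns. In `lenient` mode each test column is BH-adjusted separately
#' over its non-missing genes and a gene is selected if any test gives
#' q < `rare_lenient_q`. In `stringent` mode Bonferroni is applied within
#' each column (p < alpha / m for that column's m non-missing genes) and a
#' gene is selected if any test passes. Per-gene p-values carried into the
#' result are the minimum over the available tests.
#'
#' @param table a [gene_score_table()] with at least one rare-test column.
#' @param mode `"lenient"` or `"stringent"`.
#' @param cfg a [seed_selection_config()].
#' @param name name for the resulting set.
#' @return a [seed_gene_set()] with `source = "rare"`.
#' @export
select_rare_seeds <- function(table, mode = c("lenient", "stringent"),
                              cfg = seed_selection_config(),
                              name = "rare_seeds") {
  mode <- match.arg(mode)
  if (!is.data.frame(table) || nrow(table) == 0L) stop("empty score table")
  cols <- intersect(.RARE_COLS, names(table))
  if (length(cols) == 0L)
    stop("table has none of the rare-test columns: ",
         paste(.RARE_COLS, collapse = ", "))
  hit <- rep(FALSE, nrow(table))
  for (cl in cols) {
    p <- table[[cl]]
    ok <- !is.na(p)
    if (!any(ok)) next
    if (mode == "lenient") {
      q <- rep(NA_real_, length(p)); q[ok] <- bh_fdr(p[ok])
      hit <- hit | (!is.na(q) & q < cfg$rare_lenient_q)
    } else {
      m <- sum(ok)
      hit <- hit | (ok & p < cfg$rare_stringent_alpha / m)
    }
  }
  pmin_tests <- do.call(pmin, c(lapply(cols, function(cl) table[[cl]]),
                                list(na.rm = TRUE)))
  seed_gene_set(table$gene[hit], name = name, source = "rare",
                pvalues = setNames(pmin_tests[hit], table$gene[hit]),
                allow_empty = TRUE)
}

#' Filter rare variants by minor allele count
#'
#' Retains variants with `MAC > variant_mac_min` (strict), removing
#' singleton-like variants before gene-level aggregation.
#'
#' @param variant_table data frame with columns `variant`, `mac`, and
#'   optionally `p`.
#' @param cfg a [seed_selection_config()].
#' @return the filtered data frame (possibly zero rows).
#' @export
filter_variants <- function(variant_table, cfg = seed_selection_config()) {
  stopifnot(is.data.frame(variant_table))
  if (nrow(variant_table) == 0L) return(variant_table)
  if (!"mac" %in% names(variant_table)) stop("variant table needs a 'mac' column")
  mac <- variant_table$mac
  if (any(is.na(mac)) || any(mac < 0) || any(mac != floor(mac)))
    stop("MAC must be non-negative integers")
  variant_table[mac > cfg$variant_mac_min, , drop = FALSE]
}

#' Intersect a seed set with the network
#'
#' Drops seeds absent from the network (reporting them) and enforces the
#' minimum-seed rule required for a stable propagation null (n > 5 by
#' default).
#'
#' @param seeds a [seed_gene_set()].
#' @param network a [gene_network()].
#' @param cfg a [seed_selection_config()].
#' @param quiet suppress the dropped-symbol message.
#' @return a [seed_gene_set()] restricted to network nodes.
#' @export
map_seeds_to_network <- function(seeds, network, cfg = seed_selection_config(),
                                 quiet = FALSE) {
  stopifnot(inherits(seeds, "seed_gene_set"), inherits(network, "gene_network"))
  keep <- seeds$genes %in% network$nodes
  dropped <- seeds$genes[!keep]
  kept <- seeds$genes[keep]
  if (length(kept) < cfg$min_seeds)
    stop(sprintf(
      "too few seeds after network mapping: %d mapped, need >= %d (n > %d rule)",
      length(kept), cfg$min_seeds, cfg$min_seeds - 1L))
  if (!quiet && length(dropped))
    message(sprintf("map_seeds_to_network: dropped %d seed(s) not in network: %s",
                    length(dropped),
                    paste(head(dropped, 10L), collapse = ", ")))
  seed_gene_set(kept, name = seeds$name, source = seeds$source,
                pvalues = if (is.null(seeds$pvalues)) NULL else seeds$pvalues[kept])
}
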