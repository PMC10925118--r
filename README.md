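# rwrcoloc

Do the genes implicated by **common variants** (GWAS) and by **rare
variants** (exome gene-based tests) for the same trait converge on the same
molecular network? `rwrcoloc` answers that question with a network
colocalization pipeline: each gene set is used to seed a random walk with
restart over a molecular interaction network, per-gene proximity is
calibrated against degree-matched random seed sets, and genes proximal to
*both* sources are extracted as a colocalized subnetwork whose size and
score are tested by label permutation. The package is aimed at statistical
geneticists doing gene-based follow-up of GWAS and exome studies on
PCNet-style interactomes.

## The model

Given an undirected network with column-stochastic transition matrix
`W = A D⁻¹` and a seed set *S*, propagation solves the fixed point

```
F = (1 − α) F₀ + α W F,      F₀(g) = 1/|S| for g ∈ S,   α = 0.5
```

so `F(g)` ("heat") measures proximity of gene *g* to the seeds. The
**network proximity score** is a z-score against a degree-matched null:
genes are binned by degree (≥ 10 genes per bin), each of *R* = 1000 null
seed sets replaces every seed with a random gene from the same bin, and

```
NPS(g) = ( log h(g) − mean_r log h_r(g) ) / sd_r log h_r(g)
```

Scores from the two sources combine multiplicatively,
`NPS_common-rare = NPS_common × NPS_rare`, and the colocalized network is
the subgraph induced on genes with `NPS_common-rare > 3`,
`NPS_common > 1.5` and `NPS_rare > 1.5`. Significance of the network size
and of the mean combined score comes from 10,000 permutations of the score
labels (genes seeded by both sources are permuted within their own
stratum), summarized by a one-sided Z-test.

Seed sets are derived from gene-level association tables with fixed rules:
common variants, `p < 2.6×10⁻⁶`; rare variants, Benjamini–Hochberg
`FDR < 0.25` (lenient) or per-test Bonferroni at 0.05 (stringent) across
burden/SKAT-O/SKAT with union-over-tests semantics; sets with ≤ 5
network-mapped seeds are rejected; sets above 500 seeds are handled by
100 subsamples weighted by −log₁₀ p with a 75th-percentile consensus.
Downstream, hypergeometric catalog enrichment and a tissue
differential-expression enrichment (Welch t-test per tissue vs rest,
Bonferroni p < 0.05, |logFC| ≥ 0.58) annotate the extracted network.

## Worked example

Everything below is synthetic — a 1000-gene scale-free network with a
planted 40-gene module at 10× background density, and two score tables
whose significant genes lie in the module:

```r
library(rwrcoloc)

spec  <- synthetic_spec(n_genes = 1000, module_size = 40,
                        seeds_per_source = 15, density_multiplier = 10,
                        rng_seed = 42)
truth <- make_network(spec)
tabs  <- make_seed_tables(spec, truth)
net   <- truth$network
net
#> gene_network: 1000 nodes, 4048 edges (degree range 4-119)

common <- map_seeds_to_network(select_common_seeds(tabs$common), net)
rare   <- map_seeds_to_network(select_rare_seeds(tabs$rare, "lenient"), net)

nps_c <- compute_nps(net, common, R = 500, rng_seed = 1)
nps_r <- compute_nps(net, rare,   R = 500, rng_seed = 2)
npst  <- combine_nps(nps_c, nps_r)

ext   <- extract_network(npst, net)
stats <- permutation_test(npst,
                          shared_genes = intersect(common$genes, rare$genes),
                          cfg = coloc_config(n_permutations = 10000,
                                             rng_seed = 3))
stats
#> colocalization: size 30 (null 13.35 +/- 2.39, z = 6.95, p = 1.8e-12)
#>   mean score 0.4967 (null 0.0516 +/- 0.0303, z = 14.70, p = 3.24e-49)
#>   observed/expected size ratio 2.25 [0.67, 1.35]
```

The two 15-seed sets colocalize: the extracted network holds 30 genes
where random label pairings give 13.4 ± 2.4, a 2.25-fold excess
(one-sided Z-test p = 1.8×10⁻¹²), and 11 of the 30 are planted-module
genes (hypergeometric p = 3.2×10⁻⁹ against the planted-module catalog):

```r
catal <- annotation_catalog(list(planted_module = truth$module),
                            universe = net$nodes)
annotate_catalog(ext$genes, catal)[, 1:6]
#>         category overlap category_size query_size universe_size            p
#> 1 planted_module      11            40         30          1000 3.163303e-09
```

A full pipeline run (`seeds → propagate → nps → coloc → enrich`) from
files on disk, with every artifact and parameter recorded in a manifest:

```r
run_colocalization_pipeline(list(network = "network.tsv",
                                 scores_common = "scores_common.tsv",
                                 scores_rare = "scores_rare.tsv",
                                 catalog = "catalog.gmt",
                                 out_dir = "results", rng_seed = 1))
```

or from the shell via the installed CLI
(`system.file("scripts", "rwrcoloc", package = "rwrcoloc")`), with
subcommands `seeds`, `propagate`, `nps`, `coloc`, `enrich`, `simulate`,
`run`.

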