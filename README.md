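# fmtlink

Linking reciprocal fecal microbiota transplantation (FMT) to host colonic
transcriptome changes, as one tested R pipeline.

## The problem

In a reciprocal-FMT design, two mouse genotypes — wild-type (WT) and a
knockout (KO) with a disturbed gut community — exchange fecal microbiota
after bowel cleansing, giving four groups: WT, KO, WT-FMT (WT recipients of
the KO community) and KO-FMT (KO recipients of the WT community). The
analysis must answer, in order: did the donor community engraft, and how
much of each recipient's community is donor-derived; which taxa moved; which
host genes respond to the transferred community rather than to the transfer
procedure; and which taxa do those genes track.

`fmtlink` implements that chain for anyone running or reanalyzing such a
design:

* **Microbiota profiling** — observed richness, bias-corrected Chao1
  (`S_obs + F1(F1-1)/(2(F2+1))`), Shannon H, inverse Simpson; genus
  collapsing; cumulative-sum-scaling (CSS) normalization with the adaptive
  quantile rule; paired Wilcoxon differential abundance with an exact
  tie-aware null; a two-class LDA effect-size biomarker scan; Bray–Curtis
  PERMANOVA and constrained ordination (RDA) via vegan.
* **Source attribution** — the collapsed Gibbs sampler of classical
  microbial source tracking (priors α1 = α2 = 0.001, β = 10, rarefaction to
  1000), estimating per-recipient posterior donor/self/unknown mixing
  proportions.
* **Differential expression** — a compact negative-binomial Wald engine:
  median-of-ratios size factors, moment dispersions with a calibrated
  trend and geometric shrinkage, cell-means NB GLM, BH adjustment.
* **Core signature** — genes significant in both recipient-vs-donor
  contrasts with |log2FC| > 0.58 in *opposite* directions; restoration
  labels from the cross-genotype comparisons; interaction-network pruning
  (combined score > 0.4, components ≥ 3) and ClusterONE-style cohesiveness
  clustering, `f(V) = W_in/(W_in + W_bound + p|V|)`, with Mann–Whitney
  cluster significance.
* **Integration** — per-genotype Pearson correlation of normalized
  expression against CSS taxon abundances, BH adjustment, and the
  sign-consistency filter: keep a positive correlation only when gene and
  taxon log2 fold-changes share a sign, a negative one only when they
  differ.
* **Synthetic studies** — `simulate_study()` generates the full four-group
  design (overdispersed ASV counts with genotype-specific taxa and
  asymmetric transfer rates 0.65/0.27, NB gene counts with planted
  opposite-direction effects and same-sign confounders, planted gene–taxon
  links, scored interaction modules) with a machine-readable ground-truth
  manifest, so every stage is testable against known answers.

## A worked example

```r
library(fmtlink)

cfg <- pipeline_config(output_dir = "fmt_run", seed = 7, n_perm = 999)
summary <- run_pipeline(cfg)
str(summary$counts)
#> List of 11
#>  $ n_samples             : int 40
#>  $ n_taxa                : int 120
#>  $ n_genes               : int 2000
#>  $ n_signature_genes     : int 60
#>  $ n_restored            : int 60
#>  $ n_network_nodes       : num 37
#>  $ n_network_edges       : num 61
#>  $ n_clusters            : int 7
#>  $ n_significant_clusters: int 6
#>  $ n_kept_correlations   : int 19
#>  $ fraction_genes_linked : num 0.317
summary$permanova
#>      factor df pseudo_F         R2 p_perm n_permutations
#> 1  genotype  1 7.812705 0.16559034  0.001            999
#> 2 treatment  1 2.368217 0.05019438  0.032            999
```

Reading this: the generator planted 60 opposite-direction genes, and the
signature stage recovered 60 (all classified as restored, as planted); 37 of
them are connected in the pruned interaction network (61 edges), organized
into 6 significant cohesive clusters; 19 gene–taxon correlations survive
significance and sign-consistency filtering, linking 31.7% of the signature
genes to at least one taxon. PERMANOVA attributes community variation
primarily to genotype (R² = 0.17, p = 0.001) with a smaller FMT effect
(p = 0.032). Per-sample diversity, per-taxon differential abundance, the
per-sink donor proportions, all four DE contrast tables, the network, the
clusters and the kept correlations are written as TSV files under
`fmt_run/`, with parameters, seeds and per-file checksums in
`fmt_run/summary.json`.

Each stage is equally usable on its own (e.g. `read_count_table()` +
`alpha_diversity()`, or `gibbs_source_proportions()` on your own source and
sink tables); see the function reference and the methods vignette
(`vignettes/fmtlink-methods.Rmd`).

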