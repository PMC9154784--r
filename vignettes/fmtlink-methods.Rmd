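---
title: "Methods: from reciprocal FMT microbiota profiles to host transcriptome signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from reciprocal FMT microbiota profiles to host transcriptome signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtlink)
```

# The experimental design this package models

`fmtlink` implements the computational chain of a reciprocal fecal microbiota
transplantation (FMT) study in mice: two genotypes (wild-type, WT, and a
knockout, KO, with a disturbed gut community), each of which receives the
other genotype's fecal community after bowel cleansing. Four groups result —
WT, KO, WT-FMT (WT recipients of KO microbiota) and KO-FMT (KO recipients of
WT microbiota) — with 16S amplicon profiles before and after transfer and a
colonic transcriptome per animal. The scientific questions, in pipeline
order:

1. Did the transplanted community engraft, and how much of each recipient's
   community is donor-derived? (diversity statistics, ordination, PERMANOVA,
   Gibbs-sampling source attribution)
2. Which taxa moved? (paired differential abundance, LDA effect-size scan)
3. Which host genes respond to the transferred community rather than to the
   FMT procedure itself? (negative-binomial Wald tests, opposite-direction
   signature)
4. Do those genes form coherent functional modules, and which taxa do they
   track? (cohesiveness clustering of a protein-interaction network,
   sign-consistency-filtered gene–taxon correlations)

Every stage is exercisable on synthetic data with planted ground truth, so
the whole chain can be validated end to end without the original sequencing
data.

# The synthetic study generator

`simulation_config()` / `simulate_study()` generate the four-group design.
The generator's defaults are the study conditions; they are not meant to be
tuned per analysis.

**Communities.** A base community of 120 ASVs has log-normal relative
abundances (`base_abundance_sdlog = 2.2`). This evenness was chosen so the
simulated inverse Simpson index sits near 10, the scale typical of mouse gut
16S data; an unrealistically even community also misbehaves under source
attribution (see below). A fraction `taxon_shift_fraction = 0.3` of taxa is
genotype-specific: up- or down-shifted `taxon_shift_lfc = 4` log2 units in
the KO community. The shift magnitude was set once so that, in the
constrained ordination, genotype explains on the order of a fifth of
community variation and FMT treatment a few percent — the regime this
design targets. Realized fractions vary considerably between
simulated studies (single runs between roughly 8% and 30% for genotype);
that spread is a property of 40-sample designs with skewed communities, not
a bug.

**Engraftment.** Each FMT group's expected composition is the convex mixture
of the donor-genotype composition and its own control composition at the
configured transfer rate (`fmt_transfer_rate = c(0.65, 0.27)`: the KO→WT
direction engrafts strongly, the WT→KO direction only weakly — reciprocal
engraftment is typically asymmetric). Mixing acts on
expected proportions, which is the quantity the source-attribution model
estimates. Per-sample compositions are Dirichlet draws around the group
expectation (concentration 50 — strong overdispersion of the kind real
mouse cohorts show), and counts are multinomial at log-normal library sizes
(median 20,000 reads).

**Transcriptomes.** 2,000 genes with log-normal base means and NB counts
(dispersion 0.2, log-normal size factors, median depth 5·10⁶). Planted
opposite-direction genes (60) carry a genotype effect of ±1.5 log2 units
that the FMT *swaps*: the gene sits at the WT level in WT and KO-FMT animals
and at the KO level in KO and WT-FMT animals. This makes the two
recipient-vs-donor fold-changes equal and opposite and both cross-genotype
comparisons null, so restoration is true by construction. A disjoint set of
60 same-sign confounders carries a pure treatment effect (both FMT arms
shift together) — exactly the pattern the opposite-direction filter must
reject. Planted genes are drawn from the detectably expressed stratum (base
mean ≥ 20): an effect planted on a gene with a handful of reads is not a
test of the method but of the sequencing depth.

**Planted gene–taxon correlations.** 30 planted edges (all in the WT
recipient arm, the arm the default integration focuses on) tie a planted gene's
latent mean to a genus' abundance through an exponential link: the mean is
multiplied by `exp(gamma * z)` with `z` the standardized CSS-normalized
genus abundance and `gamma = 0.7` nats per abundance standard deviation
(about one log2 unit per sd). Three deliberate choices here:

* The link is planted on the *CSS-normalized scale* that the correlation
  stage measures. Under the generator's strong compositional overdispersion
  the CSS scaling factor itself carries sampling noise, which caps any
  correlation between expression and normalized abundance regardless of the
  biological link strength. Planting on the measured scale isolates what the
  planted edges are for — validating correlation detection and the
  sign-consistency filter — from normalization noise, which the CSS tests
  assess separately. Consequently, edge-recovery results should be read as
  statements about the detection and filtering stages, not about CSS
  robustness on real data.
* Planted genes get a reduced residual dispersion
  (`corr_gene_dispersion = 0.05`): a strongly microbe-driven gene is
  idealized as a low-noise readout of taxon abundance. Real microbe–host
  associations are weaker and noisier; the planted edges are a positive
  control, not a claim about effect sizes in real tissue.
* Planted taxa are restricted to genera with an unambiguous expected
  fold-change (|log2FC| ≥ 1.5 in the WT arm) that are measurable in every
  WT-FMT sample. The sign-consistency filter consumes *estimated*
  fold-change signs; a taxon whose true change is near zero has an
  unstable estimated sign, and no filter can remove "100% of inconsistent
  edges" when the inconsistency labels themselves are coin flips. When a
  community realization offers no such genus the generator falls back to
  the most strongly shifted measurable genera rather than failing.

One third of planted edges are sign-inconsistent decoys (correlation sign
contradicting the product of gene and taxon fold-change signs); the filter
must remove them all. The manifest additionally lists *implied* edges — a
gene driven by taxon T1 genuinely covaries with every taxon whose abundance
is strongly correlated (|r| ≥ 0.8) with T1 in the same samples — so that
precision is measured against the complete truth of the generating process,
while recall is measured against the planted edges only.

# Microbiome profiling

**Alpha diversity** is computed on raw, unrarefied counts — rarefying
before diversity estimation discards data, and the estimators used here do
not require even depth; the choice is recorded so comparisons to
rarefaction-based workflows are made knowingly. Chao1 uses the bias-corrected form
`S_obs + F1(F1−1)/(2(F2+1))`, which stays defined without doubletons and
reduces to observed richness when F1 ≤ 1. Shannon's H is reported in natural
log (recorded in the output's `shannon_base` attribute).

**Genus collapsing** sums ASVs within identical Phylum..Genus lineages;
ASVs without a genus assignment are pooled per finest assigned rank under an
`unclassified_<rank>` label, so column sums are conserved exactly.

**CSS normalization.** The per-sample factor is the sum of counts at or
below a chosen quantile of the sample's nonzero counts; normalized values
are `count/factor × 1000`. The quantile is chosen adaptively: per-sample
nonzero-quantile profiles are compared to their cross-sample mean and the
smallest probability at which the median relative deviation profile starts
moving by more than 10% is selected, floored at the median (the original
CSS implementation's own fallback behavior). The floor matters: on strongly
skewed communities an unbounded instability rule can select a tiny quantile
whose factor is a handful of reads — pure noise.

**Paired differential abundance** uses a two-sided Wilcoxon signed-rank test
on CSS-normalized abundances of pre/post pairs. The null distribution is
computed *exactly* by sign-flip convolution (ties among absolute differences
handled with midranks) for up to 16 informative pairs; zero differences are
dropped per the classical procedure and taxa with fewer than three
informative pairs are reported as NA. The taxon fold-change entering the
sign-consistency rule downstream is the median paired log2 ratio with
pseudocount 1 (the construction is not specified by the upstream
literature; the median paired ratio is robust and sign-stable).

**LDA effect-size scan** (`lefse_lite()`): clades expanded over phylum..genus
at per-mille scale, a Kruskal–Wallis gate at α = 0.05, then a bootstrapped
(30 rounds, 2/3 subsampling) one-dimensional discriminant effect size
reported as log10, passing at 2.0. The within-class subclass stage of the
original procedure is omitted — this design has no subclasses.

**PERMANOVA and RDA** delegate to vegan (`adonis2`, `rda`/`anova.cca`) with
sequential sums of squares; Bray–Curtis on CSS-normalized genus tables is
the default distance (the upstream methods do not name one; Bray–Curtis is
the field default and the choice is configurable).

# Source attribution

`gibbs_source_proportions()` implements the collapsed Gibbs sampler of the
classical microbial source-tracking model. Each sink read carries a latent
environment label (one per source environment plus "unknown"). Every
environment's taxon distribution is estimated from its current read mass —
known environments start from their rarefied, per-environment-summed
training counts, the unknown from zero — smoothed by a per-taxon
pseudocount β = 10, and the collapsed mixing factor gives each known
environment prior mass `depth·α1` and the unknown `depth·α2` (defaults
α1 = α2 = 0.001, rarefaction depth 1000). Allowing sink reads to
update the source distributions is essential, not cosmetic: holding the
source distributions fixed leaves a likelihood degeneracy in which the
adaptive unknown environment explains mixture sinks as well as the true
sources do and absorbs a large, arbitrary share of the reads.

Estimates average 25 recorded sweeps after 100 burn-in sweeps within each of
10 restarts; the reported `sd` is the spread across restart means.
Environments are processed in a canonical alphabetical order internally, so
relabelling or reordering sources permutes outputs without changing them.

Two properties of the model worth knowing. First, the unknown environment's
smoothed distribution puts probability ≈ β/(β·T) = 1/T on every taxon, so
evidence carried by taxa rarer than ~1/T leaks toward "unknown"; with
realistic (skewed) communities most reads sit far above this floor and the
leak is negligible, which is one reason the generator's community evenness
matters. Second, the reported donor fraction is the posterior read-mixing
proportion. Engraftment is often described loosely as "% of taxa
transferred", which is ambiguous between a mixing proportion and a
taxon-count overlap; this package computes the mixing proportion, which is
what the underlying model estimates.

# Differential expression

The NB-Wald engine is deliberately compact: median-of-ratios size factors;
method-of-moments per-gene dispersions pooled over within-group
mean/variance pairs; a log-linear dispersion–mean trend fitted by robust
regression; and a Wald test from a cell-means NB GLM fitted by Newton
iterations with expected-information standard errors and two-sided normal
p-values, BH-adjusted per contrast. Exact numerical parity with the large
established DE packages is a non-goal (one of them serves as an independent
cross-check in the test suite); statistical calibration is the quality bar.

Two corrections make the moment pipeline calibrated. The robust log-scale
trend targets the geometric center of the right-skewed raw estimates and
therefore underestimates the dispersion *level*; the trend is recalibrated
on the arithmetic scale (winsorized mean ratio over all estimable genes —
including clamped zeros, so equidispersed data keep a near-zero trend). The
final dispersion shrinks the (skew-corrected) raw estimate toward the
calibrated trend with prior weight `prior_df = 20` against ~10 residual
degrees of freedom in the default design. The heavy moderation is a
small-sample choice: per-gene estimates at n = 6–10 per group are noisy and
plugging noisy dispersions into a Wald test inflates the type-I error by
convexity. On 5000-gene null simulations (α = 0.2, 6 vs 6) the realized
rejection rate at p < 0.05 is ≈ 0.056–0.062, against ≈ 0.050–0.059 for an
oracle that knows the true dispersion — i.e. most of the residual excess is
the normal approximation at 10 degrees of freedom, not the estimator. The
price of moderation is insensitivity to genuine per-gene dispersion
outliers; with thousands of samples one would lower `prior_df`.

Genes with zero counts across both contrast groups are excluded before
testing and the BH family is the tested genes of that contrast. Cell-means
parameterization avoids reference-level ambiguity in the four-group design;
a group with all-zero counts is floored at half a read to keep the fit
finite, and such fits are flagged via the `converged` column.

Over-representation (`ora_enrichment()`) is the plain upper-tail
hypergeometric with `expected = de_size × set_size / universe`, matching the
gene-ratio/background-ratio convention of standard GO tooling. Gene sets and
annotations are inputs; no annotation database ships with the package.

# Core signature, network, clusters

A gene joins the **opposite-direction signature** exactly when both
recipient-vs-donor contrasts are significant (padj < 0.05), both |log2FC|
strictly exceed 0.58, and the fold-changes disagree in sign. The threshold
is interpreted strictly (a fold-change of exactly 0.58 is excluded); the
upstream description uses both ">0.58" and ">±0.58" and does not settle
ties. **Restoration** requires non-significance in *both* cross-genotype
comparisons when the gene is present in both — the stricter of the two
readings of "no longer differentially expressed"; genes present in only one
cross contrast are judged on that one, and genes in neither get NA.

The **interaction network** is the induced subgraph of the signature genes
over a scored edge list (a STRING-like export is an input, never fetched),
keeping edges with combined score strictly above 0.4 and deleting components
smaller than 3 (singletons and two-gene clusters).

**Cohesiveness clustering** maximizes `f(V) = W_in/(W_in + W_bound + p·|V|)`
with penalty p = 2. The search grows/shrinks greedily from every vertex and
every edge-endpoint pair, escapes one-move local optima through improving
add+remove swaps, and finishes with a bounded agglomerative phase that
reruns the search from unions of connected candidate pairs (at most 3
rounds over the 25 most cohesive candidates) — growth alone cannot assemble
an optimum whose intermediate states dip below the objective. Strongly
overlapping candidates (match coefficient |A∩B|²/(|A||B|) ≥ 0.8) are merged,
keeping whichever of the regrown union or either member scores best, so
merging deduplicates without ever degrading the objective. Cluster
significance is a one-sided Mann–Whitney test of members' in-cluster versus
boundary edge weights. On random graphs of up to 12 vertices the search
attains the exhaustive-enumeration optimum; on larger networks it is a
heuristic with the same guarantees as the greedy family it belongs to.

# Gene–taxon integration

Within one genotype's FMT arm, every signature gene's `log2(normalized
count + 1)` expression is correlated (Pearson) against every genus'
CSS-normalized abundance; p-values are two-sided t-based and BH-adjusted
over all gene×taxon pairs of that genotype (the more conservative of the
plausible adjustment families). Candidates at padj < 0.05 then pass the
sign-consistency rule: a positive correlation is kept only when the gene's
and taxon's log2 fold-changes share a sign, a negative one only when they
differ; genes are additionally restricted to the opposite-direction set
with |log2FC| > 0.58. The filter is a pure predicate — it never adds
edges and is idempotent — and the two genotypes' edge sets are computed on
disjoint samples. The kept edges and the interaction network assemble into
a mixed graph with gene and taxon nodes, correlation and interaction edge
types, and a per-run report of the fraction of signature genes linked to at
least one taxon.

# Problem sizes, determinism, limitations

The validation suite runs the full default design (40 samples, 120 ASVs,
2,000 genes) for the end-to-end checks and smaller designs (300–500 genes,
6 samples per group) for per-stage unit tests; null-calibration simulations
use 5,000 genes and permutation tests 199–999 permutations. These sizes
were chosen to give stable Monte-Carlo estimates at interactive runtimes.
Every stochastic stage draws from R's RNG under a seed derived from the
master seed by a fixed per-stage offset, so a pipeline run is bit-identical
across repeats and individual stages can be re-run in isolation;
`run_pipeline()` records per-file checksums in its summary to make this
checkable.

What passing the synthetic suite does *not* show: robustness to real-data
features the generator omits — read-level artifacts (chimeras, denoising
errors), phylogenetic correlation among taxa, batch effects, library
composition bias, gene–gene expression correlation beyond the planted
links, and microbe–host effects weaker than the planted idealization.
The generator validates the logic and calibration of the chain, not its
power on any particular real dataset.
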