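#' Configuration for core-signature extraction and clustering
#'
#' @param lfc_threshold strict absolute log2 fold-change gate (both
#'   contrasts).
#' @param padj_threshold adjusted-p gate (both contrasts).
#' @param score_threshold minimum interaction combined score (strict `>`).
#' @param min_cluster_size smallest reported cluster / surviving network
#'   component.
#' @param cohesiveness_penalty per-vertex penalty of the cohesiveness
#'   objective.
#' @param cluster_p_threshold significance gate for clusters.
#' @param merge_overlap match-coefficient threshold above which overlapping
#'   candidate clusters are merged.
#' @return object of class `fmt_sig_config`.
#' @export
signature_config <- function(lfc_threshold = 0.58, padj_threshold = 0.05,
                             score_threshold = 0.4, min_cluster_size = 3,
                             cohesiveness_penalty = 2.0,
                             cluster_p_threshold = 0.05,
                             merge_overlap = 0.8) {
  cfg <- as.list(environment())
  for (f in c("lfc_threshold", "padj_threshold", "score_threshold",
              "cluster_p_threshold"))
    if (cfg[[f]] <= 0) fmt_config_error(f, "must be positive")
  if (cfg$cohesiveness_penalty < 0)
    fmt_config_error("cohesiveness_penalty", "must be non-negative")
  if (cfg$min_cluster_size < 1)
    fmt_config_error("min_cluster_size", "must be >= 1")
  structure(cfg, class = "fmt_sig_config")
}

#' Extract the opposite-direction core gene signature
#'
#' A gene belongs to the signature exactly when, in both recipient-vs-donor
#' contrasts, it is significant (`padj < padj_threshold`), its absolute log2
#' fold-change strictly exceeds `lfc_threshold`, and the two fold-changes have
#' opposite signs. Genes carrying the same-sign response in both arms — the
#' mark of a treatment-only effect — are rejected.
#'
#' @param contrast_A,contrast_B results of [nb_wald_test()] for the two
#'   recipient-vs-donor contrasts (e.g. KO vs KO-FMT and WT vs WT-FMT),
#'   sharing a gene universe.
#' @param cfg `fmt_sig_config`.
#' @return data.frame: `gene_id`, `lfc_A`, `lfc_B`, `padj_A`, `padj_B`,
#'   `restored` (NA until [classify_restoration()]).
#' @export
extract_opposite_signature <- function(contrast_A, contrast_B,
                                       cfg = signature_config()) {
  shared <- intersect(contrast_A$gene_id, contrast_B$gene_id)
  if (!length(shared)) fmt_stop("extract_opposite_signature: empty shared gene universe")
  a <- contrast_A[match(shared, contrast_A$gene_id), ]
  b <- contrast_B[match(shared, contrast_B$gene_id), ]
  keep <- !is.na(a$padj) & !is.na(b$padj) &
    a$padj < cfg$padj_threshold & b$padj < cfg$padj_threshold &
    abs(a$log2FC) > cfg$lfc_threshold & abs(b$log2FC) > cfg$lfc_threshold &
    a$log2FC * b$log2FC < 0
  keep[is.na(keep)] <- FALSE
  data.frame(gene_id = shared[keep],
             lfc_A = a$log2FC[keep], lfc_B = b$log2FC[keep],
             padj_A = a$padj[keep], padj_B = b$padj[keep],
             restored = rep(NA, sum(keep)), stringsAsFactors = FALSE)
}

#' Label signature genes as restored by FMT
#'
#' A signature gene counts as restored when it is no longer significantly
#' differentially expressed in the cross-genotype comparisons of recipients
#' against the opposite genotype's control (KO-FMT vs WT and WT-FMT vs KO):
#' `padj >= padj_threshold` in both comparisons where the gene is present.
#' Genes missing from both cross contrasts get `restored = NA`.
#'
#' @param signature result of [extract_opposite_signature()].
#' @param cross_A,cross_B results of [nb_wald_test()] for the two
#'   cross-genotype comparisons.
#' @param padj_threshold significance threshold.
#' @return `signature` with the `restored` column filled.
#' @export
classify_restoration <- function(signature, cross_A, cross_B,
                                 padj_threshold = 0.05) {
  pa <- cross_A$padj[match(signature$gene_id, cross_A$gene_id)]
  pb <- cross_B$padj[match(signature$gene_id, cross_B$gene_id)]
  ns_a <- !is.na(pa) & pa >= padj_threshold
  ns_b <- !is.na(pb) & pb >= padj_threshold
  present_a <- !is.na(pa); present_b <- !is.na(pb)
  restored <- ifelse(present_a & present_b, ns_a & ns_b,
              ifelse(present_a, ns_a,
              ifelse(present_b, ns_b, NA)))
  missing <- !present_a & !present_b
  if (any(missing))
    message(sprintf("classify_restoration: %d gene(s) absent from both cross contrasts; restored = NA",
                    sum(missing)))
  signature$restored <- restored
  signature
}

#' Build and prune the signature interaction network
#'
#' Induces the interaction subgraph on the signature genes, keeps edges with
#' combined score strictly greater than `score_threshold`, and deletes every
#' connected component smaller than `min_cluster_size` (singletons and
#' two-gene clusters at the defaults).
#'
#' @param signature_genes character vector of gene ids (or a data.frame with a
#'   `gene_id` column).
#' @param edges edge data.frame (`gene_a`, `gene_b`, `score` in \[0, 1\]).
#' @param cfg `fmt_sig_config`.
#' @return weighted undirected [igraph::graph] with a `component` vertex
#'   attribute; possibly empty.
#' @export
build_network <- function(signature_genes, edges, cfg = signature_config()) {
  if (is.data.frame(signature_genes)) signature_genes <- signature_genes$gene_id
  if (any(edges$score < 0 | edges$score > 1))
    fmt_stop("build_network: edge scores must lie in [0, 1]")
  e <- edges[edges$gene_a %in% signature_genes &
             edges$gene_b %in% signature_genes &
             edges$score > cfg$score_threshold &
             edges$gene_a != edges$gene_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$gene_a, to = e$gene_b, weight = e$score),
    directed = FALSE,
    vertices = data.frame(name = signature_genes))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "max"))
  comp <- igraph::components(g)
  small <- which(comp$csize < cfg$min_cluster_size)
  g <- igraph::delete_vertices(g, which(comp$membership %in% small))
  if (igraph::vcount(g) > 0)
    igraph::V(g)$component <- igraph::components(g)$membership
  g
}
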