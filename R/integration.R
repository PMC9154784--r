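#' Pairwise gene-taxon Pearson correlations within one genotype's FMT arm
#'
#' Correlates each gene's normalized expression (log2 of size-factor-
#' normalized counts plus one) against each taxon's CSS-normalized abundance
#' over the FMT samples of one genotype. Two-sided p-values come from the
#' t-distribution with n-2 degrees of freedom; Benjamini-Hochberg adjustment
#' is applied over all gene-by-taxon pairs of the genotype. Zero-variance
#' genes or taxa are skipped with a message.
#'
#' @param expression normalized expression matrix (genes x samples); restrict
#'   the rows to the FMT-responsive genes of interest before calling.
#' @param taxa CSS-normalized taxon abundance matrix (taxa x samples).
#' @param meta sample metadata (`sample`, `genotype`, `treatment`).
#' @param genotype `"WT"` or `"KO"`: the recipient arm to analyze.
#' @return data.frame: `gene_id`, `taxon_id`, `genotype`, `r`, `p`, `padj`,
#'   `n`; one row per computable pair.
#' @export
correlate_gene_taxon <- function(expression, taxa, meta, genotype) {
  samples <- meta$sample[meta$genotype == genotype & meta$treatment == "FMT"]
  samples <- Reduce(intersect, list(samples, colnames(expression), colnames(taxa)))
  if (length(samples) < 4)
    fmt_stop("correlate_gene_taxon: fewer than 4 shared FMT samples for the genotype")
  e <- expression[, samples, drop = FALSE]
  x <- taxa[, samples, drop = FALSE]
  ve <- apply(e, 1, var); vx <- apply(x, 1, var)
  if (any(ve == 0))
    message(sprintf("correlate_gene_taxon: skipping %d zero-variance gene(s)", sum(ve == 0)))
  if (any(vx == 0))
    message(sprintf("correlate_gene_taxon: skipping %d zero-variance taxon(-a)", sum(vx == 0)))
  e <- e[ve > 0, , drop = FALSE]
  x <- x[vx > 0, , drop = FALSE]
  n <- length(samples)
  r <- cor(t(e), t(x))                       # genes x taxa
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  out <- data.frame(
    gene_id = rep(rownames(r), times = ncol(r)),
    taxon_id = rep(colnames(r), each = nrow(r)),
    genotype = genotype,
    r = as.vector(r), p = as.vector(p), n = n,
    stringsAsFactors = FALSE)
  out$padj <- p.adjust(out$p, method = "BH")
  out
}

#' Sign-consistency filter for gene-taxon correlations
#'
#' Discards candidate correlations whose sign contradicts the fold-change
#' evidence: a positive correlation is kept only when the gene's and taxon's
#' log2 fold-changes share a sign, a negative correlation only when they
#' differ. Candidates must additionally be significant (`padj <
#' padj_threshold`), and when `opposite_genes` is supplied the genes are
#' restricted to that opposite-direction set with `|gene_lfc| >
#' lfc_threshold`. Candidates missing either fold-change are dropped with an
#' `NA` verdict.
#'
#' @param candidates result of [correlate_gene_taxon()].
#' @param gene_lfc data.frame with `gene_id` and `log2FC` (the genotype's
#'   recipient-vs-donor contrast).
#' @param taxon_lfc data.frame with `taxon` and `median_lfc` (from
#'   [diff_abundance_paired()] in the same genotype).
#' @param opposite_genes optional character vector restricting the genes.
#' @param lfc_threshold strict gene |log2FC| gate.
#' @param padj_threshold significance gate on the correlation.
#' @return `candidates` with added `gene_lfc`, `taxon_lfc`, `sign_consistent`,
#'   `kept` columns.
#' @export
sign_consistency_filter <- function(candidates, gene_lfc, taxon_lfc,
                                    opposite_genes = NULL,
                                    lfc_threshold = 0.58,
                                    padj_threshold = 0.05) {
  gl <- gene_lfc$log2FC[match(candidates$gene_id, gene_lfc$gene_id)]
  tl <- taxon_lfc$median_lfc[match(candidates$taxon_id, taxon_lfc$taxon)]
  miss <- is.na(gl) | is.na(tl)
  if (any(miss))
    message(sprintf("sign_consistency_filter: %d candidate(s) missing a fold-change; dropped with NA verdict",
                    sum(miss)))
  consistent <- (candidates$r > 0 & gl * tl > 0) |
                (candidates$r < 0 & gl * tl < 0)
  consistent[miss] <- NA
  kept <- !miss & consistent & candidates$padj < padj_threshold &
    abs(gl) > lfc_threshold
  if (!is.null(opposite_genes))
    kept <- kept & candidates$gene_id %in% opposite_genes
  kept[is.na(kept)] <- FALSE
  candidates$gene_lfc <- gl
  candidates$taxon_lfc <- tl
  candidates$sign_consistent <- consistent
  candidates$kept <- kept
  candidates
}

#' Assemble the mixed gene-taxon network
#'
#' Union of the kept gene-taxon correlation edges (bipartite, "correlation"
#' type) and the gene-gene interaction network ("interaction" type), with a
#' per-node degree report and the fraction of signature genes linked to at
#' least one taxon.
#'
#' @param kept_edges filtered correlation edges (rows of
#'   [sign_consistency_filter()] output with `kept = TRUE` are used).
#' @param gene_network igraph of gene-gene interactions (may be empty).
#' @param signature_genes character vector used for the linked fraction.
#' @return list with `graph` (igraph; vertex attribute `node_type` in
#'   gene/taxon, edge attribute `edge_type`), `degrees` (named vector) and
#'   `fraction_genes_linked`.
#' @export
assemble_mixed_network <- function(kept_edges, gene_network = NULL,
                                   signature_genes = character(0)) {
  ke <- kept_edges
  if (!is.null(ke$kept)) ke <- ke[ke$kept %in% TRUE, , drop = FALSE]
  corr_df <- if (nrow(ke)) data.frame(
    from = ke$gene_id, to = paste0("taxon:", ke$taxon_id),
    weight = abs(ke$r), sign = sign(ke$r), edge_type = "correlation",
    stringsAsFactors = FALSE) else NULL
  int_df <- if (!is.null(gene_network) && igraph::ecount(gene_network) > 0) {
    df <- igraph::as_data_frame(gene_network, what = "edges")
    data.frame(from = df$from, to = df$to, weight = df$weight,
               sign = 1, edge_type = "interaction", stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(corr_df, int_df)
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), sign = numeric(0),
                        edge_type = character(0), stringsAsFactors = FALSE)
  verts <- unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = if (length(verts)) data.frame(name = verts) else NULL)
  if (igraph::vcount(g) > 0)
    igraph::V(g)$node_type <- ifelse(startsWith(igraph::V(g)$name, "taxon:"),
                                     "taxon", "gene")
  linked_genes <- unique(ke$gene_id)
  frac <- if (length(signature_genes))
    mean(signature_genes %in% linked_genes) else 0
  list(graph = g,
       degrees = if (igraph::vcount(g)) setNames(igraph::degree(g), igraph::V(g)$name)
                 else setNames(numeric(0), character(0)),
       fraction_genes_linked = frac)
}
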