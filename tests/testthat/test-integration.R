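mk_meta <- function(n = 5, genotype = "WT") {
  data.frame(sample = paste0("s", 1:n), genotype = genotype, treatment = "FMT")
}

test_that("Pearson correlations match hand computations", {
  meta <- mk_meta(5)
  expr <- matrix(1:5, 1, 5, dimnames = list("g1", meta$sample))
  taxa <- rbind(t_linear = 2 * (1:5) + 3,
                t_toy = c(2, 1, 4, 3, 5))
  colnames(taxa) <- meta$sample
  res <- correlate_gene_taxon(expr, taxa, meta, "WT")
  expect_equal(res$r[res$taxon_id == "t_linear"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$taxon_id == "t_linear"], 1e-12)
  expect_equal(res$r[res$taxon_id == "t_toy"], 0.8, tolerance = 1e-12)

  expect_error(correlate_gene_taxon(expr[, 1:3, drop = FALSE], taxa, mk_meta(3),
                                    "WT"), "fewer than 4")
})

test_that("zero-variance rows are skipped with a message", {
  meta <- mk_meta(5)
  expr <- rbind(g1 = 1:5, g2 = rep(2, 5))
  colnames(expr) <- meta$sample
  taxa <- rbind(t1 = c(5, 1, 4, 2, 3)); colnames(taxa) <- meta$sample
  expect_message(res <- correlate_gene_taxon(expr, taxa, meta, "WT"),
                 "zero-variance gene")
  expect_equal(unique(res$gene_id), "g1")
})

test_that("correlation p-values are uniform under the null", {
  set.seed(26)
  n <- 10
  meta <- mk_meta(n)
  expr <- matrix(rnorm(200 * n), 200, dimnames = list(paste0("g", 1:200),
                                                      meta$sample))
  taxa <- matrix(rnorm(10 * n), 10, dimnames = list(paste0("t", 1:10),
                                                    meta$sample))
  res <- correlate_gene_taxon(expr, taxa, meta, "WT")
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the sign-consistency predicate follows the fold-change rule", {
  cand <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                     taxon_id = c("t1", "t2", "t2", "t3"),
                     genotype = "WT",
                     r = c(0.9, 0.9, -0.8, 0.9),
                     p = 1e-6, n = 10, padj = 1e-4)
  gl <- data.frame(gene_id = c("g1", "g2"), log2FC = c(1, 1))
  tl <- data.frame(taxon = c("t1", "t2"), median_lfc = c(0.5, -0.5))
  expect_message(out <- sign_consistency_filter(cand, gl, tl),
                 "missing a fold-change")
  expect_true(out$kept[1])                 # +r, both lfc positive
  expect_false(out$kept[2])                # +r, discordant lfcs
  expect_true(out$kept[3])                 # -r, discordant lfcs
  expect_true(is.na(out$sign_consistent[4]))  # g3/t3 lfc missing
  expect_false(out$kept[4])
})

test_that("the filter restricts to the opposite-direction set and |lfc| gate", {
  cand <- data.frame(gene_id = c("g1", "g2"), taxon_id = "t1", genotype = "WT",
                     r = 0.9, p = 1e-6, n = 10, padj = 1e-4)
  gl <- data.frame(gene_id = c("g1", "g2"), log2FC = c(1, 0.5))
  tl <- data.frame(taxon = "t1", median_lfc = 0.5)
  out <- sign_consistency_filter(cand, gl, tl, opposite_genes = "g1")
  expect_true(out$kept[1])
  expect_false(out$kept[2])   # |lfc| below 0.58 and not in the set
  # pure predicate: applying it twice changes nothing
  out2 <- sign_consistency_filter(out[, names(cand)], gl, tl,
                                  opposite_genes = "g1")
  expect_equal(out2$kept, out$kept)
})

test_that("edges are computed per genotype on disjoint samples", {
  set.seed(27)
  meta <- data.frame(sample = paste0("s", 1:12),
                     genotype = rep(c("WT", "KO"), each = 6),
                     treatment = "FMT")
  expr <- matrix(rnorm(60 * 12), 60, dimnames = list(paste0("g", 1:60),
                                                     meta$sample))
  taxa <- matrix(rnorm(5 * 12), 5, dimnames = list(paste0("t", 1:5),
                                                   meta$sample))
  wt1 <- correlate_gene_taxon(expr, taxa, meta, "WT")
  # shuffling the KO samples leaves the WT edge set untouched
  perm <- meta
  ko <- perm$genotype == "KO"
  expr2 <- expr; expr2[, ko] <- expr[, sample(which(ko))]
  wt2 <- correlate_gene_taxon(expr2, taxa, perm, "WT")
  expect_equal(wt1$r, wt2$r)
})

test_that("the mixed network reports the taxon-linked gene fraction", {
  empty <- assemble_mixed_network(
    data.frame(gene_id = character(0), taxon_id = character(0),
               r = numeric(0), kept = logical(0)),
    NULL, signature_genes = c("g1", "g2"))
  expect_equal(empty$fraction_genes_linked, 0)
  expect_equal(igraph::vcount(empty$graph), 0)

  kept <- data.frame(gene_id = c("g1", "g2"), taxon_id = c("t1", "t1"),
                     r = c(0.9, -0.8), kept = TRUE)
  full <- assemble_mixed_network(kept, NULL, signature_genes = c("g1", "g2"))
  expect_equal(full$fraction_genes_linked, 1)
  expect_setequal(igraph::V(full$graph)$name[igraph::V(full$graph)$node_type == "taxon"],
                  "taxon:t1")
  expect_equal(unname(full$degrees["taxon:t1"]), 2)

  # interaction edges ride along as a second layer
  gnet <- graph_from_weights(matrix(c(0, 0.9, 0.9, 0), 2, 2,
                                    dimnames = list(c("g1", "g2"),
                                                    c("g1", "g2"))))
  mixed <- assemble_mixed_network(kept, gnet, signature_genes = c("g1", "g2"))
  expect_equal(igraph::ecount(mixed$graph), 3)
  expect_setequal(unique(igraph::E(mixed$graph)$edge_type),
                  c("correlation", "interaction"))
})
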