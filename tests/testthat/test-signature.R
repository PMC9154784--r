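mk_contrast <- function(genes, lfc, padj, label = "KO_vs_KOFMT") {
  data.frame(gene_id = genes, baseMean = 100, log2FC = lfc, se = 0.1,
             wald_z = lfc / 0.1, p = padj, padj = padj,
             contrast_label = label, stringsAsFactors = FALSE)
}

test_that("signature gates admit and reject the canonical cases", {
  a <- mk_contrast(c("g1", "g2", "g3"), c(1.0, 1.0, 0.50), c(0.01, 0.01, 0.001))
  b <- mk_contrast(c("g1", "g2", "g3"), c(-0.7, 1.2, -2.0), c(0.03, 0.01, 0.001),
                   "WT_vs_WTFMT")
  sig <- extract_opposite_signature(a, b)
  expect_equal(sig$gene_id, "g1")      # g2 same sign, g3 fails |lfc_A| gate
  expect_equal(sig$lfc_A, 1.0)
  expect_equal(sig$lfc_B, -0.7)
})

test_that("the threshold is strict and NA significance excludes", {
  a <- mk_contrast(c("g1", "g2"), c(0.58, 0.59), c(0.01, NA))
  b <- mk_contrast(c("g1", "g2"), c(-1, -1), c(0.01, 0.01), "WT_vs_WTFMT")
  sig <- extract_opposite_signature(a, b)
  expect_equal(nrow(sig), 0)           # g1 at the boundary, g2 padj NA
  expect_error(extract_opposite_signature(a, mk_contrast("zz", 1, 0.1)),
               "empty shared")
})

test_that("extraction is idempotent and order-independent", {
  set.seed(24)
  n <- 200
  a <- mk_contrast(paste0("g", 1:n), rnorm(n), runif(n))
  b <- mk_contrast(paste0("g", 1:n), rnorm(n), runif(n), "WT_vs_WTFMT")
  s1 <- extract_opposite_signature(a, b)
  perm <- sample(n)
  s2 <- extract_opposite_signature(a[perm, ], b[rev(perm), ])
  expect_setequal(s1$gene_id, s2$gene_id)
  s3 <- extract_opposite_signature(a[a$gene_id %in% s1$gene_id, ],
                                   b[b$gene_id %in% s1$gene_id, ])
  expect_setequal(s3$gene_id, s1$gene_id)
})

test_that("restoration requires non-significance in both cross comparisons", {
  sig <- data.frame(gene_id = c("g1", "g2", "g3"), lfc_A = 1, lfc_B = -1,
                    padj_A = 0.01, padj_B = 0.01, restored = NA)
  xa <- mk_contrast(c("g1", "g2"), 0.1, c(0.30, 0.01), "KOFMT_vs_WT")
  xb <- mk_contrast(c("g1", "g2"), 0.1, c(0.45, 0.80), "WTFMT_vs_KO")
  expect_message(out <- classify_restoration(sig, xa, xb),
                 "absent from both cross contrasts")
  expect_true(out$restored[out$gene_id == "g1"])    # 0.30 and 0.45
  expect_false(out$restored[out$gene_id == "g2"])   # significant in one
  expect_true(is.na(out$restored[out$gene_id == "g3"]))
})

test_that("planted fully-reversed genes classify as restored", {
  sim <- local_study(11)
  de <- local_study_de(11)
  sig <- extract_opposite_signature(de$KO, de$WT)
  sig <- classify_restoration(sig, de$xKO, de$xWT)
  planted <- sig[sig$gene_id %in% sim$truth$opposite_gene_ids, ]
  expect_gt(nrow(planted), 40)
  expect_gte(mean(planted$restored, na.rm = TRUE), 0.9)
  # the confounders with a shared-direction response are rejected
  expect_equal(sum(sig$gene_id %in% sim$truth$same_sign_gene_ids), 0)
})

test_that("network building prunes scores, singletons and two-node clusters", {
  cfg <- signature_config()
  genes <- c("a", "b", "c", "d", "e", "f")
  edges <- data.frame(
    gene_a = c("a", "b", "c", "d", "x", "a"),
    gene_b = c("b", "c", "a", "e", "y", "f"),
    score  = c(0.9, 0.9, 0.9, 0.95, 0.99, 0.4))
  g <- build_network(genes, edges, cfg)
  # triangle a-b-c survives; d-e is a two-node cluster; x,y are not signature
  # genes; the a-f edge sits exactly at the threshold and is excluded
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 3)
  expect_error(build_network(genes, transform(edges, score = score + 1), cfg),
               "scores must lie")
})

test_that("pruning never increases the graph and leaves components >= 3", {
  set.seed(25)
  genes <- paste0("g", 1:40)
  for (i in 1:10) {
    n_e <- 60
    edges <- data.frame(gene_a = sample(genes, n_e, TRUE),
                        gene_b = sample(genes, n_e, TRUE),
                        score = runif(n_e))
    g <- build_network(genes, edges, signature_config())
    expect_lte(igraph::vcount(g), length(genes))
    expect_lte(igraph::ecount(g), n_e)
    if (igraph::vcount(g) > 0)
      expect_true(all(igraph::components(g)$csize >= 3))
    expect_true(all(igraph::E(g)$weight > 0.4))
  }
})
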