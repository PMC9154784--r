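test_that("configuration errors name the offending field", {
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(taxon_shift_fraction = 1.2), "taxon_shift_fraction")
  expect_error(simulation_config(fmt_transfer_rate = c(0.5, 1.5)), "fmt_transfer_rate")
  expect_error(simulation_config(n_opposite_genes = 900, n_same_sign_genes = 900,
                                 n_genes = 1000), "n_opposite_genes")
})

test_that("fixed seed gives byte-identical simulations", {
  a <- simulate_asv_table(simulation_config(seed = 1, n_per_group = 3,
                                            n_taxa = 40))
  b <- simulate_asv_table(simulation_config(seed = 1, n_per_group = 3,
                                            n_taxa = 40))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  g1 <- simulate_gene_counts(simulation_config(seed = 2, n_genes = 300,
                                               n_opposite_genes = 20,
                                               n_same_sign_genes = 20,
                                               n_planted_correlations = 0,
                                               n_per_group = 3))
  g2 <- simulate_gene_counts(simulation_config(seed = 2, n_genes = 300,
                                               n_opposite_genes = 20,
                                               n_same_sign_genes = 20,
                                               n_planted_correlations = 0,
                                               n_per_group = 3))
  expect_identical(g1$counts, g2$counts)
})

test_that("taxon_shift_fraction = 0 leaves the genotypes indistinguishable", {
  sim <- simulate_asv_table(simulation_config(seed = 3, taxon_shift_fraction = 0,
                                              n_per_group = 4, n_taxa = 50))
  p <- sim$truth$expected_group_composition
  expect_equal(p[, "WT"], p[, "KO"])
  expect_true(all(sim$truth$genotype_taxa == "shared"))
})

test_that("full transfer makes the recipient expectation equal the donor", {
  sim <- simulate_asv_table(simulation_config(seed = 4, n_per_group = 4,
                                              fmt_transfer_rate = c(1, 1)))
  p <- sim$truth$expected_group_composition
  expect_equal(p[, "WTFMT"], p[, "KO"])
  expect_equal(p[, "KOFMT"], p[, "WT"])
  # on expectations, the FMT group sits closer to its donor than to its own
  # genotype's control
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)
  expect_lt(bc(p[, "WTFMT"], p[, "KO"]), bc(p[, "WTFMT"], p[, "WT"]))
})

test_that("group compositions are simplex-valid and manifest mixtures sum to 1", {
  sim <- simulate_asv_table(simulation_config(seed = 5, n_per_group = 3))
  expect_equal(unname(colSums(sim$truth$expected_group_composition)),
               rep(1, 4), tolerance = 1e-9)
  for (mix in sim$truth$source_mixtures)
    expect_equal(sum(mix), 1, tolerance = 1e-9)
})

test_that("planted opposite genes have anti-correlated true fold-changes", {
  sim <- local_study(11)
  tl <- sim$truth$gene_true_lfc
  opp <- tl[tl$gene %in% sim$truth$opposite_gene_ids, ]
  expect_true(all(opp$lfc_KO_vs_KOFMT * opp$lfc_WT_vs_WTFMT < 0))
  expect_equal(abs(opp$lfc_KO_vs_KOFMT), rep(1.5, nrow(opp)))
  same <- tl[tl$gene %in% sim$truth$same_sign_gene_ids, ]
  expect_true(all(same$lfc_KO_vs_KOFMT * same$lfc_WT_vs_WTFMT > 0))
})

test_that("null effect size leaves all true fold-changes at zero", {
  sim <- simulate_gene_counts(simulation_config(seed = 6, effect_lfc = 0,
                                                n_genes = 200,
                                                n_opposite_genes = 10,
                                                n_same_sign_genes = 10,
                                                n_planted_correlations = 0,
                                                n_per_group = 3))
  expect_length(sim$truth$opposite_gene_ids, 10)
  expect_true(all(sim$truth$gene_true_lfc$lfc_KO_vs_KOFMT == 0))
})

test_that("planted correlation genes track their taxon at the latent level", {
  sim <- local_study(11)
  pe <- sim$truth$planted_edges
  lat <- sim$truth$latent_mu_planted
  meta <- sim$genes$meta
  wtfmt <- meta$sample[meta$group == "WTFMT"]
  genus <- collapse_genus(sim$asv$counts, sim$asv$taxonomy)
  gprop <- sweep(unclass(genus), 2, colSums(genus), "/")
  for (k in seq_len(nrow(pe))) {
    r <- cor(log(lat[k, wtfmt]), gprop[pe$taxon[k], wtfmt])
    expect_gt(r * pe$sign[k], 0)
  }
  # every planted edge references an existing gene and taxon
  expect_true(all(pe$gene %in% rownames(sim$genes$counts)))
  expect_true(all(pe$taxon %in% rownames(genus)))
})

test_that("interaction-edge simulation respects threshold logic and modules", {
  cfg <- simulation_config(seed = 7)
  ids <- sprintf("g%02d", 1:12)
  # scores all below 0.4: nothing survives the strict score filter
  low <- simulate_interaction_edges(cfg, ids, module_genes = list(ids[1:6]),
                                    p_within = 1, p_background = 0,
                                    score_within = c(0.1, 0.39))
  g_low <- build_network(ids, low$edges, signature_config())
  expect_equal(igraph::vcount(g_low), 0)
  # zero background, one fully connected module: pruned network = the module
  mod <- simulate_interaction_edges(cfg, ids, module_genes = list(ids[1:6]),
                                    p_within = 1, p_background = 0)
  g_mod <- build_network(ids, mod$edges, signature_config())
  expect_setequal(igraph::V(g_mod)$name, ids[1:6])
})

test_that("written simulations are readable and consistent", {
  sim <- local_study(11)
  d <- file.path(tempdir(), "simout")
  write_simulation(sim, d)
  counts <- read_count_table(file.path(d, "asv_counts.tsv"))
  expect_identical(unclass(counts), unclass(sim$asv$counts))
  meta <- read_sample_metadata(file.path(d, "metadata.tsv"))
  expect_equal(meta$sample, sim$asv$meta$sample)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_length(truth$opposite_gene_ids, 60)
  tax <- read_taxonomy(file.path(d, "taxonomy.tsv"))
  expect_true(all(rownames(counts) %in% tax$feature_id))
})
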