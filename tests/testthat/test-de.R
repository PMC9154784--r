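test_that("size factors match the median-of-ratios definition", {
  m <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L))
  rownames(m2) <- paste0("g", 1:3)
  sf <- size_factors(m2)
  expect_equal(unname(sf["b"] / sf["a"]), 2)

  # brute-force recomputation from the definition on a random table
  set.seed(20)
  m3 <- matrix(rnbinom(300, mu = 50, size = 5) + 1L, 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  geo <- exp(rowMeans(log(m3)))
  brute <- apply(m3 / geo, 2, median)
  brute <- brute / exp(mean(log(brute)))
  expect_equal(size_factors(m3), brute, tolerance = 1e-12)
})

test_that("size-factor fallback engages when no gene is always nonzero", {
  set.seed(29)
  m <- matrix(rnbinom(200, mu = 3, size = 1), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  m[cbind(1:50, (0:49) %% 4 + 1)] <- 0L   # every gene has a zero somewhere
  expect_warning(sf <- size_factors(m), "positive counts only")
  expect_true(all(sf > 0))
})

test_that("dispersion estimation recovers the truth and clamps at zero", {
  grp <- rep(c("A", "B"), each = 6)
  set.seed(21)
  mu <- rlnorm(2000, log(100), 1)
  nb <- cbind(matrix(rnbinom(2000 * 6, mu = mu, size = 5), 2000),
              matrix(rnbinom(2000 * 6, mu = mu, size = 5), 2000))
  dimnames(nb) <- list(paste0("g", 1:2000), paste0("s", 1:12))
  d_nb <- estimate_dispersion(nb, size_factors(nb), grp)
  expect_gt(median(d_nb$final_alpha), 0.1)
  expect_lt(median(d_nb$final_alpha), 0.4)

  pois <- sapply(1:12, function(j) rpois(2000, mu))
  dimnames(pois) <- dimnames(nb)
  d_p <- estimate_dispersion(pois, size_factors(pois), grp)
  expect_lte(median(d_p$final_alpha), 0.01)

  # a gene with variance below its mean clamps to zero and follows the trend
  under <- which(d_nb$raw_alpha == 0)
  if (length(under))
    expect_true(all(d_nb$final_alpha[under] <= d_nb$fitted_alpha[under]))

  expect_error(estimate_dispersion(nb[, 1:2], c(1, 1), c("A", "B")),
               "no group has replicates")
})

test_that("identical groups give zero fold-change and p near 1", {
  m <- matrix(rep(c(30L, 100L, 7L), 4), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  grp <- rep(c("A", "B"), each = 2)
  disp <- data.frame(gene_id = rownames(m), baseMean = rowMeans(m),
                     raw_alpha = 0.1, fitted_alpha = 0.1, final_alpha = 0.1)
  de <- nb_wald_test(m, grp, c("A", "B"), sf = setNames(rep(1, 4), colnames(m)),
                     dispersions = disp)
  expect_equal(de$log2FC, rep(0, 3), tolerance = 1e-8)
  expect_true(all(de$p > 0.999))
  expect_equal(unique(de$contrast_label), "A_vs_B")
})

test_that("contrast direction antisymmetry and sign coherence", {
  sim <- local_study(11)
  meta <- sim$genes$meta
  de <- local_study_de(11)
  rev_de <- nb_wald_test(sim$genes$counts, meta$group, c("KOFMT", "KO"),
                         de$sf, de$disp)
  expect_equal(de$KO$log2FC, -rev_de$log2FC, tolerance = 1e-10)
  expect_equal(de$KO$wald_z, -rev_de$wald_z, tolerance = 1e-10)
  expect_equal(de$KO$p, rev_de$p, tolerance = 1e-10)
  ok <- !is.na(de$KO$wald_z) & de$KO$log2FC != 0
  expect_true(all(sign(de$KO$log2FC[ok]) == sign(de$KO$wald_z[ok])))
  expect_true(all(de$KO$padj >= de$KO$p, na.rm = TRUE))
})

test_that("scaling one sample's counts scales its factor and not the lfc", {
  set.seed(22)
  m <- matrix(rnbinom(200 * 8, mu = 80, size = 5) + 1L, 200, 8,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  grp <- rep(c("A", "B"), each = 4)
  de1 <- nb_wald_test(m, grp, c("A", "B"))
  m2 <- m; m2[, 1] <- m2[, 1] * 3L
  sf1 <- size_factors(m); sf2 <- size_factors(m2)
  expect_equal(unname(sf2[1] / sf1[1] / (sf2[2] / sf1[2])), 3, tolerance = 1e-9)
  de2 <- nb_wald_test(m2, grp, c("A", "B"))
  expect_equal(de1$log2FC, de2$log2FC, tolerance = 0.02)
})

test_that("estimates agree with DESeq2 on a common simulation", {
  set.seed(23)
  n <- 400
  mu <- rlnorm(n, log(150), 1)
  lfc <- c(rep(0, n - 40), sample(c(-1.5, 1.5), 40, replace = TRUE))
  cnt <- cbind(matrix(rnbinom(n * 5, mu = mu, size = 5), n),
               matrix(rnbinom(n * 5, mu = mu * 2^lfc, size = 5), n))
  dimnames(cnt) <- list(paste0("g", 1:n), paste0("s", 1:10))
  grp <- rep(c("A", "B"), each = 5)
  ours <- nb_wald_test(cnt, grp, c("A", "B"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(cnt, S4Vectors::DataFrame(
      condition = factor(grp, levels = c("A", "B"))), ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  })
  ok <- !is.na(ours$log2FC) & !is.na(ref$log2FoldChange)
  expect_gt(cor(ours$log2FC[ok], ref$log2FoldChange[ok]), 0.98)
  # calls at padj < 0.05 substantially agree
  call_ours <- which(ours$padj < 0.05)
  call_ref <- which(ref$padj < 0.05)
  expect_gt(length(intersect(call_ours, call_ref)) /
              max(1, length(union(call_ours, call_ref))), 0.7)
})

test_that("hypergeometric enrichment matches exact tail sums", {
  res <- ora_enrichment(paste0("g", 1:20),
                        list(set1 = paste0("g", c(1, 2, 30:37))),
                        paste0("g", 1:100))
  expect_equal(res$overlap, 2)
  expect_equal(res$expected, 20 * 10 / 100)
  expect_equal(res$p_hyper, sum(dhyper(2:10, 10, 90, 20)), tolerance = 1e-12)

  # overlap 9 of a 10-set against 20 DE genes: essentially impossible by chance
  res2 <- ora_enrichment(paste0("g", 1:20),
                         list(set1 = paste0("g", c(1:9, 50))),
                         paste0("g", 1:100))
  expect_lt(res2$p_hyper, 1e-5)

  # degenerate full overlap
  res3 <- ora_enrichment(paste0("g", 1:10), list(s = paste0("g", 1:10)),
                         paste0("g", 1:10))
  expect_equal(res3$p_hyper, 1)
  expect_equal(res3$expected, 10)
  expect_error(ora_enrichment("g1", list(s = "g1"), character(0)),
               "empty universe")
})
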