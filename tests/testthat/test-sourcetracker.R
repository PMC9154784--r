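test_that("rarefaction keeps exact-depth samples and drops shallow ones", {
  m <- matrix(c(600L, 400L,
                30L, 20L,
                5000L, 5000L), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_warning(r <- rarefy_counts(m, 1000), "below depth")
  expect_equal(colnames(r), c("s1", "s3"))
  expect_equal(unname(r[, "s1"]), c(600, 400))  # already at depth
  expect_equal(sum(r[, "s3"]), 1000)

  r1 <- rarefy_counts(m[, "s3", drop = FALSE], 1, seed = 1)
  expect_equal(sum(r1), 1)
  expect_equal(sum(r1 > 0), 1)

  expect_error(rarefy_counts(m[, "s2", drop = FALSE], 1000), "below the rarefaction depth")
})

test_that("rarefaction is unbiased for taxon proportions", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  m <- matrix(as.integer(p * 20000), 4, 1,
              dimnames = list(paste0("t", 1:4), "s"))
  set.seed(99)
  depth <- 500
  draws <- replicate(200, rarefy_counts(m, depth)[, 1])
  mc_se <- sqrt(depth * p * (1 - p)) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - depth * p) < 3 * mc_se + 1e-9))
})

test_that("source-attribution configuration is validated", {
  expect_error(source_attribution_config(alpha1 = 0), "alpha1")
  expect_error(source_attribution_config(rarefaction_depth = 0.5),
               "rarefaction_depth")
})

test_that("disjoint-support sources are attributed almost entirely", {
  set.seed(14)
  T <- 90
  pA <- c(rlnorm(30, 0, 1), rep(0, 60)); pA <- pA / sum(pA)
  pB <- c(rep(0, 30), rlnorm(30, 0, 1), rep(0, 30)); pB <- pB / sum(pB)
  src <- cbind(rmultinom(3, 3000, pA), rmultinom(3, 3000, pB))
  dimnames(src) <- list(paste0("t", 1:T), paste0("src", 1:6))
  sink_A <- rmultinom(2, 3000, pA)
  dimnames(sink_A) <- list(rownames(src), c("k1", "k2"))
  est <- gibbs_source_proportions(src, rep(c("A", "B"), each = 3), sink_A,
                                  source_attribution_config(seed = 2))
  expect_true(all(est$proportions[, "A"] >= 0.95))

  # a sink living on taxa absent from every source goes to "unknown"
  set.seed(15)
  alien <- matrix(0L, T, 1, dimnames = list(rownames(src), "alien"))
  alien[61:90, 1] <- as.integer(rmultinom(1, 3000, rep(1 / 30, 30)))
  est2 <- gibbs_source_proportions(src, rep(c("A", "B"), each = 3), alien,
                                   source_attribution_config(seed = 3))
  expect_gte(est2$proportions[, "unknown"], 0.9)
})

test_that("draws are simplex-valid and labels are order-symmetric", {
  set.seed(16)
  T <- 40
  pA <- rlnorm(T, 0, 1.5); pA <- pA / sum(pA)
  pB <- rlnorm(T, 0, 1.5); pB <- pB / sum(pB)
  src <- cbind(rmultinom(2, 2000, pA), rmultinom(2, 2000, pB))
  dimnames(src) <- list(paste0("t", 1:T), paste0("s", 1:4))
  sink <- rmultinom(1, 2000, 0.5 * pA + 0.5 * pB)
  dimnames(sink) <- list(rownames(src), "mix")
  cfg <- source_attribution_config(seed = 4, rarefaction_depth = 500,
                                   n_burnin = 30, n_draws = 10, restarts = 3)
  e1 <- gibbs_source_proportions(src, c("A", "A", "B", "B"), sink, cfg)
  expect_true(all(abs(rowSums(e1$draws$mix) - 1) < 1e-9))
  expect_true(all(e1$draws$mix >= 0 & e1$draws$mix <= 1))
  # permuting the source sample order (hence environment order) changes nothing
  perm <- c(3, 4, 1, 2)
  e2 <- gibbs_source_proportions(src[, perm], c("B", "B", "A", "A"), sink, cfg)
  expect_equal(e1$proportions, e2$proportions)
})

test_that("a 50/50 mixture of separable communities is recovered", {
  set.seed(17)
  T <- 80
  pA <- rlnorm(T, 0, 1.5); pA[41:80] <- pA[41:80] * 1e-4; pA <- pA / sum(pA)
  pB <- rlnorm(T, 0, 1.5); pB[1:40] <- pB[1:40] * 1e-4; pB <- pB / sum(pB)
  src <- cbind(rmultinom(4, 3000, pA), rmultinom(4, 3000, pB))
  dimnames(src) <- list(paste0("t", 1:T), paste0("s", 1:8))
  mix <- rmultinom(4, 3000, 0.5 * pA + 0.5 * pB)
  dimnames(mix) <- list(rownames(src), paste0("m", 1:4))
  est <- gibbs_source_proportions(src, rep(c("A", "B"), each = 4), mix,
                                  source_attribution_config(seed = 5))
  m <- colMeans(est$proportions)
  expect_lt(abs(m["A"] - 0.5), 0.10)
  expect_lt(abs(m["B"] - 0.5), 0.10)
})
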