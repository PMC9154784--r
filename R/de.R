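#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median across genes of the ratio of the
#' sample's count to the gene's geometric mean over samples, computed on genes
#' with nonzero counts in every sample. When no such gene exists the geometric
#' means are taken over positive counts only, with a warning. Factors are
#' scaled to geometric mean 1.
#'
#' @param counts gene count matrix (genes x samples).
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- unclass(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    logc <- log(counts[all_pos, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- apply(exp(sweep(logc, 1, loggeo)), 2, median)
  } else {
    warning("size_factors: no gene with nonzero counts in all samples; using positive counts only")
    logc <- log(counts)
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    keep <- is.finite(loggeo)
    ratio <- exp(sweep(logc[keep, , drop = FALSE], 1, loggeo[keep]))
    sf <- apply(ratio, 2, median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0))
    fmt_stop("size_factors: degenerate sample (non-positive factor)")
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Moderated negative-binomial dispersion estimates
#'
#' Per-gene method-of-moments "raw" dispersion from within-group means and
#' variances of size-factor-normalized counts, a log-linear mean-dispersion
#' trend fitted by robust regression ([MASS::rlm()]) and recalibrated on the
#' arithmetic scale (the log-scale fit targets the geometric center of the
#' right-skewed raw estimates, which would underestimate the dispersion
#' level), and a final value that shrinks the skew-corrected raw estimate
#' toward the trend by a weighted geometric combination (weight of the raw
#' estimate = residual degrees of freedom, weight of the trend = `prior_df`).
#' The default `prior_df` moderates strongly, which keeps the Wald test near
#' its nominal level in small designs at the cost of adaptivity to
#' gene-specific dispersion outliers.
#'
#' @param counts gene count matrix.
#' @param sf size factors from [size_factors()].
#' @param groups group label per sample (>= 2 replicates in some group).
#' @param prior_df prior weight of the trend in the shrinkage.
#' @return data.frame: `gene_id`, `baseMean`, `raw_alpha`, `fitted_alpha`,
#'   `final_alpha`.
#' @export
estimate_dispersion <- function(counts, sf, groups, prior_df = 20) {
  counts <- unclass(counts)
  groups <- as.factor(groups)
  reps <- table(groups)
  if (all(reps < 2)) fmt_stop("estimate_dispersion: no group has replicates")
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)

  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts)); df <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    m <- rowMeans(q[, idx, drop = FALSE])
    v <- apply(q[, idx, drop = FALSE], 1, var)
    zbar <- mean(1 / sf[idx])          # Poisson part of Var(y/s)
    w <- length(idx) - 1
    num <- num + w * (v - m * zbar)
    den <- den + w * m^2
    df <- df + w
  }
  raw <- pmax(0, ifelse(den > 0, num / den, NA_real_))

  ok <- which(is.finite(raw) & raw > 1e-6 & base_mean > 0)
  fitted <- rep(NA_real_, nrow(counts))
  if (length(ok) >= 10) {
    fit <- tryCatch(
      MASS::rlm(log(raw[ok]) ~ log(base_mean[ok]), maxit = 50),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- coef(fit)
      fitted <- exp(co[1] + co[2] * log(pmax(base_mean, 1e-8)))
    }
  }
  if (anyNA(fitted)) {
    med <- if (length(ok)) median(raw[ok]) else 1e-4
    fitted[is.na(fitted)] <- med
  }
  fitted <- pmax(fitted, 1e-8)

  # The robust log-scale regression targets the geometric center of the
  # right-skewed moment estimates, which underestimates the dispersion level;
  # recalibrate the trend on the arithmetic scale over all estimable genes
  # (winsorized against outliers). Including clamped-to-zero raw values keeps
  # equidispersed (Poisson-like) data at a near-zero trend.
  est <- which(is.finite(raw))
  if (length(est) >= 10) {
    rw <- pmin(raw[est], quantile(raw[est], 0.995))
    cal <- mean(rw) / mean(fitted[est])
    fitted <- pmax(fitted * max(cal, 1e-6), 1e-8)
  }

  # geometric shrinkage toward the calibrated trend; zero raw estimates are
  # floored relative to it so they are pulled to (not through) the trend, and
  # the skew of log raw around the trend is moment-matched out (b)
  raw_f <- pmax(raw, 0.01 * fitted)
  lr <- log(raw_f[ok] / fitted[ok])
  b <- if (length(ok) >= 10)
    log(mean(pmin(exp(lr), quantile(exp(lr), 0.995)))) - mean(lr) else 0
  final <- exp((df * (log(raw_f) + b) + prior_df * log(fitted)) /
                 (df + prior_df))
  final <- pmax(final, 1e-8)
  data.frame(gene_id = rownames(counts), baseMean = base_mean,
             raw_alpha = raw, fitted_alpha = fitted, final_alpha = final,
             stringsAsFactors = FALSE)
}

# Vectorized NB log-mean MLE for one group: Newton iterations on
# score U = sum (y - mu)/(1 + a*mu), info I = sum mu/(1 + a*mu), mu = s*exp(b)
fit_group_logmean <- function(y, s, alpha, max_iter = 50, tol = 1e-10) {
  tot <- rowSums(y)
  beta <- log(pmax(tot / sum(s), 1e-8))
  beta_min <- log(0.5 / sum(s))  # half-read floor for all-zero groups
  for (it in seq_len(max_iter)) {
    mu <- exp(beta) %o% s
    w <- 1 + alpha * mu
    U <- rowSums((y - mu) / w)
    I <- rowSums(mu / w)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    beta <- pmax(beta + step, beta_min)
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  list(beta = beta, info = info, converged = max(abs(step)) < 1e-4)
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' Fits, per gene, a negative-binomial GLM with log link in group-mean
#' parameterization (size factors as offsets, dispersion fixed at the
#' moderated estimate) and reports the Wald test of the log2 fold-change of
#' the second contrast group relative to the first — e.g.
#' `contrast = c("KO", "KOFMT")` tests log2(KOFMT / KO) and is labelled
#' `KO_vs_KOFMT`. Standard errors come from the expected information;
#' p-values are two-sided normal; adjustment is Benjamini-Hochberg across the
#' tested genes. Genes with zero counts in every sample of both contrast
#' groups are excluded before testing.
#'
#' @param counts gene count matrix.
#' @param groups group label per sample.
#' @param contrast length-2 character: reference group, then the group whose
#'   relative change is reported.
#' @param sf size factors; computed with [size_factors()] when `NULL`.
#' @param dispersions result of [estimate_dispersion()]; computed when `NULL`.
#' @return data.frame: `gene_id`, `baseMean`, `log2FC`, `se`, `wald_z`, `p`,
#'   `padj`, `contrast_label`, `converged`.
#' @export
nb_wald_test <- function(counts, groups, contrast, sf = NULL,
                         dispersions = NULL) {
  counts <- unclass(counts)
  groups <- as.character(groups)
  if (length(contrast) != 2 || !all(contrast %in% groups))
    fmt_stop("nb_wald_test: contrast must name two groups present in the design")
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(counts, sf, groups)
  alpha <- dispersions$final_alpha[match(rownames(counts), dispersions$gene_id)]
  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))

  ref_idx <- which(groups == contrast[1])
  alt_idx <- which(groups == contrast[2])
  tested <- rowSums(counts[, c(ref_idx, alt_idx), drop = FALSE]) > 0

  y_ref <- counts[tested, ref_idx, drop = FALSE]
  y_alt <- counts[tested, alt_idx, drop = FALSE]
  a <- alpha[tested]
  f_ref <- fit_group_logmean(y_ref, sf[ref_idx], a)
  f_alt <- fit_group_logmean(y_alt, sf[alt_idx], a)

  lfc <- (f_alt$beta - f_ref$beta) / log(2)
  se <- sqrt(1 / f_ref$info + 1 / f_alt$info) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))

  out <- data.frame(
    gene_id = rownames(counts), baseMean = base_mean,
    log2FC = NA_real_, se = NA_real_, wald_z = NA_real_,
    p = NA_real_, padj = NA_real_,
    contrast_label = paste0(contrast[1], "_vs_", contrast[2]),
    converged = NA, stringsAsFactors = FALSE)
  out$log2FC[tested] <- lfc
  out$se[tested] <- se
  out$wald_z[tested] <- z
  out$p[tested] <- p
  out$converged[tested] <- f_ref$converged && f_alt$converged
  out$padj[tested] <- p.adjust(p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation with expected counts
#'
#' Upper-tail hypergeometric test of the overlap between a differentially
#' expressed gene list and each gene set, with the expected overlap
#' `de_size * set_size / universe` (the product of the background ratio and
#' the DE list size), and Benjamini-Hochberg adjustment across sets.
#'
#' @param de_ids character vector of DE gene ids (subset of `universe`).
#' @param gene_sets named list of character vectors (subsets of `universe`).
#' @param universe character vector, the testable gene background.
#' @return data.frame: `set_id`, `overlap`, `set_size`, `de_size`, `universe`,
#'   `expected`, `p_hyper`, `padj`.
#' @export
ora_enrichment <- function(de_ids, gene_sets, universe) {
  if (!length(universe)) fmt_stop("ora_enrichment: empty universe")
  universe <- unique(universe)
  de_ids <- intersect(unique(de_ids), universe)
  n_u <- length(universe); n_de <- length(de_ids)
  res <- do.call(rbind, lapply(names(gene_sets), function(sid) {
    set <- intersect(unique(gene_sets[[sid]]), universe)
    k <- length(intersect(set, de_ids))
    data.frame(set_id = sid, overlap = k, set_size = length(set),
               de_size = n_de, universe = n_u,
               expected = n_de * length(set) / n_u,
               p_hyper = phyper(k - 1, length(set), n_u - length(set), n_de,
                                lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$padj <- p.adjust(res$p_hyper, method = "BH")
  rownames(res) <- NULL
  res
}
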