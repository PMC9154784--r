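#' Bray-Curtis distances on a normalized abundance matrix
#'
#' Thin wrapper over [vegan::vegdist()] with samples in columns (the package's
#' orientation convention).
#'
#' @param normalized abundance matrix, features x samples.
#' @param method distance method passed to vegan.
#' @return `dist` object over samples.
#' @export
sample_distances <- function(normalized, method = "bray") {
  vegan::vegdist(t(normalized), method = method)
}

#' PERMANOVA on a sample distance matrix
#'
#' Distance-based multivariate ANOVA with sequential (adonis-style) sums of
#' squares and free permutation of sample labels, via [vegan::adonis2()].
#'
#' @param d `dist` object or symmetric zero-diagonal distance matrix over
#'   samples.
#' @param meta metadata aligned to the samples of `d` (by `sample` column when
#'   labels are available, otherwise by order).
#' @param factors character vector of metadata columns, tested sequentially.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for the permutations.
#' @return data.frame: `factor`, `df`, `pseudo_F`, `R2`, `p_perm`,
#'   `n_permutations`.
#' @export
permanova <- function(d, meta, factors = c("genotype", "treatment"),
                      n_perm = 999, seed = NULL) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d)) || any(abs(diag(d)) > 1e-12))
      fmt_stop("permanova: distance matrix must be symmetric with zero diagonal")
    d <- stats::as.dist(d)
  }
  labs <- labels(d)
  if (!is.null(labs) && all(labs %in% meta$sample))
    meta <- meta[match(labs, meta$sample), , drop = FALSE]
  if (attr(d, "Size") != nrow(meta))
    fmt_stop("permanova: metadata does not match the distance matrix")
  miss <- setdiff(factors, names(meta))
  if (length(miss)) fmt_stop(sprintf("permanova: unknown factor '%s'", miss[1]))
  if (!is.null(seed)) set.seed(seed)
  form <- stats::as.formula(paste("d ~", paste(factors, collapse = " + ")))
  fit <- vegan::adonis2(form, data = meta, permutations = n_perm, by = "terms")
  rows <- seq_along(factors)
  data.frame(factor = factors,
             df = fit$Df[rows],
             pseudo_F = fit$F[rows],
             R2 = fit$R2[rows],
             p_perm = fit$`Pr(>F)`[rows],
             n_permutations = n_perm,
             stringsAsFactors = FALSE)
}

#' Constrained ordination (RDA) of normalized abundances
#'
#' Redundancy analysis of the sample-by-feature abundance matrix constrained
#' on categorical design factors, partitioning variance sequentially per
#' factor, with an ANOVA-like permutation test per term
#' ([vegan::rda()] / [vegan::anova.cca()]).
#'
#' @param normalized abundance matrix, features x samples (e.g. CSS output).
#' @param meta metadata with the constraint columns; aligned by `sample`.
#' @param constraints character vector of factor names.
#' @param n_perm permutations for the per-term test.
#' @param seed optional RNG seed.
#' @return list with `variance_fraction` (named, per factor, of total
#'   inertia), `p_perm` (named), `axis_scores` (samples x constrained axes),
#'   `taxon_loadings`, `total_inertia`, `constrained_inertia`, and the fitted
#'   `rda` object in `fit`.
#' @export
rda_constrained <- function(normalized, meta,
                            constraints = c("genotype", "treatment"),
                            n_perm = 999, seed = NULL) {
  if (all(colnames(normalized) %in% meta$sample))
    meta <- meta[match(colnames(normalized), meta$sample), , drop = FALSE]
  x <- t(unclass(normalized))
  for (f in constraints) {
    if (!f %in% names(meta)) fmt_stop(sprintf("rda_constrained: unknown constraint '%s'", f))
    if (length(unique(meta[[f]])) < 2)
      fmt_stop(sprintf("rda_constrained: constraint '%s' has fewer than 2 levels", f))
    meta[[f]] <- factor(meta[[f]])
  }
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(constraints, collapse = " + "))), meta)
  if (qr(mm)$rank < ncol(mm))
    fmt_stop("rda_constrained: aliased (collinear) constraint design")
  form <- stats::as.formula(paste("x ~", paste(constraints, collapse = " + ")))
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::rda(form, data = meta)
  an <- vegan::anova.cca(fit, by = "terms", permutations = n_perm)
  total <- fit$tot.chi
  vf <- setNames(an$Variance[seq_along(constraints)] / total, constraints)
  pp <- setNames(an$`Pr(>F)`[seq_along(constraints)], constraints)
  list(variance_fraction = vf,
       p_perm = pp,
       axis_scores = vegan::scores(fit, display = "sites",
                                   choices = seq_len(max(1, fit$CCA$rank))),
       taxon_loadings = vegan::scores(fit, display = "species",
                                      choices = seq_len(max(1, fit$CCA$rank))),
       total_inertia = total,
       constrained_inertia = fit$CCA$tot.chi,
       fit = fit)
}
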