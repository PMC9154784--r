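#' Expand a count table over taxonomic ranks
#'
#' Builds the clade-by-sample abundance table used by the LDA effect-size
#' scan: per-mille relative abundances per sample, summed at every rank from
#' phylum down to genus (clade labels are prefixed with the rank letter, e.g.
#' `p__Firmicutes`, `g__Akkermansia`).
#'
#' @param counts ASV count matrix.
#' @param taxonomy taxonomy covering every feature.
#' @return real matrix, clades x samples, in per-mille units.
#' @export
expand_clades <- function(counts, taxonomy) {
  miss <- setdiff(rownames(counts), taxonomy$feature_id)
  if (length(miss))
    fmt_stop(sprintf("expand_clades: no taxonomy row for ASV '%s'", miss[1]))
  tax <- taxonomy[match(rownames(counts), taxonomy$feature_id), , drop = FALSE]
  rel <- sweep(unclass(counts), 2, colSums(counts), "/") * 1000
  ranks <- c(Phylum = "p", Class = "c", Order = "o", Family = "f", Genus = "g")
  blocks <- lapply(names(ranks), function(rk) {
    lab <- as.character(tax[[rk]])
    keep <- nzchar(lab) & !is.na(lab)
    if (!any(keep)) return(NULL)
    m <- rowsum(rel[keep, , drop = FALSE], paste0(ranks[rk], "__", lab[keep]))
    m
  })
  do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
}

#' LDA effect-size biomarker scan (two classes)
#'
#' A compact re-expression of the LEfSe procedure for a two-class design with
#' no subclass stratum: clades (per-mille relative abundances expanded over
#' phylum..genus) are first gated by a Kruskal-Wallis test at `alpha`; the
#' survivors' effect sizes are estimated as the absolute between-class
#' difference of means along the (one-dimensional, per-feature) linear
#' discriminant axis, averaged over bootstrap rounds that subsample two thirds
#' of each class, and reported on a log10 scale. A clade passes when its
#' Kruskal-Wallis p is below `alpha` and its score reaches `lda_threshold`.
#'
#' @param clades clade abundance matrix from [expand_clades()] (per-mille).
#' @param class_labels factor-like vector, one label per sample column;
#'   exactly two levels, each with at least 3 samples.
#' @param alpha Kruskal-Wallis significance gate.
#' @param lda_threshold log10 effect-size threshold.
#' @param n_boot bootstrap rounds.
#' @param boot_fraction per-class subsampling fraction per round.
#' @return data.frame: `taxon`, `enriched_class`, `kw_p`, `lda_score`,
#'   `passes`.
#' @export
lefse_lite <- function(clades, class_labels, alpha = 0.05,
                       lda_threshold = 2.0, n_boot = 30,
                       boot_fraction = 2 / 3) {
  cls <- as.factor(class_labels)
  if (nlevels(cls) != 2)
    fmt_stop("lefse_lite: exactly two classes required")
  if (any(table(cls) < 3))
    fmt_stop("lefse_lite: every class needs at least 3 samples")
  lv <- levels(cls)
  idx1 <- which(cls == lv[1]); idx2 <- which(cls == lv[2])

  res <- do.call(rbind, lapply(rownames(clades), function(tx) {
    x <- clades[tx, ]
    kw <- if (stats::var(x) == 0) 1 else
      suppressWarnings(kruskal.test(x, cls)$p.value)
    if (is.na(kw)) kw <- 1
    m1 <- mean(x[idx1]); m2 <- mean(x[idx2])
    eff <- vapply(seq_len(n_boot), function(b) {
      s1 <- sample(idx1, max(2, floor(boot_fraction * length(idx1))))
      s2 <- sample(idx2, max(2, floor(boot_fraction * length(idx2))))
      abs(mean(x[s1]) - mean(x[s2]))
    }, numeric(1))
    score <- log10(max(mean(eff), 1e-10))
    data.frame(taxon = tx,
               enriched_class = if (m1 >= m2) lv[1] else lv[2],
               kw_p = kw, lda_score = score,
               passes = (kw < alpha) && (score >= lda_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
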