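#' Collapse ASV counts to the genus level
#'
#' Rows are summed within identical Phylum..Genus lineages. ASVs without a
#' genus assignment are grouped per finest assigned rank under an
#' `unclassified_<rank value>` label, so that no counts are discarded: column
#' sums are conserved exactly.
#'
#' @param counts validated ASV count matrix.
#' @param taxonomy taxonomy data.frame from [read_taxonomy()] covering every
#'   feature in `counts`.
#' @return count matrix with one row per collapsed lineage, labelled by genus
#'   (or `unclassified_<rank>`).
#' @export
collapse_genus <- function(counts, taxonomy) {
  miss <- setdiff(rownames(counts), taxonomy$feature_id)
  if (length(miss))
    fmt_stop(sprintf("collapse_genus: no taxonomy row for ASV '%s'", miss[1]))
  tax <- taxonomy[match(rownames(counts), taxonomy$feature_id), , drop = FALSE]
  ranks <- c("Phylum", "Class", "Order", "Family", "Genus")
  label <- vapply(seq_len(nrow(tax)), function(i) {
    vals <- as.character(tax[i, ranks])
    vals[is.na(vals)] <- ""
    if (nzchar(vals[length(ranks)])) return(vals[length(ranks)])
    assigned <- which(nzchar(vals))
    if (!length(assigned)) return("unclassified_root")
    paste0("unclassified_", vals[max(assigned)])
  }, character(1))
  out <- rowsum(unclass(counts), group = label)
  out <- out[order(rownames(out)), , drop = FALSE]
  class(out) <- c("count_table", class(out))
  out
}

# Adaptive quantile in the spirit of the original CSS method: per-sample
# nonzero-count quantile profiles are compared to their cross-sample mean
# reference, and the chosen probability is the smallest one at which the
# relative change of the median deviation profile exceeds `rel_change` (the
# point where sample quantiles start diverging). As in the original tool the
# result is floored at the median, which is also the fallback whenever the
# rule is undefined (tiny or degenerate tables).
css_adaptive_quantile <- function(counts, rel_change = 0.1) {
  probs <- seq(0.05, 0.95, by = 0.05)
  qmat <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    quantile(x[x > 0], probs = probs, type = 7, names = FALSE)
  }, numeric(length(probs)))
  if (ncol(counts) < 3 || nrow(counts) < 10) return(0.5)
  ref <- rowMeans(qmat)
  dev <- apply(abs(qmat - ref) / pmax(ref, .Machine$double.eps), 1, median)
  rel <- abs(diff(dev)) / pmax(dev[-1], .Machine$double.eps)
  hit <- which(rel > rel_change)
  p <- if (!length(hit)) 0.5 else probs[hit[1] + 1]
  if (p <= 0.5) {
    message("css_normalize: adaptive quantile at or below the median; using 0.5")
    p <- 0.5
  }
  p
}

#' Cumulative sum scaling (CSS) normalization
#'
#' For each sample, the scaling factor is the sum of the counts not exceeding
#' the chosen quantile of that sample's nonzero counts; the normalized value is
#' `count / factor * 1000`. By default the quantile is chosen by an adaptive
#' instability rule (smallest quantile at which the cross-sample quantile
#' values start changing by more than 10%), falling back to the median when the
#' rule is undefined; a fixed quantile may be supplied instead.
#'
#' @param counts validated count matrix.
#' @param quantile_p fixed quantile probability in (0, 1), or `NULL` for the
#'   adaptive rule.
#' @param log2_transform if `TRUE`, return `log2(x + 1)` of the normalized
#'   values.
#' @return list with `normalized` (real matrix, same dimnames), `factors`
#'   (per-sample scaling factors) and `quantile_used`.
#' @export
css_normalize <- function(counts, quantile_p = NULL, log2_transform = FALSE) {
  nz <- colSums(counts > 0)
  if (any(nz < 2))
    fmt_stop(sprintf("css_normalize: sample '%s' has fewer than 2 nonzero features",
                     colnames(counts)[which(nz < 2)[1]]))
  q <- if (is.null(quantile_p)) css_adaptive_quantile(counts) else quantile_p
  if (q <= 0 || q >= 1) fmt_stop("css_normalize: quantile must lie in (0, 1)")
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    qv <- quantile(x[x > 0], probs = q, type = 7, names = FALSE)
    sum(x[x <= qv])
  }, numeric(1))
  if (any(factors <= 0))
    fmt_stop("css_normalize: degenerate sample with zero scaling factor")
  names(factors) <- colnames(counts)
  normalized <- sweep(unclass(counts), 2, factors, "/") * 1000
  if (log2_transform) normalized <- log2(normalized + 1)
  list(normalized = normalized, factors = factors, quantile_used = q)
}
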