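#' Per-sample alpha diversity
#'
#' Computes, on raw (unrarefied) counts: observed richness, the bias-corrected
#' Chao1 estimator, Shannon's H (natural log) and the inverse Simpson index,
#' plus the singleton (F1) and doubleton (F2) frequencies the Chao1 estimator
#' is built from.
#'
#' Chao1 uses the bias-corrected form
#' \deqn{S_{chao1} = S_{obs} + \frac{F_1 (F_1 - 1)}{2 (F_2 + 1)}}
#' which stays defined when no doubletons are observed and reduces to the
#' observed richness when `F1 <= 1`.
#'
#' @param counts validated count matrix (features x samples).
#' @return data.frame with one row per sample: `sample_id`, `observed`,
#'   `chao1`, `shannon`, `inv_simpson`, `F1`, `F2`. Shannon's base (natural
#'   log) is recorded in the `shannon_base` attribute.
#' @export
alpha_diversity <- function(counts) {
  if (any(colSums(counts) == 0))
    fmt_stop("alpha_diversity: all-zero sample present (should have been dropped at IO)")
  res <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    p <- x / sum(x)
    data.frame(
      sample_id = colnames(counts)[j],
      observed = obs,
      chao1 = obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
      shannon = -sum(p * log(p)),
      inv_simpson = 1 / sum(p^2),
      F1 = f1, F2 = f2,
      stringsAsFactors = FALSE)
  }))
  attr(res, "shannon_base") <- "e"
  res
}
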