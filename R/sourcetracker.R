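#' Configuration for Gibbs-sampling source attribution
#'
#' Defaults follow the original microbial source-tracking tool: Dirichlet
#' prior mass 0.001 per known environment (`alpha1`) and for the unknown
#' environment (`alpha2`), a flat taxon prior `beta = 10` in the unknown
#' environment, rarefaction to 1000 reads, 100 burn-in sweeps, 25 recorded
#' draws and 10 independent restarts.
#'
#' @param alpha1 mixing prior mass per known source environment.
#' @param alpha2 mixing prior mass for the unknown environment.
#' @param beta taxon pseudocount of the unknown environment.
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param n_burnin,n_draws,restarts Gibbs schedule.
#' @param seed RNG seed.
#' @return object of class `fmt_st_config`.
#' @export
source_attribution_config <- function(alpha1 = 0.001, alpha2 = 0.001,
                                      beta = 10, rarefaction_depth = 1000,
                                      n_burnin = 100, n_draws = 25,
                                      restarts = 10, seed = 1) {
  cfg <- as.list(environment())
  for (f in c("alpha1", "alpha2", "beta"))
    if (cfg[[f]] <= 0) fmt_config_error(f, "must be positive")
  for (f in c("rarefaction_depth", "n_burnin", "n_draws", "restarts"))
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      fmt_config_error(f, "must be a positive integer")
  structure(cfg, class = "fmt_st_config")
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' ([vegan::rrarefy()]); samples already at `depth` are returned unchanged and
#' samples below `depth` are dropped with a warning.
#'
#' @param counts count matrix (features x samples).
#' @param depth target reads per sample.
#' @param seed optional RNG seed.
#' @return rarefied count matrix (possibly fewer samples).
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  if (depth < 1) fmt_stop("rarefy_counts: depth must be >= 1")
  tot <- colSums(counts)
  low <- tot < depth
  if (all(low)) fmt_stop("rarefy_counts: every sample is below the rarefaction depth")
  if (any(low))
    warning(sprintf("rarefy_counts: dropping %d sample(s) below depth %d: %s",
                    sum(low), depth, paste(colnames(counts)[low], collapse = ", ")))
  counts <- counts[, !low, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  out <- t(suppressWarnings(vegan::rrarefy(t(unclass(counts)), sample = depth)))
  storage.mode(out) <- "double"
  class(out) <- c("count_table", class(out))
  out
}

#' Posterior source proportions per sink sample
#'
#' For each sink community, estimates via collapsed Gibbs sampling the
#' posterior fraction of its reads attributable to each source environment
#' plus an "unknown" source. Source samples are rarefied and summed per
#' environment; each environment's taxon distribution is re-estimated during
#' sampling from its training counts plus the sink reads currently assigned
#' to it (the unknown environment has no training counts, so its distribution
#' is learned entirely from the assignments, smoothed by the `beta` taxon
#' prior). Proportions are averaged within each restart and
#' then across restarts; `sd` is the spread across restart means.
#'
#' Environments are processed in a canonical (alphabetical) internal order, so
#' relabelling or reordering sources permutes the output columns without
#' changing the estimates.
#'
#' @param source_counts count matrix of source samples (taxa x samples).
#' @param source_env environment label per source sample.
#' @param sink_counts count matrix of sink samples on the same taxa.
#' @param cfg `fmt_st_config` from [source_attribution_config()].
#' @return list with `proportions` (sinks x environments + "unknown"), `sd`
#'   (same shape) and `draws` (per-sink matrices of per-sweep proportions).
#' @export
gibbs_source_proportions <- function(source_counts, source_env, sink_counts,
                                     cfg = source_attribution_config()) {
  stopifnot(inherits(cfg, "fmt_st_config"))
  if (ncol(source_counts) != length(source_env))
    fmt_stop("gibbs_source_proportions: one environment label per source sample required")
  if (ncol(sink_counts) == 0) fmt_stop("gibbs_source_proportions: no sink samples")
  if (!identical(rownames(source_counts), rownames(sink_counts)))
    fmt_stop("gibbs_source_proportions: sources and sinks must share the taxon index")

  set.seed(cfg$seed)
  envs <- sort(unique(source_env))
  # canonical sample order so relabelled/reordered sources consume the RNG
  # identically (label-symmetry)
  ord <- order(colnames(source_counts))
  source_counts <- source_counts[, ord, drop = FALSE]
  source_env <- source_env[ord]
  src <- rarefy_counts(source_counts, cfg$rarefaction_depth)
  source_env <- source_env[match(colnames(src), colnames(source_counts))]
  m <- vapply(envs, function(e)
    rowSums(src[, source_env == e, drop = FALSE]), numeric(nrow(src)))
  snk <- rarefy_counts(sink_counts, cfg$rarefaction_depth)

  labels <- c(envs, "unknown")
  props <- matrix(NA_real_, ncol(snk), length(labels),
                  dimnames = list(colnames(snk), labels))
  sds <- props
  draws <- vector("list", ncol(snk))
  names(draws) <- colnames(snk)
  for (j in seq_len(ncol(snk))) {
    d <- gibbs_sink(as.integer(snk[, j]), m,
                    cfg$alpha1, cfg$alpha2, cfg$beta,
                    cfg$n_burnin, cfg$n_draws, cfg$restarts)
    colnames(d) <- labels
    restart_id <- rep(seq_len(cfg$restarts), each = cfg$n_draws)
    restart_means <- rowsum(d, restart_id) / cfg$n_draws
    props[j, ] <- colMeans(restart_means)
    sds[j, ] <- apply(restart_means, 2, sd)
    draws[[j]] <- d
  }
  list(proportions = props, sd = sds, draws = draws)
}
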