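#' Pipeline configuration
#'
#' Collects the per-stage configurations, the master seed and the output
#' directory of one reproducible end-to-end run. When `input_dir` is `NULL`
#' the synthetic-data generator provides the inputs; otherwise the directory
#' must contain `asv_counts.tsv`, `gene_counts.tsv`, `taxonomy.tsv`,
#' `metadata.tsv` and `edges.tsv` in the package's TSV dialect.
#'
#' @param output_dir directory for all stage outputs.
#' @param input_dir optional directory of pre-existing inputs.
#' @param sim `fmt_sim_config`; its seed is overridden by `seed`.
#' @param source_attribution `fmt_st_config`.
#' @param signature `fmt_sig_config`.
#' @param n_perm permutations for PERMANOVA and the RDA term tests.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it by a fixed offset so stages can be re-run individually.
#' @return object of class `fmt_pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            input_dir = NULL,
                            sim = simulation_config(),
                            source_attribution = source_attribution_config(),
                            signature = signature_config(),
                            n_perm = 999,
                            seed = 1) {
  if (!is.null(input_dir)) {
    need <- file.path(input_dir, c("asv_counts.tsv", "gene_counts.tsv",
                                   "taxonomy.tsv", "metadata.tsv", "edges.tsv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      fmt_config_error("input_dir", paste("missing input file:", miss[1]))
  }
  structure(list(output_dir = output_dir, input_dir = input_dir,
                 sim = sim, source_attribution = source_attribution,
                 signature = signature, n_perm = n_perm, seed = seed),
            class = "fmt_pipeline_config")
}

stage_seed <- function(cfg, k) (cfg$seed * 1000L + k) %% 2147483647L

#' Run the full FMT-to-transcriptome pipeline
#'
#' Orchestrates simulate (or load) -> microbiome profile -> source
#' attribution -> differential expression -> opposite-direction signature ->
#' network clustering -> gene-taxon correlation, writing every stage result
#' under the configured output directory plus a machine-readable
#' `summary.json` with parameters, seeds, per-file checksums and headline
#' counts. Any stage failure aborts with the stage name; outputs of completed
#' stages are retained.
#'
#' @param cfg `fmt_pipeline_config`.
#' @return the run summary, invisibly (a list, also written as JSON).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "fmt_pipeline_config"))
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      fmt_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                       conditionMessage(e)), class = "fmtlink_stage_error"))
  }

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if (is.null(cfg$input_dir)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- stage_seed(cfg, 1L)
    sim <- with_stage("simulate", {
      s <- simulate_study(sim_cfg)
      write_simulation(s, file.path(out, "inputs"))
      s
    })
    asv_counts <- sim$asv$counts; taxonomy <- sim$asv$taxonomy
    meta <- sim$asv$meta; gene_counts <- sim$genes$counts
    edges <- sim$edges; truth <- sim$truth
    written <- c(written, list.files(file.path(out, "inputs"), full.names = TRUE))
  } else {
    asv_counts <- read_count_table(file.path(cfg$input_dir, "asv_counts.tsv"))
    gene_counts <- read_count_table(file.path(cfg$input_dir, "gene_counts.tsv"))
    taxonomy <- read_taxonomy(file.path(cfg$input_dir, "taxonomy.tsv"))
    meta <- read_sample_metadata(file.path(cfg$input_dir, "metadata.tsv"))
    edges <- read_edge_table(file.path(cfg$input_dir, "edges.tsv"))
  }
  al <- align_tables(asv_counts, meta)
  asv_counts <- al$counts; asv_meta <- al$meta
  gl <- align_tables(gene_counts, meta)
  gene_counts <- gl$counts; gene_meta <- gl$meta

  # --- microbiome profile ----------------------------------------------
  profile <- with_stage("profile", {
    divers <- alpha_diversity(asv_counts)
    emit(divers, "alpha_diversity.tsv")
    genus <- collapse_genus(asv_counts, taxonomy)
    css <- css_normalize(genus)
    emit(data.frame(sample = names(css$factors), factor = css$factors),
         "css_factors.tsv")
    d <- sample_distances(css$normalized)
    set.seed(stage_seed(cfg, 2L))
    perm <- permanova(d, asv_meta, c("genotype", "treatment"), n_perm = cfg$n_perm)
    emit(perm, "permanova.tsv")
    rda <- rda_constrained(css$normalized, asv_meta,
                           c("genotype", "treatment"), n_perm = cfg$n_perm,
                           seed = stage_seed(cfg, 3L))
    emit(data.frame(factor = names(rda$variance_fraction),
                    variance_fraction = rda$variance_fraction,
                    p_perm = rda$p_perm), "rda.tsv")
    da <- lapply(c(WT = "WT", KO = "KO"), function(gt)
      diff_abundance_paired(css$normalized, asv_meta, genotype = gt))
    emit(da$WT, "diffabund_WT.tsv"); emit(da$KO, "diffabund_KO.tsv")
    set.seed(stage_seed(cfg, 4L))
    clades <- expand_clades(asv_counts, taxonomy)
    lef <- lapply(c(WT = "WT", KO = "KO"), function(gt) {
      sel <- asv_meta$genotype == gt
      lefse_lite(clades[, asv_meta$sample[sel], drop = FALSE],
                 asv_meta$treatment[sel])
    })
    emit(lef$WT, "lefse_WT.tsv"); emit(lef$KO, "lefse_KO.tsv")
    list(diversity = divers, genus = genus, css = css, permanova = perm,
         rda = rda, diffabund = da, lefse = lef)
  })

  # --- source attribution ----------------------------------------------
  st <- with_stage("sourcetrack", {
    src_sel <- asv_meta$treatment == "control"
    snk_sel <- asv_meta$treatment == "FMT"
    st_cfg <- cfg$source_attribution
    st_cfg$seed <- stage_seed(cfg, 5L)
    est <- gibbs_source_proportions(
      asv_counts[, asv_meta$sample[src_sel], drop = FALSE],
      asv_meta$genotype[src_sel],
      asv_counts[, asv_meta$sample[snk_sel], drop = FALSE],
      st_cfg)
    emit(data.frame(sink = rownames(est$proportions), est$proportions,
                    sd = est$sd, check.names = FALSE), "source_proportions.tsv")
    est
  })

  # --- differential expression -----------------------------------------
  de <- with_stage("de", {
    sf <- size_factors(gene_counts)
    disp <- estimate_dispersion(gene_counts, sf, gene_meta$group)
    contrasts <- list(KO_vs_KOFMT = c("KO", "KOFMT"),
                      WT_vs_WTFMT = c("WT", "WTFMT"),
                      KOFMT_vs_WT = c("WT", "KOFMT"),
                      WTFMT_vs_KO = c("KO", "WTFMT"))
    res <- lapply(contrasts, function(ct)
      nb_wald_test(gene_counts, gene_meta$group, ct, sf = sf,
                   dispersions = disp))
    for (nm in names(res)) emit(res[[nm]], paste0("de_", nm, ".tsv"))
    list(sf = sf, dispersions = disp, contrasts = res)
  })

  # --- core signature & clustering -------------------------------------
  sig <- with_stage("signature", {
    s <- extract_opposite_signature(de$contrasts$KO_vs_KOFMT,
                                    de$contrasts$WT_vs_WTFMT, cfg$signature)
    s <- classify_restoration(s, de$contrasts$KOFMT_vs_WT,
                              de$contrasts$WTFMT_vs_KO,
                              cfg$signature$padj_threshold)
    emit(s, "signature.tsv")
    s
  })
  net <- with_stage("cluster", {
    g <- build_network(sig$gene_id, edges, cfg$signature)
    if (igraph::ecount(g) > 0)
      emit(igraph::as_data_frame(g, what = "edges"), "network_edges.tsv")
    cl <- clusterone_clusters(g, cfg$signature)
    emit(cl, "clusters.tsv")
    list(graph = g, clusters = cl)
  })

  # --- gene-taxon correlation ------------------------------------------
  integ <- with_stage("correlate", {
    css_expr <- log2(sweep(unclass(gene_counts), 2, de$sf, "/") + 1)
    genus_css <- profile$css$normalized
    per_gt <- lapply(c(WT = "WT", KO = "KO"), function(gt) {
      if (!nrow(sig)) return(NULL)
      cand <- correlate_gene_taxon(css_expr[sig$gene_id, , drop = FALSE],
                                   genus_css, gene_meta, gt)
      contrast <- if (gt == "WT") de$contrasts$WT_vs_WTFMT else de$contrasts$KO_vs_KOFMT
      sign_consistency_filter(cand, contrast, profile$diffabund[[gt]],
                              opposite_genes = sig$gene_id,
                              lfc_threshold = cfg$signature$lfc_threshold,
                              padj_threshold = cfg$signature$padj_threshold)
    })
    kept <- do.call(rbind, per_gt[!vapply(per_gt, is.null, logical(1))])
    if (!is.null(kept)) emit(kept[kept$kept, , drop = FALSE], "correlations_kept.tsv")
    mixed <- assemble_mixed_network(
      if (is.null(kept)) data.frame(gene_id = character(0), taxon_id = character(0),
                                    r = numeric(0), kept = logical(0))
      else kept,
      net$graph, sig$gene_id)
    list(edges = kept, mixed = mixed)
  })

  summary <- list(
    seed = cfg$seed,
    n_perm = cfg$n_perm,
    parameters = list(sim = unclass(cfg$sim),
                      source_attribution = unclass(cfg$source_attribution),
                      signature = unclass(cfg$signature)),
    counts = list(
      n_samples = ncol(asv_counts),
      n_taxa = nrow(asv_counts),
      n_genes = nrow(gene_counts),
      n_signature_genes = nrow(sig),
      n_restored = sum(sig$restored %in% TRUE),
      n_network_nodes = igraph::vcount(net$graph),
      n_network_edges = igraph::ecount(net$graph),
      n_clusters = nrow(net$clusters),
      n_significant_clusters = sum(net$clusters$significant),
      n_kept_correlations = if (is.null(integ$edges)) 0 else sum(integ$edges$kept),
      fraction_genes_linked = integ$mixed$fraction_genes_linked),
    permanova = profile$permanova,
    rda_variance_fraction = as.list(profile$rda$variance_fraction),
    source_proportions = as.data.frame(st$proportions),
    checksums = as.list(tools::md5sum(sort(written))))
  names(summary$checksums) <- basename(sort(written))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
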