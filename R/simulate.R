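#' Configuration for the synthetic reciprocal-FMT study generator
#'
#' Bundles all knobs of the synthetic four-group design (WT, KO, WT-FMT,
#' KO-FMT). Defaults emulate a reciprocal fecal-microbiota-transplantation
#' experiment in which engraftment is strongly asymmetric between genotypes:
#' recipients of the knockout community retain about 65% donor material while
#' recipients of the wild-type community retain about 27%.
#'
#' @param n_per_group samples (animals) per experimental group.
#' @param n_taxa number of ASVs in the community.
#' @param n_genes number of genes in the transcriptome.
#' @param n_opposite_genes genes planted with opposite-direction FMT responses
#'   in the two recipient-vs-donor contrasts.
#' @param n_same_sign_genes confounder genes planted with a shared-direction
#'   (treatment-only) FMT response, which the opposite-direction filter must
#'   reject.
#' @param n_planted_correlations planted gene-taxon correlation edges (all in
#'   the WT-recipient arm).
#' @param prop_consistent_correlations fraction of planted correlations whose
#'   sign agrees with the gene and taxon fold-change signs; the remainder are
#'   deliberate sign-inconsistent decoys for the consistency filter.
#' @param nb_dispersion negative-binomial dispersion of gene counts.
#' @param effect_lfc planted absolute log2 fold-change of gene effects.
#' @param taxon_shift_fraction fraction of taxa with genotype-specific
#'   abundance.
#' @param taxon_shift_lfc absolute log2 fold-change of genotype-specific taxa.
#' @param base_abundance_sdlog log-normal sd of the base community's taxon
#'   abundances; controls community evenness (the default gives an inverse
#'   Simpson index near 10, typical of mouse gut 16S data).
#' @param fmt_transfer_rate length-2 vector: donor-material fraction retained
#'   by WT recipients of the KO community, and by KO recipients of the WT
#'   community.
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   draw around each group's expected composition (overdispersion control).
#' @param asv_libsize_meanlog,asv_libsize_sdlog log-normal parameters of ASV
#'   library sizes.
#' @param gene_libsize_meanlog,gene_libsize_sdlog log-normal parameters of
#'   gene-count library sizes.
#' @param correlation_gamma strength of the monotone link tying a planted
#'   gene's expression to its taxon's relative abundance: the gene's latent
#'   mean is multiplied by `exp(gamma * z)` with `z` the taxon's standardized
#'   abundance, so log expression is linear in abundance with slope `gamma`
#'   (in nats per abundance standard deviation).
#' @param corr_gene_dispersion residual NB dispersion of the planted
#'   correlation genes: a strongly microbe-driven gene is modeled as a
#'   low-noise readout of taxon abundance, so its non-microbial variance is
#'   far below the transcriptome-wide dispersion.
#' @param seed integer seed; every simulation function resets the RNG from it.
#' @return object of class `fmt_sim_config` (a validated list).
#' @export
simulation_config <- function(n_per_group = 10,
                              n_taxa = 120,
                              n_genes = 2000,
                              n_opposite_genes = 60,
                              n_same_sign_genes = 60,
                              n_planted_correlations = 30,
                              prop_consistent_correlations = 2 / 3,
                              nb_dispersion = 0.2,
                              effect_lfc = 1.5,
                              taxon_shift_fraction = 0.3,
                              taxon_shift_lfc = 4,
                              base_abundance_sdlog = 2.2,
                              fmt_transfer_rate = c(0.65, 0.27),
                              dirichlet_concentration = 50,
                              asv_libsize_meanlog = log(2e4),
                              asv_libsize_sdlog = 0.3,
                              gene_libsize_meanlog = log(5e6),
                              gene_libsize_sdlog = 0.25,
                              correlation_gamma = 0.7,
                              corr_gene_dispersion = 0.05,
                              seed = 1) {
  cfg <- as.list(environment())
  check_count <- function(field, x, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min)
      fmt_config_error(field, sprintf("must be a single integer >= %d", min))
  }
  check_count("n_per_group", cfg$n_per_group, 2)
  check_count("n_taxa", cfg$n_taxa, 4)
  check_count("n_genes", cfg$n_genes, 1)
  check_count("n_opposite_genes", cfg$n_opposite_genes, 0)
  check_count("n_same_sign_genes", cfg$n_same_sign_genes, 0)
  check_count("n_planted_correlations", cfg$n_planted_correlations, 0)
  check_count("seed", cfg$seed, 0)
  if (cfg$n_opposite_genes + cfg$n_same_sign_genes > cfg$n_genes)
    fmt_config_error("n_opposite_genes",
                     "planted gene sets exceed the gene universe")
  if (cfg$n_planted_correlations > max(cfg$n_opposite_genes, 0))
    fmt_config_error("n_planted_correlations",
                     "cannot exceed n_opposite_genes (one edge per gene)")
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    fmt_config_error("nb_dispersion", "must be a positive real")
  if (!is.numeric(cfg$effect_lfc) || cfg$effect_lfc < 0)
    fmt_config_error("effect_lfc", "must be a non-negative real")
  if (cfg$taxon_shift_fraction < 0 || cfg$taxon_shift_fraction >= 1)
    fmt_config_error("taxon_shift_fraction", "must lie in [0, 1)")
  if (length(cfg$fmt_transfer_rate) != 2 ||
      any(cfg$fmt_transfer_rate <= 0 | cfg$fmt_transfer_rate > 1))
    fmt_config_error("fmt_transfer_rate",
                     "must be two rates in (0, 1], one per direction")
  if (cfg$prop_consistent_correlations < 0 || cfg$prop_consistent_correlations > 1)
    fmt_config_error("prop_consistent_correlations", "must lie in [0, 1]")
  if (cfg$dirichlet_concentration <= 0)
    fmt_config_error("dirichlet_concentration", "must be positive")
  if (cfg$corr_gene_dispersion <= 0)
    fmt_config_error("corr_gene_dispersion", "must be positive")
  structure(cfg, class = "fmt_sim_config")
}

# One Dirichlet draw with concentration vector a (gamma representation).
rdirichlet1 <- function(a) {
  x <- rgamma(length(a), shape = a, rate = 1)
  if (all(x == 0)) x[which.max(a)] <- 1
  x / sum(x)
}

# Real gut genera seen in mouse 16S surveys, recycled for synthetic lineages.
.sim_genera <- c(
  "Akkermansia", "Dubosiella", "Bifidobacterium", "Jeotgalicoccus",
  "Staphylococcus", "Turicibacter", "Peptococcus", "Ruminococcus",
  "Harryflintia", "Intestinimonas", "Parasutterella", "Desulfovibrio",
  "Bilophila", "Lactobacillus", "Bacteroides", "Alistipes", "Prevotella",
  "Mucispirillum", "Roseburia", "Blautia", "Faecalibaculum", "Oscillibacter",
  "Lachnoclostridium", "Anaerotruncus", "Butyricicoccus")

.sim_phyla <- c("Firmicutes", "Bacteroidota", "Verrucomicrobiota",
                "Actinobacteriota", "Proteobacteria", "Patescibacteria",
                "Desulfobacterota")

# Deterministic synthetic 7-rank taxonomy with shared genera (about two ASVs
# per genus) and a small unassigned-genus tail to exercise collapse fallbacks.
make_taxonomy <- function(taxon_ids) {
  n <- length(taxon_ids)
  n_gen <- max(2L, ceiling(n / 2))
  gnames <- c(.sim_genera, paste0("Genus", seq_len(max(0, n_gen - length(.sim_genera)))))
  gnames <- gnames[seq_len(n_gen)]
  genus_of <- gnames[((seq_len(n) - 1L) %% n_gen) + 1L]
  phy_of_gen <- .sim_phyla[((seq_len(n_gen) - 1L) %% length(.sim_phyla)) + 1L]
  fam_of_gen <- paste0(phy_of_gen, "_fam", ((seq_len(n_gen) - 1L) %/% length(.sim_phyla)) + 1L)
  idx <- match(genus_of, gnames)
  tax <- data.frame(
    feature_id = taxon_ids,
    Kingdom = "Bacteria",
    Phylum = phy_of_gen[idx],
    Class = paste0(phy_of_gen[idx], "_class"),
    Order = paste0(phy_of_gen[idx], "_order"),
    Family = fam_of_gen[idx],
    Genus = genus_of,
    stringsAsFactors = FALSE)
  # last few ASVs lack a genus assignment (classifier failed at genus level)
  n_unassigned <- min(4L, n %/% 10L)
  if (n_unassigned > 0)
    tax$Genus[seq(n - n_unassigned + 1L, n)] <- ""
  tax
}

#' Simulate the four-group ASV count table
#'
#' Group compositions: a log-normal base community for WT; the KO community
#' shifts a configurable fraction of taxa up or down by `taxon_shift_lfc`
#' log2 units; each FMT group's expected composition is the convex mixture of
#' the donor-genotype composition and its own genotype's control composition at
#' the configured transfer rate. Per-sample compositions are Dirichlet draws
#' around the group expectation and counts are multinomial at a log-normal
#' library size (a Dirichlet-multinomial, i.e. overdispersed, count model).
#'
#' @param cfg `fmt_sim_config` from [simulation_config()].
#' @return list with `counts` (count_table), `taxonomy`, `meta`, and `truth`
#'   (ground-truth manifest: genotype taxa, expected group compositions,
#'   per-sink donor mixtures).
#' @export
simulate_asv_table <- function(cfg) {
  stopifnot(inherits(cfg, "fmt_sim_config"))
  set.seed(cfg$seed)
  n_taxa <- cfg$n_taxa
  taxon_ids <- sprintf("ASV%03d", seq_len(n_taxa))

  base <- rlnorm(n_taxa, meanlog = 0, sdlog = cfg$base_abundance_sdlog)
  p_wt <- base / sum(base)
  n_shift <- round(cfg$taxon_shift_fraction * n_taxa)
  shift_idx <- sample.int(n_taxa, n_shift)
  ko_up <- shift_idx[seq_len(ceiling(n_shift / 2))]
  wt_up <- setdiff(shift_idx, ko_up)
  w_ko <- p_wt
  w_ko[ko_up] <- w_ko[ko_up] * 2^cfg$taxon_shift_lfc
  w_ko[wt_up] <- w_ko[wt_up] * 2^(-cfg$taxon_shift_lfc)
  p_ko <- w_ko / sum(w_ko)

  genotype_taxa <- rep("shared", n_taxa)
  genotype_taxa[ko_up] <- "KO"
  genotype_taxa[wt_up] <- "WT"
  names(genotype_taxa) <- taxon_ids

  r_wtfmt <- cfg$fmt_transfer_rate[1]  # WT recipients of the KO community
  r_kofmt <- cfg$fmt_transfer_rate[2]  # KO recipients of the WT community
  p_group <- cbind(
    WT    = p_wt,
    KO    = p_ko,
    WTFMT = r_wtfmt * p_ko + (1 - r_wtfmt) * p_wt,
    KOFMT = r_kofmt * p_wt + (1 - r_kofmt) * p_ko)
  rownames(p_group) <- taxon_ids
  stopifnot(abs(colSums(p_group) - 1) < 1e-9)

  groups <- colnames(p_group)
  meta <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      sample = sprintf("%s_%d", g, seq_len(cfg$n_per_group)),
      genotype = if (g %in% c("WT", "WTFMT")) "WT" else "KO",
      treatment = if (g %in% c("WTFMT", "KOFMT")) "FMT" else "control",
      pair_id = sprintf("%s_pair_%d",
                        if (g %in% c("WT", "WTFMT")) "WT" else "KO",
                        seq_len(cfg$n_per_group)),
      stringsAsFactors = FALSE)
  }))
  meta$group <- paste0(meta$genotype, ifelse(meta$treatment == "FMT", "FMT", ""))

  counts <- matrix(0, n_taxa, nrow(meta),
                   dimnames = list(taxon_ids, meta$sample))
  for (j in seq_len(nrow(meta))) {
    pg <- p_group[, meta$group[j]]
    ps <- rdirichlet1(cfg$dirichlet_concentration * pg)
    depth <- max(1, round(rlnorm(1, cfg$asv_libsize_meanlog, cfg$asv_libsize_sdlog)))
    counts[, j] <- rmultinom(1, size = depth, prob = ps)
  }

  sinks <- meta$sample[meta$treatment == "FMT"]
  source_mixtures <- lapply(setNames(sinks, sinks), function(s) {
    if (startsWith(s, "WTFMT")) c(KO = r_wtfmt, WT = 1 - r_wtfmt)
    else c(WT = r_kofmt, KO = 1 - r_kofmt)
  })

  truth <- list(
    genotype_taxa = genotype_taxa,
    expected_group_composition = p_group,
    source_mixtures = source_mixtures,
    transfer_rates = c(WTFMT = r_wtfmt, KOFMT = r_kofmt))

  list(counts = validate_count_table(counts, "simulated ASV counts"),
       taxonomy = make_taxonomy(taxon_ids),
       meta = meta,
       truth = truth)
}

# genus-level proportions of a count matrix (pseudocount keeps logs finite)
genus_proportions <- function(counts, taxonomy) {
  coll <- collapse_genus(counts, taxonomy)
  sweep(coll + 0.5, 2, colSums(coll), "/")
}

#' Simulate the four-group gene count matrix
#'
#' Negative-binomial counts under a cell-means model. Planted
#' opposite-direction genes carry a genotype effect that the FMT fully swaps:
#' the gene sits at the WT level in WT and KO-FMT animals and at the KO level
#' in KO and WT-FMT animals, so its two recipient-vs-donor log2 fold-changes
#' are equal in magnitude and opposite in sign and both cross-genotype
#' comparisons are null (the gene is "restored"). Same-sign confounder genes
#' carry a pure treatment effect (both FMT groups shift the same way). When an
#' ASV simulation is supplied, planted correlation genes additionally couple
#' their WT-FMT expression to a genus' realized relative abundance through a
#' power link.
#'
#' @param cfg `fmt_sim_config`.
#' @param asv optional result of [simulate_asv_table()]; required to plant
#'   gene-taxon correlations against realized taxon abundances.
#' @return list with `counts`, `meta`, and `truth` (opposite/same-sign gene
#'   ids, true per-contrast log2FC, planted correlation edges, latent means of
#'   planted genes).
#' @export
simulate_gene_counts <- function(cfg, asv = NULL) {
  stopifnot(inherits(cfg, "fmt_sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(n))

  base_mean <- rlnorm(n, meanlog = log(100), sdlog = 1.2)
  # planted genes are drawn from the detectably expressed stratum
  eligible <- which(base_mean >= 20)
  need <- cfg$n_opposite_genes + cfg$n_same_sign_genes
  if (length(eligible) < need)
    fmt_stop("too few well-expressed genes to plant effects; increase n_genes")
  planted <- sample(eligible, need)
  opp_idx <- planted[seq_len(cfg$n_opposite_genes)]
  same_idx <- setdiff(planted, opp_idx)

  # genotype effect delta (log2): WT level = mu, KO level = mu * 2^delta
  delta <- rep(0, n)
  delta[opp_idx] <- sample(c(-1, 1), length(opp_idx), replace = TRUE) * cfg$effect_lfc
  tau <- rep(0, n)
  tau[same_idx] <- sample(c(-1, 1), length(same_idx), replace = TRUE) * cfg$effect_lfc

  meta <- if (!is.null(asv)) asv$meta else {
    groups <- c("WT", "KO", "WTFMT", "KOFMT")
    m <- do.call(rbind, lapply(groups, function(g) data.frame(
      sample = sprintf("%s_%d", g, seq_len(cfg$n_per_group)),
      genotype = if (g %in% c("WT", "WTFMT")) "WT" else "KO",
      treatment = if (g %in% c("WTFMT", "KOFMT")) "FMT" else "control",
      pair_id = sprintf("%s_pair_%d",
                        if (g %in% c("WT", "WTFMT")) "WT" else "KO",
                        seq_len(cfg$n_per_group)),
      stringsAsFactors = FALSE)))
    m$group <- paste0(m$genotype, ifelse(m$treatment == "FMT", "FMT", ""))
    m
  }

  # group mean matrix: genes x groups
  mu_group <- cbind(
    WT    = base_mean,
    KO    = base_mean * 2^delta,
    WTFMT = base_mean * 2^delta * 2^tau,  # swapped to KO level (+ treatment)
    KOFMT = base_mean * 2^tau)            # swapped back to WT level
  # non-planted genes: identical across groups by construction (delta=tau=0)

  # per-sample latent means
  mu <- mu_group[, meta$group, drop = FALSE]
  colnames(mu) <- meta$sample

  # planted gene-taxon correlations (WT-recipient arm)
  planted_edges <- NULL
  implied_edges <- NULL
  disp_vec <- rep(cfg$nb_dispersion, n)
  if (cfg$n_planted_correlations > 0 && !is.null(asv)) {
    gprop <- genus_proportions(asv$counts, asv$taxonomy)
    wtfmt <- meta$sample[meta$group == "WTFMT"]
    gp <- gprop[, wtfmt, drop = FALSE]
    # the link is planted on the CSS-normalized abundance scale the
    # correlation stage measures, so edge recovery validates detection and
    # sign filtering in isolation from normalization noise
    gcss <- css_normalize(collapse_genus(asv$counts, asv$taxonomy),
                          quantile_p = 0.5)$normalized[, wtfmt, drop = FALSE]
    # candidate genera: genotype-shifted with an unambiguous genus-level
    # fold-change in the WT arm (a genus can mix up- and down-shifted ASVs
    # and net out to nothing) and abundant enough to be measured reliably
    shifted <- names(asv$truth$genotype_taxa)[asv$truth$genotype_taxa != "shared"]
    shifted_gen <- unique(asv$taxonomy$Genus[asv$taxonomy$feature_id %in% shifted])
    shifted_gen <- setdiff(shifted_gen, "")
    exp_comp <- asv$truth$expected_group_composition
    genus_exp <- rowsum(exp_comp, ifelse(asv$taxonomy$Genus == "",
                                         asv$taxonomy$feature_id, asv$taxonomy$Genus))
    genus_lfc <- log2((genus_exp[, "WTFMT"] + 1e-12) / (genus_exp[, "WT"] + 1e-12))
    pool <- intersect(rownames(gp), rownames(genus_exp))
    measurable <- pool[apply(gp[pool, , drop = FALSE], 1, min) >= 5e-4]
    if (!length(measurable)) measurable <- pool
    cand <- intersect(measurable, shifted_gen)
    cand <- cand[abs(genus_lfc[cand]) >= 1.5]
    if (!length(cand)) {
      # fall back to the most strongly shifted measurable genera so the
      # planted ground truth stays recoverable for any community realization
      cand <- measurable[order(-abs(genus_lfc[measurable]))]
      cand <- cand[seq_len(min(5L, length(cand)))]
    }
    if (!length(cand))
      fmt_stop("no suitable genera to plant correlations against")
    corr_genes <- opp_idx[seq_len(cfg$n_planted_correlations)]
    corr_taxa <- sample(cand, cfg$n_planted_correlations, replace = TRUE)
    taxon_sign <- sign(genus_lfc[corr_taxa])
    gene_sign <- sign(delta[corr_genes])  # gene lfc in WTFMT vs WT is +delta
    n_cons <- ceiling(cfg$prop_consistent_correlations * cfg$n_planted_correlations)
    consistent <- seq_len(cfg$n_planted_correlations) <= n_cons
    r_sign <- ifelse(consistent, gene_sign * taxon_sign, -gene_sign * taxon_sign)
    for (k in seq_len(cfg$n_planted_correlations)) {
      tk <- gcss[corr_taxa[k], ]
      z <- (tk - mean(tk)) / max(sd(tk), 1e-12)
      link <- exp(r_sign[k] * cfg$correlation_gamma * z)
      link <- link / mean(link)  # keep the group's arithmetic mean (and lfc)
      mu[corr_genes[k], wtfmt] <- mu[corr_genes[k], wtfmt] * link
    }
    disp_vec[corr_genes] <- cfg$corr_gene_dispersion
    planted_edges <- data.frame(
      gene = gene_ids[corr_genes], taxon = corr_taxa,
      sign = as.integer(r_sign), consistent = consistent,
      genotype = "WT", stringsAsFactors = FALSE)
    # a gene driven by taxon T1 also covaries with every taxon strongly
    # correlated with T1 in these samples (compositional coupling); list
    # those implied associations so the ground truth is complete
    tcor <- suppressWarnings(
      cor(t(gcss[unique(corr_taxa), , drop = FALSE]), t(gcss)))
    imp <- do.call(rbind, lapply(seq_len(cfg$n_planted_correlations), function(k) {
      rho <- tcor[corr_taxa[k], ]
      t2 <- setdiff(names(rho)[abs(rho) >= 0.8 & !is.na(rho)], corr_taxa[k])
      if (!length(t2)) return(NULL)
      data.frame(gene = gene_ids[corr_genes[k]], taxon = t2,
                 sign = as.integer(sign(r_sign[k] * rho[t2])),
                 genotype = "WT", stringsAsFactors = FALSE)
    }))
    implied_edges <- if (is.null(imp)) imp else unique(imp)
  }

  lib <- rlnorm(nrow(meta), cfg$gene_libsize_meanlog, cfg$gene_libsize_sdlog)
  sf_true <- lib / exp(cfg$gene_libsize_meanlog)
  scale <- exp(cfg$gene_libsize_meanlog) / sum(base_mean)
  counts <- matrix(0L, n, nrow(meta), dimnames = list(gene_ids, meta$sample))
  for (j in seq_len(nrow(meta)))
    counts[, j] <- rnbinom(n, mu = mu[, j] * sf_true[j] * scale,
                           size = 1 / disp_vec)

  truth <- list(
    opposite_gene_ids = gene_ids[opp_idx],
    same_sign_gene_ids = gene_ids[same_idx],
    gene_true_lfc = data.frame(
      gene = gene_ids,
      lfc_KO_vs_KOFMT = tau - delta,  # log2(KOFMT / KO)
      lfc_WT_vs_WTFMT = delta + tau,  # log2(WTFMT / WT)
      stringsAsFactors = FALSE),
    planted_edges = planted_edges,
    implied_edges = implied_edges,
    size_factors_true = setNames(sf_true, meta$sample),
    latent_mu_planted = if (!is.null(planted_edges))
      mu[match(planted_edges$gene, gene_ids), meta$sample[meta$group == "WTFMT"],
         drop = FALSE])

  list(counts = validate_count_table(counts, "simulated gene counts"),
       meta = meta, truth = truth)
}

#' Simulate a scored protein-protein interaction edge list
#'
#' Plants cohesive modules (dense, high-score cliquish subsets) among the
#' opposite-direction genes and sprinkles random background edges over the
#' rest of the universe, mimicking a STRING combined-score export.
#'
#' @param cfg `fmt_sim_config` (used for the RNG seed).
#' @param gene_ids character vector, the network universe.
#' @param module_genes list of character vectors: planted module memberships;
#'   defaults to three disjoint 6-gene modules taken from the head of
#'   `gene_ids`.
#' @param p_within within-module edge probability.
#' @param p_background background edge probability.
#' @param score_within,score_background length-2 ranges for uniform scores.
#' @return list with `edges` (data.frame gene_a, gene_b, score) and `truth`
#'   (module memberships).
#' @export
simulate_interaction_edges <- function(cfg, gene_ids,
                                       module_genes = NULL,
                                       p_within = 0.9,
                                       p_background = 0.02,
                                       score_within = c(0.6, 0.95),
                                       score_background = c(0.2, 0.8)) {
  stopifnot(inherits(cfg, "fmt_sim_config"))
  if (length(gene_ids) == 0) fmt_stop("gene_ids must be non-empty")
  set.seed(cfg$seed + 2L)
  if (is.null(module_genes)) {
    n_mod <- min(3L, length(gene_ids) %/% 6L)
    module_genes <- lapply(seq_len(n_mod), function(m)
      gene_ids[seq((m - 1) * 6 + 1, m * 6)])
  }
  in_module <- matrix(FALSE, length(gene_ids), length(gene_ids))
  rownames(in_module) <- colnames(in_module) <- gene_ids
  for (mod in module_genes) in_module[mod, mod] <- TRUE

  pairs <- which(upper.tri(in_module), arr.ind = TRUE)
  within <- in_module[pairs]
  keep <- runif(nrow(pairs)) < ifelse(within, p_within, p_background)
  pairs <- pairs[keep, , drop = FALSE]
  within <- within[keep]
  score <- numeric(length(within))
  score[within] <- runif(sum(within), score_within[1], score_within[2])
  score[!within] <- runif(sum(!within), score_background[1], score_background[2])
  edges <- data.frame(
    gene_a = gene_ids[pairs[, 1]],
    gene_b = gene_ids[pairs[, 2]],
    score = round(score, 4),
    stringsAsFactors = FALSE)
  list(edges = edges, truth = list(modules = module_genes))
}

#' Simulate a complete reciprocal-FMT study
#'
#' Runs [simulate_asv_table()], [simulate_gene_counts()] (with gene-taxon
#' correlations planted against the realized ASV table) and
#' [simulate_interaction_edges()] (modules planted among the
#' opposite-direction genes) and merges the ground-truth manifests.
#'
#' @param cfg `fmt_sim_config`.
#' @return list with `asv`, `genes`, `edges` and a merged `truth` manifest.
#' @export
simulate_study <- function(cfg) {
  asv <- simulate_asv_table(cfg)
  genes <- simulate_gene_counts(cfg, asv)
  universe <- unique(c(genes$truth$opposite_gene_ids,
                       genes$truth$same_sign_gene_ids))
  net <- simulate_interaction_edges(cfg, universe,
    module_genes = {
      ids <- genes$truth$opposite_gene_ids
      n_mod <- min(3L, length(ids) %/% 6L)
      lapply(seq_len(n_mod), function(m) ids[seq((m - 1) * 6 + 1, m * 6)])
    })
  truth <- c(asv$truth, genes$truth, net$truth)
  list(asv = asv, genes = genes, edges = net$edges, truth = truth, config = cfg)
}

#' Write a simulated study to disk
#'
#' Emits `asv_counts.tsv`, `gene_counts.tsv`, `taxonomy.tsv`, `metadata.tsv`,
#' `edges.tsv` and `truth.json` under `dir`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$asv$counts, file.path(dir, "asv_counts.tsv"), "ASV")
  write_count_table(sim$genes$counts, file.path(dir, "gene_counts.tsv"), "gene")
  write.table(sim$asv$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$asv$meta, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$edges, file.path(dir, "edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$expected_group_composition <-
    as.data.frame(truth$expected_group_composition)
  truth$latent_mu_planted <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
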