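# Shared fixtures, built in code. The default-size study simulation is
# expensive enough to be worth caching across test files within one run.

tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                1L, 3L, 0L,
                10L, 10L, 10L), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2", "s3")))
  validate_count_table(m)
}

tiny_taxonomy <- function(ids = c("t1", "t2", "t3"),
                          genus = c("Akkermansia", "Akkermansia", "Bacteroides")) {
  data.frame(feature_id = ids, Kingdom = "Bacteria", Phylum = "P",
             Class = "C", Order = "O", Family = "F", Genus = genus,
             stringsAsFactors = FALSE)
}

# small weighted graph from an upper-triangular weight specification
graph_from_weights <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = rownames(w)[idx[, 1]], to = rownames(w)[idx[, 2]],
               weight = w[idx]),
    directed = FALSE, vertices = data.frame(name = rownames(w)))
}

# brute-force maximum cohesiveness over all non-empty vertex subsets
# (optionally restricted to subsets of at most max_size vertices)
brute_force_max_cohesiveness <- function(w, penalty, max_size = nrow(w)) {
  n <- nrow(w); best <- 0
  deg <- colSums(w)
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > max_size) next
    win <- sum(w[idx, idx]) / 2
    wb <- sum(deg[idx]) - sum(w[idx, idx])
    den <- win + wb + penalty * length(idx)
    f <- if (den == 0) 0 else win / den
    if (f > best) best <- f
  }
  best
}

local_study <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressMessages(suppressWarnings(
        simulate_study(simulation_config(seed = seed))))
    cache[[key]]
  }
})

# DE results for the cached study, cached alongside it
local_study_de <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 11) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      sim <- local_study(seed)
      meta <- sim$genes$meta
      sf <- size_factors(sim$genes$counts)
      disp <- estimate_dispersion(sim$genes$counts, sf, meta$group)
      cache[[key]] <- list(
        sf = sf, disp = disp,
        KO = nb_wald_test(sim$genes$counts, meta$group, c("KO", "KOFMT"), sf, disp),
        WT = nb_wald_test(sim$genes$counts, meta$group, c("WT", "WTFMT"), sf, disp),
        xKO = nb_wald_test(sim$genes$counts, meta$group, c("WT", "KOFMT"), sf, disp),
        xWT = nb_wald_test(sim$genes$counts, meta$group, c("KO", "WTFMT"), sf, disp))
    }
    cache[[key]]
  }
})
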