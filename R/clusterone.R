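#' Cohesiveness of a vertex set
#'
#' \deqn{f(V) = \frac{W_{in}(V)}{W_{in}(V) + W_{bound}(V) + p\,|V|}}
#' where `W_in` is the total weight of edges inside `V`, `W_bound` the total
#' weight of edges crossing its boundary, and `p` the per-vertex penalty that
#' models unobserved interactions.
#'
#' @param graph weighted undirected igraph.
#' @param members vertex names (or indices) of the set.
#' @param penalty per-vertex penalty `p`.
#' @return cohesiveness in \[0, 1\].
#' @export
cohesiveness <- function(graph, members, penalty = 2.0) {
  w <- weight_matrix(graph)
  idx <- if (is.character(members)) match(members, rownames(w)) else members
  if (anyNA(idx)) fmt_stop("cohesiveness: unknown vertex in members")
  win <- sum(w[idx, idx]) / 2
  wbound <- sum(w[idx, -idx, drop = FALSE])
  denom <- win + wbound + penalty * length(idx)
  if (denom == 0) return(0)
  win / denom
}

weight_matrix <- function(graph) {
  w <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  diag(w) <- 0
  w
}

# Greedy local search from a seed vertex set: best-improvement grow/shrink on
# the cohesiveness objective until no single-vertex move helps.
grow_cluster <- function(w, w_deg, seed, penalty) {
  n <- nrow(w)
  in_set <- rep(FALSE, n)
  in_set[seed] <- TRUE
  in_w <- rowSums(w[, seed, drop = FALSE])  # each vertex's weight into the set
  win <- sum(w[seed, seed]) / 2
  wbound <- sum(w_deg[seed]) - sum(w[seed, seed])
  f <- function(win, wbound, size)
    if (win + wbound + penalty * size == 0) 0
    else win / (win + wbound + penalty * size)
  size <- length(seed)
  f_cur <- f(win, wbound, size)
  repeat {
    cand_add <- which(!in_set & in_w > 0)
    cand_rem <- if (size > 1) which(in_set) else integer(0)
    best_gain <- 1e-12; best_v <- 0L; best_op <- ""
    if (length(cand_add)) {
      win_a <- win + in_w[cand_add]
      wb_a <- wbound - in_w[cand_add] + (w_deg[cand_add] - in_w[cand_add])
      f_a <- f_vec(win_a, wb_a, size + 1, penalty)
      i <- which.max(f_a)
      if (f_a[i] - f_cur > best_gain) {
        best_gain <- f_a[i] - f_cur; best_v <- cand_add[i]; best_op <- "add"
      }
    }
    if (length(cand_rem)) {
      win_r <- win - in_w[cand_rem]
      wb_r <- wbound + in_w[cand_rem] - (w_deg[cand_rem] - in_w[cand_rem])
      f_r <- f_vec(win_r, wb_r, size - 1, penalty)
      i <- which.max(f_r)
      if (f_r[i] - f_cur > best_gain) {
        best_gain <- f_r[i] - f_cur; best_v <- cand_rem[i]; best_op <- "remove"
      }
    }
    if (best_op == "") {
      # single moves exhausted: look for an improving swap (add u, drop v),
      # which escapes local optima a one-vertex move cannot leave
      sw <- best_swap(w, w_deg, in_set, in_w, win, wbound, size, penalty, f_cur)
      if (is.null(sw)) break
      u <- sw[1]; v <- sw[2]
      in_set[u] <- TRUE
      win <- win + in_w[u]
      wbound <- wbound - in_w[u] + (w_deg[u] - in_w[u])
      in_w <- in_w + w[, u]
      in_set[v] <- FALSE
      win <- win - in_w[v]
      wbound <- wbound + in_w[v] - (w_deg[v] - in_w[v])
      in_w <- in_w - w[, v]
      f_cur <- f(win, wbound, size)
      next
    }
    if (best_op == "add") {
      in_set[best_v] <- TRUE
      win <- win + in_w[best_v]
      wbound <- wbound - in_w[best_v] + (w_deg[best_v] - in_w[best_v])
      in_w <- in_w + w[, best_v]
      size <- size + 1L
    } else {
      in_set[best_v] <- FALSE
      win <- win - in_w[best_v]
      wbound <- wbound + in_w[best_v] - (w_deg[best_v] - in_w[best_v])
      in_w <- in_w - w[, best_v]
      size <- size - 1L
    }
    f_cur <- f(win, wbound, size)
  }
  list(members = which(in_set), f = f_cur)
}

# Best strictly improving (add u, remove v) pair, or NULL. O(|cand| * |S|)
# with O(1) incremental evaluation per pair.
best_swap <- function(w, w_deg, in_set, in_w, win, wbound, size, penalty, f_cur) {
  cand_u <- which(!in_set & in_w > 0)
  members <- which(in_set)
  if (!length(cand_u) || length(members) < 2) return(NULL)
  best <- f_cur + 1e-12; best_pair <- NULL
  for (u in cand_u) {
    win_a <- win + in_w[u]
    wb_a <- wbound - in_w[u] + (w_deg[u] - in_w[u])
    iw_v <- in_w[members] + w[members, u]
    win_2 <- win_a - iw_v
    wb_2 <- wb_a + iw_v - (w_deg[members] - iw_v)
    f2 <- f_vec(win_2, wb_2, size, penalty)
    i <- which.max(f2)
    if (f2[i] > best) { best <- f2[i]; best_pair <- c(u, members[i]) }
  }
  best_pair
}

f_vec <- function(win, wbound, size, penalty) {
  denom <- win + wbound + penalty * size
  ifelse(denom == 0, 0, win / denom)
}

#' Cohesiveness-based overlapping cluster detection
#'
#' Greedy seeded growth in the style of the ClusterONE algorithm: every vertex
#' seeds a local search that adds or removes single vertices while the
#' cohesiveness objective increases; duplicate local optima are collapsed;
#' candidate clusters whose match coefficient `|A.B|^2 / (|A||B|)` reaches the
#' merge threshold are merged; clusters below the minimum size are dropped.
#' Each cluster's p-value is a one-sided Mann-Whitney test comparing its
#' members' in-cluster versus boundary edge weights.
#'
#' @param graph weighted undirected igraph (e.g. from [build_network()]).
#' @param cfg `fmt_sig_config` (penalty, minimum size, merge threshold,
#'   significance gate).
#' @return data.frame: `cluster_id`, `members` (comma-joined gene ids),
#'   `size`, `cohesiveness`, `p`, `significant`; ordered by decreasing
#'   cohesiveness.
#' @export
clusterone_clusters <- function(graph, cfg = signature_config()) {
  if (igraph::vcount(graph) == 0)
    return(data.frame(cluster_id = integer(0), members = character(0),
                      size = integer(0), cohesiveness = numeric(0),
                      p = numeric(0), significant = logical(0)))
  w <- weight_matrix(graph)
  w_deg <- colSums(w)
  penalty <- cfg$cohesiveness_penalty

  # seeds: every vertex (decreasing degree) plus every edge's endpoint pair;
  # the extra pair seeds make the local search much harder to trap
  vert_seeds <- as.list(order(w_deg, decreasing = TRUE))
  ep <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edge_seeds <- lapply(seq_len(nrow(ep)), function(k) as.integer(ep[k, ]))
  found <- list()
  keys <- character(0)
  for (s in c(vert_seeds, edge_seeds)) {
    cl <- grow_cluster(w, w_deg, s, penalty)
    key <- paste(cl$members, collapse = ",")
    if (!key %in% keys) {
      keys <- c(keys, key)
      found[[length(found) + 1]] <- cl$members
    }
  }

  # agglomerative re-seeding: local optima can stop short of a larger optimum
  # whose assembly requires a temporary dip in the objective, so rerun the
  # search from unions of connected candidate pairs. Bounded (3 rounds, pair
  # budget per round) to stay near-linear on large networks while exhausting
  # small ones.
  coh_of <- function(idx)
    f_vec(sum(w[idx, idx]) / 2, sum(w_deg[idx]) - sum(w[idx, idx]),
          length(idx), penalty)
  for (round in 1:3) {
    nf <- length(found)
    if (nf < 2) break
    ord <- order(vapply(found, coh_of, numeric(1)), decreasing = TRUE)
    top <- ord[seq_len(min(nf, 25L))]
    new_any <- FALSE
    for (i in top) for (j in top) {
      if (j <= i) next
      a <- found[[i]]; b <- found[[j]]
      if (sum(w[a, b]) == 0) next
      cl <- grow_cluster(w, w_deg, sort(union(a, b)), penalty)
      key <- paste(cl$members, collapse = ",")
      if (!key %in% keys && length(found) < 400L) {
        keys <- c(keys, key)
        found[[length(found) + 1]] <- cl$members
        new_any <- TRUE
      }
    }
    if (!new_any) break
  }

  # iterative merging of strongly overlapping candidates (match coefficient);
  # the merge keeps whichever of {regrown union, either member} scores best,
  # so merging can only deduplicate, never degrade the objective
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(found)) {
      j <- i + 1
      while (j <= length(found)) {
        a <- found[[i]]; b <- found[[j]]
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov >= cfg$merge_overlap) {
          grown <- grow_cluster(w, w_deg, sort(union(a, b)), penalty)$members
          cands <- list(grown, a, b)
          found[[i]] <- cands[[which.max(vapply(cands, coh_of, numeric(1)))]]
          found[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  found <- unique(found)
  found <- found[vapply(found, length, integer(1)) >= cfg$min_cluster_size]
  if (!length(found))
    return(data.frame(cluster_id = integer(0), members = character(0),
                      size = integer(0), cohesiveness = numeric(0),
                      p = numeric(0), significant = logical(0)))

  res <- do.call(rbind, lapply(found, function(idx) {
    in_w <- colSums(w[idx, , drop = FALSE])
    inside <- in_w[idx]
    boundary <- w_deg[idx] - in_w[idx]
    p <- tryCatch(
      suppressWarnings(wilcox.test(inside, boundary,
                                   alternative = "greater")$p.value),
      error = function(e) NA_real_)
    data.frame(members = paste(rownames(w)[idx], collapse = ","),
               size = length(idx),
               cohesiveness = f_vec(sum(w[idx, idx]) / 2,
                                    sum(w_deg[idx]) - sum(w[idx, idx]),
                                    length(idx), penalty),
               p = p, stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$cohesiveness), , drop = FALSE]
  res$cluster_id <- seq_len(nrow(res))
  res$significant <- !is.na(res$p) & res$p < cfg$cluster_p_threshold
  rownames(res) <- NULL
  res[, c("cluster_id", "members", "size", "cohesiveness", "p", "significant")]
}
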