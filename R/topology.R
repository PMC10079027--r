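#' Global efficiency
#'
#' Integration measure: the average over all ordered node pairs of the
#' inverse geodesic distance, `E_glob = 1/(N(N-1)) * sum_{i!=j} 1/s_ij`,
#' with distances the reciprocal-weight Dijkstra geodesics. Unreachable
#' pairs contribute 0.
#'
#' @param cm a [connectivity_matrix] with at least 2 nodes.
#' @param rel_tol tie tolerance passed to [shortest_paths()].
#' @return A single non-negative number.
#' @export
global_efficiency <- function(cm, rel_tol = 1e-9) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- nrow(cm$weights)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  d <- shortest_paths(cm, rel_tol)$dist
  off <- d[row(d) != col(d)]
  eff <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  sum(eff) / (n * (n - 1))
}

#' Modularity of a partition
#'
#' Newman-style weighted modularity,
#' `Q = 1/(2m) * sum_ij [a_ij - d_i d_j/(2m)] delta(c_i, c_j)` with
#' `m = 1/2 sum_ij a_ij`: the within-community weight excess over a
#' degree-preserving random null. The single-community partition scores
#' exactly 0.
#'
#' @param cm a [connectivity_matrix] with positive total weight.
#' @param membership integer/character vector assigning each node a
#'   community.
#' @return A single number in `[-1, 1]`.
#' @export
modularity_score <- function(cm, membership) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  n <- nrow(w)
  if (length(membership) != n) stop("membership must cover all nodes")
  two_m <- sum(w)
  if (two_m <= 0) stop("modularity undefined for an empty graph")
  d <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(d, d) / two_m) * same) / two_m
}

#' Louvain modularity maximization
#'
#' Greedy multilevel heuristic (local moves followed by community
#' aggregation, resolution 1) for the partition maximizing modularity.
#' The node visiting order is shuffled per restart under a seeded stream and
#' the best partition over `n_restarts` restarts is kept; the
#' single-community partition (Q = 0) is always a candidate, so the returned
#' modularity is never negative. The returned `q` is recomputed from the
#' original matrix with [modularity_score()].
#'
#' @param cm a [connectivity_matrix] with positive total weight.
#' @param seed integer seed for the restart shuffles.
#' @param n_restarts number of seeded restarts (default 10).
#' @return List with `membership` (integer communities, contiguous from 0),
#'   `n_communities`, and `q`.
#' @export
louvain_partition <- function(cm, seed = 1L, n_restarts = 10L) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  if (sum(w) <= 0) stop("modularity maximization needs positive total weight")
  best_mem <- rep(0L, nrow(w))
  best_q <- 0   # single-community fallback
  for (r in seq_len(n_restarts)) {
    mem <- with_seed(derive_seed(seed, r), louvain_once(w))
    q <- modularity_score(cm, mem)
    if (q > best_q + 1e-15) {
      best_q <- q
      best_mem <- mem
    }
  }
  mem <- as.integer(factor(best_mem, levels = unique(best_mem))) - 1L
  list(membership = stats::setNames(mem, cm$node_names),
       n_communities = length(unique(mem)),
       q = modularity_score(cm, mem))
}

# one full multilevel Louvain run on the double-sum adjacency matrix
# (A[k,k] carries the aggregated internal mass, so rowSums are degrees)
louvain_once <- function(a) {
  n0 <- nrow(a)
  node_comm <- seq_len(n0)   # community of each original node
  two_m <- sum(a)
  repeat {
    n <- nrow(a)
    mem <- seq_len(n)
    sigma_tot <- rowSums(a)
    k <- sigma_tot
    improved_level <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        ci <- mem[i]
        wi <- a[i, ]
        wi[i] <- 0
        links <- rowsum(wi, mem)                 # weight from i to each community
        comms <- as.integer(rownames(links))
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        gains <- links[, 1] - k[i] * sigma_tot[comms] / two_m
        best <- which.max(gains)
        target <- comms[best]
        cur <- which(comms == ci)
        if (length(cur) == 0 || gains[best] > gains[cur] + 1e-12) {
          mem[i] <- target
          sigma_tot[target] <- sigma_tot[target] + k[i]
          if (target != ci) moved <- TRUE
        } else {
          sigma_tot[ci] <- sigma_tot[ci] + k[i]
        }
      }
      if (!moved) break
      improved_level <- TRUE
    }
    if (!improved_level) break
    # aggregate communities into super-nodes
    fac <- factor(mem, levels = sort(unique(mem)))
    node_comm <- as.integer(fac)[node_comm]
    memb <- t(sapply(levels(fac), function(l) as.numeric(fac == l)))
    a <- memb %*% a %*% t(memb)
    if (nrow(a) == length(levels(fac)) && nrow(a) == n) break
  }
  node_comm
}

#' Local reaching centrality
#'
#' For each node, the average — over all nodes reachable from it — of the
#' mean edge weight along the selected geodesic, divided by `N - 1`:
#' a weighted generalization of the fraction of the network a node can
#' reach. Geodesics use the reciprocal-weight distance; ties are broken by
#' fewest links, then by lexicographically earliest node sequence, so the
#' selected path is deterministic. Each undirected edge is treated as two
#' directed links. Unreachable targets contribute 0.
#'
#' @param cm a [connectivity_matrix].
#' @param node node index (1-based position) or node name; `NULL` computes
#'   all nodes.
#' @param rel_tol geodesic tie tolerance.
#' @return Named numeric vector of local reaching centralities (or a single
#'   value if `node` is given).
#' @export
local_reaching_centrality <- function(cm, node = NULL, rel_tol = 1e-9) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  n <- nrow(w)
  one <- function(i) {
    rp <- reaching_paths(w, i, rel_tol)
    reach <- which(!is.na(rp$nlinks))
    if (length(reach) == 0) return(0)
    sum(rp$wsum[reach] / rp$nlinks[reach]) / (n - 1)
  }
  if (!is.null(node)) {
    if (is.character(node)) node <- match(node, cm$node_names)
    return(one(node))
  }
  stats::setNames(vapply(seq_len(n), one, numeric(1)), cm$node_names)
}

#' Global reaching centrality
#'
#' Hierarchy measure: the mean gap between the maximal local reaching
#' centrality and each node's own,
#' `GRC = sum_i [C_R^max - C_R(i)] / (N - 1)`. A perfectly homogeneous
#' network (all `C_R` equal) scores 0; a star-like hierarchy scores high.
#'
#' @param cm a [connectivity_matrix] with at least 2 nodes.
#' @param rel_tol geodesic tie tolerance.
#' @return A single number (in `[0, 1]` when weights are at most 1).
#' @export
global_reaching_centrality <- function(cm, rel_tol = 1e-9) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  n <- nrow(cm$weights)
  if (n < 2L) stop("global reaching centrality needs at least 2 nodes")
  cr <- local_reaching_centrality(cm, rel_tol = rel_tol)
  sum(max(cr) - cr) / (n - 1)
}

#' Integration / segregation / hierarchy summary across connectome variants
#'
#' For every matrix of every connectome variant, computes global efficiency
#' (integration), the maximized "ultimate" modularity (segregation), and
#' global reaching centrality (hierarchy), plus per-variant centroids of the
#' three metrics — the centres of mass used to compare variants in a
#' scatter-plot reading.
#'
#' @param variants named list: variant tag -> list of
#'   [connectivity_matrix] objects (e.g. one per subject).
#' @param seed,n_restarts passed to [louvain_partition()].
#' @param rel_tol geodesic tie tolerance.
#' @return List with `per_matrix` (data.frame: variant, subject, e_glob,
#'   q_ultimate, n_communities, grc) and `centroids` (per-variant means).
#' @export
integration_segregation_summary <- function(variants, seed = 1L,
                                            n_restarts = 10L,
                                            rel_tol = 1e-9) {
  stopifnot(is.list(variants), length(variants) >= 1,
            !is.null(names(variants)))
  rows <- list()
  for (vn in names(variants)) {
    mats <- variants[[vn]]
    if (inherits(mats, "connectivity_matrix")) mats <- list(mats)
    stopifnot(length(mats) >= 1)
    for (s in seq_along(mats)) {
      cm <- mats[[s]]
      lp <- louvain_partition(cm, seed = derive_seed(seed, match(vn, names(variants)), s),
                              n_restarts = n_restarts)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, subject = s,
        e_glob = global_efficiency(cm, rel_tol),
        q_ultimate = lp$q,
        n_communities = lp$n_communities,
        grc = global_reaching_centrality(cm, rel_tol),
        stringsAsFactors = FALSE
      )
    }
  }
  per_matrix <- do.call(rbind, rows)
  centroids <- do.call(rbind, lapply(split(per_matrix, per_matrix$variant),
                                     function(g) data.frame(
    variant = g$variant[1], n = nrow(g),
    e_glob = mean(g$e_glob), q_ultimate = mean(g$q_ultimate),
    grc = mean(g$grc), stringsAsFactors = FALSE
  )))
  rownames(centroids) <- NULL
  list(per_matrix = per_matrix, centroids = centroids)
}
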