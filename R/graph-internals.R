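# Dense weighted-graph kernels. Edge "length" is the reciprocal of the weight
# (strong connections are short); a zero weight is an absent edge. Graphs here
# never exceed a few hundred nodes, so dense O(N^2)-per-source Dijkstra is the
# right tool.

# reciprocal length matrix; Inf where no edge
length_matrix <- function(w) {
  L <- 1 / w
  L[w <= 0] <- Inf
  diag(L) <- Inf
  L
}

# Single-source Dijkstra with counting of shortest paths tied within a
# relative tolerance. Returns dist, sigma, predecessor lists, and the order
# nodes were settled (for Brandes-style accumulation).
dijkstra_source <- function(L, s, rel_tol = 1e-9, predecessors = FALSE) {
  n <- nrow(L)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  done <- rep(FALSE, n)
  order_settled <- integer(0)
  preds <- if (predecessors) vector("list", n) else NULL
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_settled <- c(order_settled, u)
    nd <- dist[u] + L[u, ]
    reach <- !done & is.finite(nd)
    # tolerance relative to the shorter of the two competing path lengths
    tolv <- rel_tol * pmax(pmin(dist, nd), 1e-300)
    improve <- reach & (nd < dist - tolv)
    tie <- reach & !improve & is.finite(dist) & (abs(nd - dist) <= tolv)
    if (any(improve)) {
      dist[improve] <- nd[improve]
      sigma[improve] <- sigma[u]
      if (predecessors) preds[which(improve)] <- list(u)
    }
    if (any(tie)) {
      sigma[tie] <- sigma[tie] + sigma[u]
      if (predecessors) {
        for (v in which(tie)) preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_settled)
}

# connected components over nonzero weights (undirected)
graph_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- which(w[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Geodesic selection for reaching centrality: inverse-weight distance, ties
# broken by fewest links then lexicographically earliest node sequence.
# Returns, per target, the number of links and the summed weight along the
# selected path from s (NA when unreachable).
reaching_paths <- function(w, s, rel_tol = 1e-9) {
  n <- nrow(w)
  L <- length_matrix(w)
  dd <- dijkstra_source(L, s, rel_tol)
  dist <- dd$dist
  nlinks <- rep(NA_integer_, n)
  wsum <- rep(NA_real_, n)
  pathkey <- rep(NA_character_, n)   # lexicographic node sequence key
  nlinks[s] <- 0L
  wsum[s] <- 0
  pathkey[s] <- ""
  ord <- order(dist)
  ord <- ord[is.finite(dist[ord]) & ord != s]
  for (v in ord) {
    cand <- which(w[, v] > 0 & !is.na(nlinks))
    if (length(cand) == 0) next
    tol <- rel_tol * max(dist[v], 1e-300)
    cand <- cand[abs(dist[cand] + L[cand, v] - dist[v]) <= tol]
    if (length(cand) == 0) next
    nl <- nlinks[cand] + 1L
    cand <- cand[nl == min(nl)]
    if (length(cand) > 1) {
      keys <- paste0(pathkey[cand], sprintf("%06d", cand))
      cand <- cand[order(keys)][1]
    }
    u <- cand[1]
    nlinks[v] <- nlinks[u] + 1L
    wsum[v] <- wsum[u] + w[u, v]
    pathkey[v] <- paste0(pathkey[u], sprintf("%06d", u))
  }
  nlinks[s] <- NA_integer_
  wsum[s] <- NA_real_
  list(nlinks = nlinks, wsum = wsum)
}
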