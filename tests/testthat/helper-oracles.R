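# Independent brute-force oracles, deliberately naive: dense matrix algebra,
# exhaustive path enumeration, and full partition enumeration. They share no
# code with the package's graph kernels.

# random symmetric weighted graph as a connectivity_matrix
rand_cm <- function(n, density = 0.7, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    npair <- n * (n - 1) / 2
    on_edge <- stats::runif(npair) < density
    vals <- stats::rexp(npair) + 0.05
    w[upper.tri(w)] <- ifelse(on_edge, vals, 0)
    w <- w + t(w)
    connectivity_matrix(w, seq_len(n))
  })
}

rand_connected_cm <- function(n, density = 0.7, seed = 1) {
  for (k in 0:200) {
    cm <- rand_cm(n, density, seed + 1000L * k)
    d <- oracle_floyd_warshall(cm$weights)
    if (all(is.finite(d))) return(cm)
  }
  stop("could not generate a connected graph")
}

# all-pairs geodesic distances under reciprocal-weight lengths
oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- 1 / w
  d[w <= 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# exhaustive enumeration of simple paths between every pair: returns, for
# each (j,k), the geodesic distance, the count of tied shortest paths, and
# per-node through-counts
oracle_path_enumeration <- function(w, rel_tol = 1e-9) {
  n <- nrow(w)
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  through <- array(0, c(n, n, n))   # [j, k, i]
  for (j in seq_len(n - 1)) {
    for (k in seq((j + 1), n)) {
      paths <- list()
      lens <- numeric(0)
      walk <- function(v, visited, len) {
        if (v == k) {
          paths[[length(paths) + 1L]] <<- visited
          lens[length(lens) + 1L] <<- len
          return(invisible())
        }
        for (u in which(w[v, ] > 0)) {
          if (!(u %in% visited)) walk(u, c(visited, u), len + 1 / w[v, u])
        }
      }
      walk(j, j, 0)
      if (length(lens) == 0) next
      best <- min(lens)
      tied <- which(lens <= best * (1 + rel_tol))
      dist[j, k] <- dist[k, j] <- best
      sigma[j, k] <- sigma[k, j] <- length(tied)
      for (t in tied) {
        mid <- setdiff(paths[[t]], c(j, k))
        through[j, k, mid] <- through[j, k, mid] + 1
        through[k, j, mid] <- through[k, j, mid] + 1
      }
    }
  }
  list(dist = dist, sigma = sigma, through = through)
}

# Eq-4 betweenness from the enumeration oracle (unordered pairs)
oracle_betweenness <- function(w, rel_tol = 1e-9) {
  n <- nrow(w)
  pe <- oracle_path_enumeration(w, rel_tol)
  b <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n - 1)) {
      for (k in seq((j + 1), n)) {
        if (j == i || k == i || pe$sigma[j, k] == 0) next
        acc <- acc + pe$through[j, k, i] / pe$sigma[j, k]
      }
    }
    b[i] <- 2 * acc / ((n - 1) * (n - 2))
  }
  b
}

# principal eigenvector by dense symmetric eigendecomposition, max = 1
oracle_eigenvector <- function(w) {
  e <- eigen(w, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v / max(v)
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(pref, maxc) {
    if (length(pref) == n) {
      out[[length(out) + 1L]] <<- pref
      return(invisible())
    }
    for (c in seq_len(maxc + 1L)) rec(c(pref, c), max(maxc, c))
  }
  rec(1L, 1L)
  out
}

# exhaustive maximum modularity
oracle_max_modularity <- function(cm) {
  parts <- all_partitions(nrow(cm$weights))
  qs <- vapply(parts, function(p) modularity_score(cm, p), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# two disconnected unit-weight cliques of size k
two_cliques_cm <- function(k) {
  n <- 2L * k
  w <- matrix(0, n, n)
  w[seq_len(k), seq_len(k)] <- 1
  w[(k + 1):n, (k + 1):n] <- 1
  diag(w) <- 0
  connectivity_matrix(w, seq_len(n))
}
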