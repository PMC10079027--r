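#' Degree centrality (node strength)
#'
#' The sum of all connection weights attached to each node,
#' `d_i = sum_j a_ij`; for a streamline-count connectome this is the total
#' number of streamlines associated with the region.
#'
#' @param cm a [connectivity_matrix].
#' @return Object of class `centrality_vector`: named numeric `values`,
#'   `measure`, `node_labels`.
#' @export
degree_centrality <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  centrality_vector(rowSums(cm$weights), "degree", cm)
}

centrality_vector <- function(values, measure, cm) {
  structure(list(values = stats::setNames(as.numeric(values), cm$node_names),
                 measure = measure, node_labels = cm$node_labels),
            class = "centrality_vector")
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("CentralityVector [%s], %d nodes; top: %s\n", x$measure,
              length(x$values),
              names(x$values)[which.max(x$values)]))
  invisible(x)
}

#' Eigenvector centrality
#'
#' Components of the eigenvector belonging to the largest eigenvalue of the
#' connectivity matrix, computed by power iteration. For a connected
#' non-negative matrix the Perron-Frobenius theorem guarantees a unique
#' positive vector; it is rescaled so its maximum component is 1 (the overall
#' factor plays no role when comparing nodes within one network). On a
#' disconnected matrix the vector is computed on the largest connected
#' component, with zeros elsewhere and a warning.
#'
#' @param cm a [connectivity_matrix].
#' @param tol convergence tolerance on the max-norm change per iteration.
#' @param max_iter iteration cap; exceeded means non-convergence (an error).
#' @return A `centrality_vector` with measure `"eigenvector"`.
#' @export
eigenvector_centrality <- function(cm, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  n <- nrow(w)
  comp <- graph_components(w)
  sizes <- tabulate(comp)
  main <- which.max(sizes)
  values <- numeric(n)
  if (length(unique(comp)) > 1L) {
    warning("matrix is disconnected; eigenvector centrality computed on the ",
            "largest connected component (", sizes[main], " of ", n,
            " nodes), zeros elsewhere")
  }
  sel <- comp == main
  if (sizes[main] >= 2L) {
    a <- w[sel, sel, drop = FALSE]
    # shift by the max strength: keeps the Perron vector, but makes the
    # dominant eigenvalue strictly largest in magnitude (bipartite graphs
    # otherwise make plain power iteration oscillate between +/- lambda)
    a <- a + diag(max(rowSums(a)), nrow(a))
    x <- rep(1, nrow(a))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.vector(a %*% x)
      nx <- max(x_new)
      if (nx <= 0) stop("power iteration collapsed (zero matrix block)")
      x_new <- x_new / nx
      if (max(abs(x_new - x)) <= tol) {
        x <- x_new
        converged <- TRUE
        break
      }
      x <- x_new
    }
    if (!converged) stop("eigenvector centrality did not converge in ",
                         max_iter, " iterations")
    values[sel] <- x / max(x)
  } else {
    # a single isolated node has no meaningful eigenvector score
    values[sel] <- 0
  }
  centrality_vector(values, "eigenvector", cm)
}

#' Weighted shortest paths with tied-path counts
#'
#' Geodesics under the reciprocal-weight distance (the distance of an edge is
#' `1/a_ij`; strong connections are short), computed by Dijkstra's algorithm
#' from every source. Paths whose lengths agree within a relative tolerance
#' are counted as tied shortest paths.
#'
#' @param cm a [connectivity_matrix].
#' @param rel_tol relative tolerance for tied path lengths.
#' @return List with `dist` (NxN geodesic distances, `Inf` for unreachable
#'   pairs, zero diagonal) and `sigma` (NxN counts of tied shortest paths,
#'   0 for unreachable pairs; diagonal 1 by convention).
#' @export
shortest_paths <- function(cm, rel_tol = 1e-9) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  n <- nrow(w)
  L <- length_matrix(w)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dd <- dijkstra_source(L, s, rel_tol)
    dist[s, ] <- dd$dist
    sigma[s, ] <- dd$sigma
  }
  dimnames(dist) <- dimnames(sigma) <- dimnames(w)
  list(dist = dist, sigma = sigma)
}

#' Betweenness centrality
#'
#' The normalized share of weighted shortest paths between all other node
#' pairs that pass through each node:
#' `b_i = 2/((N-1)(N-2)) * sum_{j<k, j,k != i} sigma_jk(i)/sigma_jk`,
#' with geodesics under the reciprocal-weight distance and path endpoints
#' excluded. The star centre of an otherwise unconnected star scores exactly
#' 1; values always lie in `[0, 1]`. Unreachable pairs contribute 0.
#'
#' @param cm a [connectivity_matrix] with at least 3 nodes.
#' @param rel_tol relative tolerance for tied geodesics.
#' @return A `centrality_vector` with measure `"betweenness"`.
#' @export
betweenness_centrality <- function(cm, rel_tol = 1e-9) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  w <- cm$weights
  n <- nrow(w)
  if (n < 3L) stop("betweenness centrality needs at least 3 nodes")
  L <- length_matrix(w)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dd <- dijkstra_source(L, s, rel_tol, predecessors = TRUE)
    delta <- numeric(n)
    for (v in rev(dd$order)) {
      for (u in dd$preds[[v]]) {
        delta[u] <- delta[u] + dd$sigma[u] / dd$sigma[v] * (1 + delta[v])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  # bc accumulates over ordered (source, target) pairs = twice the unordered
  # sum, so the printed prefactor 2/((N-1)(N-2)) becomes 1/((N-1)(N-2))
  centrality_vector(bc / ((n - 1) * (n - 2)), "betweenness", cm)
}

#' Centrality of each subject's connectome
#'
#' Applies one measure independently to every subject-level (run-averaged)
#' matrix; inter-subject spread of the results is what the ranking table's
#' SD column summarizes.
#'
#' @param matrices list of per-subject [connectivity_matrix] objects sharing
#'   a node set.
#' @param measure `"degree"`, `"eigenvector"`, or `"betweenness"`.
#' @param ... passed to the measure function.
#' @return List of `centrality_vector`s, one per subject.
#' @export
per_subject_centralities <- function(matrices,
                                     measure = c("degree", "eigenvector",
                                                 "betweenness"), ...) {
  measure <- match.arg(measure)
  stop_if_mismatched(matrices)
  fn <- switch(measure, degree = degree_centrality,
               eigenvector = eigenvector_centrality,
               betweenness = betweenness_centrality)
  lapply(seq_along(matrices), function(s) {
    tryCatch(fn(matrices[[s]], ...),
             error = function(e) stop("subject ", s, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
}

#' Cross-subject ranking table
#'
#' For each structure, the cross-subject mean and sample SD of a centrality
#' measure, the mean normalized by the maximum mean (so the top structure
#' scores exactly 1), and the descending-mean rank. Ties in the mean are
#' broken by structure name so output is deterministic.
#'
#' @param vectors list of `centrality_vector`s (one per subject, same
#'   measure and node set).
#' @param top optional: keep only the `top` highest-ranked rows.
#' @return data.frame of class `ranking_table`: columns `measure, name, mean,
#'   sd, normalized_mean, rank` (also `sd_normalized`, the SD on the same
#'   max-normalized scale as `normalized_mean`).
#' @export
rank_structures <- function(vectors, top = NULL) {
  stopifnot(length(vectors) >= 1)
  measure <- vectors[[1]]$measure
  vals <- do.call(rbind, lapply(vectors, function(v) v$values))
  mu <- colMeans(vals)
  sdv <- if (nrow(vals) >= 2) apply(vals, 2, stats::sd) else rep(NA_real_, ncol(vals))
  mx <- max(mu)
  if (mx <= 0) stop("all cross-subject means are zero; nothing to normalize")
  ord <- order(-mu, names(mu))
  out <- data.frame(
    measure = measure,
    name = names(mu)[ord],
    mean = unname(mu[ord]),
    sd = unname(sdv[ord]),
    normalized_mean = unname(mu[ord] / mx),
    sd_normalized = unname(sdv[ord] / mx),
    rank = seq_along(mu),
    stringsAsFactors = FALSE
  )
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}
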