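#' Planted-hub block-model connection probabilities
#'
#' Builds the ground-truth distribution over unordered region pairs from which
#' synthetic streamlines are drawn: within-community pairs get weight `w_in`,
#' between-community pairs `w_out`, and any pair touching a hub is boosted by
#' `hub_boost`; weights are then normalized so the total mass over unordered
#' pairs is 1. Every inter-community pair is additionally assigned a traversal
#' set containing one hub label, emulating cortico-cortical streamlines that
#' physically pass through deep structures — removing that hub from the white
#' matter mask severs those routes.
#'
#' @param parc a [parcellation] (its `community` and `is_hub` columns drive
#'   the block structure).
#' @param w_in,w_out within/between-community base weights (`w_in > w_out > 0`).
#' @param hub_boost multiplicative boost (>= 1) for pairs touching a hub.
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return Object of class `ground_truth`: list with `prob_matrix` (symmetric,
#'   zero diagonal, unordered-pair mass 1), `community_of`, `hub_ids`,
#'   `traversal_hub` (NxN integer matrix, 0 = no traversal hub), `parc`.
#' @export
make_ground_truth_matrix <- function(parc, w_in = 2, w_out = 1, hub_boost = 3,
                                     seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  n <- nrow(parc)
  if (n == 0L) stop("empty parcellation")
  if (!(w_in > w_out && w_out > 0)) stop("need w_in > w_out > 0")
  if (hub_boost < 1) stop("hub_boost must be >= 1")

  comm <- parc$community
  same <- outer(comm, comm, "==")
  w <- ifelse(same, w_in, w_out)
  hub <- parc$is_hub
  touches_hub <- outer(hub, hub, "|")
  w[touches_hub] <- w[touches_hub] * hub_boost
  diag(w) <- 0
  p <- w / (sum(w) / 2)   # sum over unordered pairs == 1

  trav <- matrix(0L, n, n)
  hubs <- parc$label_id[hub]
  if (length(hubs) > 0L) {
    inter <- !same
    trav[inter] <- hubs[1L]
  }
  diag(trav) <- 0L

  structure(list(
    prob_matrix = p,
    community_of = stats::setNames(comm, parc$label_id),
    hub_ids = hubs,
    traversal_hub = trav,
    parc = parc
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("GroundTruth: %d regions, %d hub(s), pair mass %.6f\n",
              nrow(x$prob_matrix), length(x$hub_ids), sum(x$prob_matrix) / 2))
  invisible(x)
}
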