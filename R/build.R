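#' Map world coordinates to parcellation labels
#'
#' Applies the inverse affine to get continuous 0-based voxel coordinates,
#' rounds half away from zero to the nearest voxel, and returns that voxel's
#' label; points falling outside the grid map to 0 (background).
#'
#' @param points numeric n x 3 matrix (or length-3 vector) of world-mm
#'   coordinates.
#' @param lv a [label_volume].
#' @return Integer vector of label ids (0 = background / out of bounds).
#' @export
assign_endpoint_label <- function(points, lv) {
  stopifnot(inherits(lv, "label_volume"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (any(!is.finite(points))) stop("coordinates must be finite")
  vox <- world_to_voxel(points, lv$affine)
  # round half away from zero (not R's round-half-even)
  idx <- sign(vox) * floor(abs(vox) + 0.5)
  d <- dim(lv$grid)
  ok <- idx[, 1] >= 0 & idx[, 1] < d[1] &
        idx[, 2] >= 0 & idx[, 2] < d[2] &
        idx[, 3] >= 0 & idx[, 3] < d[3]
  out <- integer(nrow(points))
  if (any(ok)) {
    out[ok] <- lv$grid[cbind(idx[ok, 1, drop = TRUE] + 1L,
                             idx[ok, 2, drop = TRUE] + 1L,
                             idx[ok, 3, drop = TRUE] + 1L)]
  }
  out
}

#' Build a connectivity matrix from endpoint records
#'
#' Labels both endpoints of every streamline against the label volume and
#' accumulates a symmetric count matrix over the requested node subset
#' (`a_ij` and `a_ji` both gain 1 per streamline — a bi-directional label
#' map). Records are discarded, with a tally by reason, when an endpoint is
#' background/out-of-bounds (`background`), when a label is outside the node
#' subset (`outside_subset`), or when both endpoints fall in the same region
#' (`self_pair`; the diagonal stays zero).
#'
#' @param es an [endpoint_set].
#' @param lv a [label_volume].
#' @param parc the [parcellation] supplying node order, names, volumes.
#' @param keep_labels node subset (default: all parcellation labels).
#' @return A [connectivity_matrix] of kind `"raw"` with a `discards` tally.
#' @export
build_matrix <- function(es, lv, parc, keep_labels = NULL) {
  stopifnot(inherits(es, "endpoint_set"), inherits(lv, "label_volume"),
            inherits(parc, "parcellation"))
  keep_labels <- as.integer(keep_labels %||% parc$label_id)
  if (length(keep_labels) == 0L) stop("keep_labels must be non-empty")
  if (!all(keep_labels %in% parc$label_id)) {
    stop("keep_labels must be a subset of the parcellation labels")
  }
  sel <- parc$label_id %in% keep_labels   # canonical order preserved
  labs <- parc$label_id[sel]
  nms <- parc$name[sel]
  n <- length(labs)

  r <- es$records
  m <- matrix(0, n, n)
  discards <- c(background = 0, outside_subset = 0, self_pair = 0)
  if (nrow(r) > 0) {
    l1 <- assign_endpoint_label(cbind(r$x1, r$y1, r$z1), lv)
    l2 <- assign_endpoint_label(cbind(r$x2, r$y2, r$z2), lv)
    bg <- l1 == 0L | l2 == 0L
    pos1 <- match(l1, labs)
    pos2 <- match(l2, labs)
    outside <- !bg & (is.na(pos1) | is.na(pos2))
    self <- !bg & !outside & pos1 == pos2
    keep <- !bg & !outside & !self
    discards <- c(background = sum(bg), outside_subset = sum(outside),
                  self_pair = sum(self))
    if (any(keep)) {
      tab <- table(factor(pmin(pos1[keep], pos2[keep]), levels = seq_len(n)),
                   factor(pmax(pos1[keep], pos2[keep]), levels = seq_len(n)))
      counts <- matrix(as.numeric(tab), n, n)
      m <- counts + t(counts)
    }
  }
  connectivity_matrix(m, labs, nms, kind = "raw", discards = discards)
}

#' Average connectivity matrices over runs
#'
#' Elementwise arithmetic mean of matrices sharing a node set; used to pool
#' the repeated probabilistic tractography runs of one subject.
#'
#' @param matrices list of [connectivity_matrix] with identical node labels.
#' @return A [connectivity_matrix] of kind `"run_mean"`.
#' @export
average_runs <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  stop_if_mismatched(matrices)
  w <- Reduce(`+`, lapply(matrices, function(m) m$weights)) / length(matrices)
  m1 <- matrices[[1]]
  connectivity_matrix(w, m1$node_labels, m1$node_names, kind = "run_mean")
}

#' Average connectivity matrices across subjects
#'
#' Elementwise mean and inter-subject sample standard deviation (divisor
#' n-1) of per-subject matrices; the mean is the "overarching" group
#' connectome and the SD captures variability between individuals.
#'
#' @param matrices list of per-subject [connectivity_matrix] objects with
#'   identical node labels.
#' @return List with `mean_matrix` (kind `"subject_mean"`), `sd_matrix`
#'   (numeric matrix, `NA` when only one subject), `n_subjects`.
#' @export
average_subjects <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  stop_if_mismatched(matrices)
  n <- length(matrices)
  ws <- lapply(matrices, function(m) m$weights)
  mean_w <- Reduce(`+`, ws) / n
  if (n >= 2) {
    ss <- Reduce(`+`, lapply(ws, function(w) (w - mean_w)^2))
    sd_w <- sqrt(ss / (n - 1))
  } else {
    sd_w <- matrix(NA_real_, nrow(mean_w), ncol(mean_w))
  }
  m1 <- matrices[[1]]
  list(mean_matrix = connectivity_matrix(mean_w, m1$node_labels,
                                         m1$node_names, kind = "subject_mean"),
       sd_matrix = sd_w, n_subjects = n)
}

#' Restrict a connectome to a subset of structures
#'
#' Three modes mirror the ways a smaller atlas can arise:
#' `"submatrix"` drops rows/columns of an existing matrix;
#' `"endpoint_filter"` rebuilds from endpoint records, discarding streamlines
#' whose endpoints touch removed structures; `"traversal_filter"`
#' additionally discards streamlines whose traversed-label set intersects the
#' removed structures, emulating re-tracking with an altered white-matter
#' mask (streamlines that physically pass through a removed structure are
#' never generated).
#'
#' @param x a [connectivity_matrix] (mode `"submatrix"`) or an
#'   [endpoint_set] (filter modes).
#' @param keep_labels non-empty subset of the current labels.
#' @param mode one of `"traversal_filter"`, `"endpoint_filter"`,
#'   `"submatrix"`.
#' @param lv,parc required for the filter modes (matrix rebuild).
#' @return A [connectivity_matrix] on the kept nodes.
#' @export
restrict_connectome <- function(x, keep_labels,
                                mode = c("traversal_filter",
                                         "endpoint_filter", "submatrix"),
                                lv = NULL, parc = NULL) {
  mode <- match.arg(mode)
  keep_labels <- as.integer(keep_labels)
  if (length(keep_labels) == 0L) stop("keep_labels must be non-empty")
  if (mode == "submatrix") {
    stopifnot(inherits(x, "connectivity_matrix"))
    if (!all(keep_labels %in% x$node_labels)) {
      stop("keep_labels must be a subset of the matrix labels")
    }
    sel <- x$node_labels %in% keep_labels
    connectivity_matrix(x$weights[sel, sel, drop = FALSE],
                        x$node_labels[sel], x$node_names[sel], kind = x$kind)
  } else {
    stopifnot(inherits(x, "endpoint_set"),
              inherits(lv, "label_volume"), inherits(parc, "parcellation"))
    if (!all(keep_labels %in% parc$label_id)) {
      stop("keep_labels must be a subset of the parcellation labels")
    }
    es <- x
    if (mode == "traversal_filter") {
      removed <- setdiff(parc$label_id, keep_labels)
      blocked <- vapply(es$records$traversed,
                        function(tr) any(tr %in% removed), logical(1))
      rec <- es$records[!blocked, , drop = FALSE]
      es <- endpoint_set(rec, es$subject_id, es$run_id)
      n_blocked <- sum(blocked)
    } else {
      n_blocked <- 0L
    }
    cm <- build_matrix(es, lv, parc, keep_labels = keep_labels)
    cm$discards <- c(cm$discards, mask_blocked = n_blocked)
    cm
  }
}

#' Normalize connection strengths by node volumes
#'
#' Divides each edge weight by the sum of the volumes of its two endpoint
#' regions, discounting the extra streamline mass that large structures
#' accrue simply by their size: `a'_ij = a_ij / (vol_i + vol_j)`.
#'
#' @param cm a [connectivity_matrix].
#' @param volumes named numeric vector of volumes (mm^3), names = node names,
#'   or a [parcellation] from which volumes for the present nodes are taken.
#' @return A [connectivity_matrix] of kind `"volume_normalized"`.
#' @export
volume_normalize <- function(cm, volumes) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (inherits(volumes, "parcellation")) {
    v <- volumes$volume_mm3[match(cm$node_labels, volumes$label_id)]
  } else {
    v <- as.numeric(volumes[cm$node_names])
  }
  if (anyNA(v) || any(v <= 0)) {
    stop("a node is missing a strictly positive volume")
  }
  denom <- outer(v, v, "+")
  w <- cm$weights / denom
  diag(w) <- 0
  connectivity_matrix(w, cm$node_labels, cm$node_names,
                      kind = "volume_normalized", discards = cm$discards)
}
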