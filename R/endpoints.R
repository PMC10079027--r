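#' Streamline endpoint records
#'
#' An endpoint record set holds, for one tractography run of one subject, the
#' first and last world-mm coordinates of each streamline plus the set of
#' region labels the streamline traverses. It is the minimal abstraction of a
#' tractogram the connectome build needs: only endpoints (and, synthetically,
#' traversed labels) matter for matrix construction.
#'
#' @param records data.frame with columns `x1,y1,z1,x2,y2,z2` and a list
#'   column `traversed` of integer vectors (possibly empty).
#' @param subject_id,run_id identifiers.
#' @return Object of class `endpoint_set`.
#' @export
endpoint_set <- function(records, subject_id = 1L, run_id = 1L) {
  stopifnot(is.data.frame(records))
  needed <- c("x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(needed %in% names(records))) {
    stop("records need columns ", paste(needed, collapse = ","))
  }
  if (is.null(records$traversed)) {
    records$traversed <- replicate(nrow(records), integer(0), simplify = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 subject_id = subject_id, run_id = run_id),
            class = "endpoint_set")
}

#' @export
print.endpoint_set <- function(x, ...) {
  cat(sprintf("EndpointRecordSet: subject %s run %s, %d streamlines\n",
              x$subject_id, x$run_id, nrow(x$records)))
  invisible(x)
}

#' Sample synthetic streamline endpoints
#'
#' Draws `n_streamlines` unordered region pairs from the ground-truth pair
#' distribution, then places each endpoint uniformly at random inside a voxel
#' of its region (voxel centre plus sub-voxel jitter) and maps it to world
#' coordinates through the label volume's affine. Which endpoint comes
#' "first" is randomized, as is record order; traversed labels are copied
#' from the ground truth.
#'
#' @param gt a `ground_truth` object.
#' @param lv the [label_volume] the endpoints are placed in.
#' @param n_streamlines number of records (>= 1).
#' @param seed integer seed.
#' @param subject_id,run_id tags stored on the output.
#' @return An [endpoint_set].
#' @export
sample_endpoints <- function(gt, lv, n_streamlines, seed = 1L,
                             subject_id = 1L, run_id = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(lv, "label_volume"))
  n_streamlines <- as.integer(n_streamlines)
  if (is.na(n_streamlines) || n_streamlines < 1L) stop("n_streamlines must be >= 1")
  sample_endpoints_impl(gt$prob_matrix, gt, lv, n_streamlines, seed,
                        subject_id, run_id)
}

# shared by sample_endpoints and generate_ensemble (which perturbs the
# probability matrix per subject)
sample_endpoints_impl <- function(p, gt, lv, n, seed, subject_id, run_id) {
  labs <- gt$parc$label_id
  nreg <- length(labs)
  ut <- which(upper.tri(p))
  probs <- p[ut]
  pair_i <- row(p)[ut]
  pair_j <- col(p)[ut]

  # voxel lookup per label (0-based indices)
  vox <- lapply(labs, function(l) label_voxels(lv, l))
  nvox <- vapply(vox, nrow, integer(1))
  if (any(nvox == 0L)) stop("a region has zero voxels in the label volume")

  with_seed(seed, {
    pick <- sample.int(length(ut), n, replace = TRUE, prob = probs)
    a <- pair_i[pick]
    b <- pair_j[pick]
    # randomize which region supplies the first endpoint
    flip <- stats::runif(n) < 0.5
    first <- ifelse(flip, b, a)
    last <- ifelse(flip, a, b)

    draw_points <- function(region_idx) {
      out <- matrix(0, length(region_idx), 3)
      for (k in unique(region_idx)) {
        rows <- which(region_idx == k)
        v <- vox[[k]]
        sel <- v[sample.int(nrow(v), length(rows), replace = TRUE), , drop = FALSE]
        jit <- matrix(stats::runif(3 * length(rows), -0.49, 0.49), ncol = 3)
        out[rows, ] <- voxel_to_world(sel + jit, lv$affine)
      }
      out
    }
    p1 <- draw_points(first)
    p2 <- draw_points(last)
    trav <- gt$traversal_hub[cbind(a, b)]
    ord <- sample.int(n, n)

    records <- data.frame(
      x1 = p1[ord, 1], y1 = p1[ord, 2], z1 = p1[ord, 3],
      x2 = p2[ord, 1], y2 = p2[ord, 2], z2 = p2[ord, 3]
    )
    records$traversed <- lapply(trav[ord], function(h) {
      if (h == 0L) integer(0) else as.integer(h)
    })
    endpoint_set(records, subject_id, run_id)
  })
}

#' Generate a multi-subject, multi-run endpoint ensemble
#'
#' Emulates the study design of repeated probabilistic tractography: each
#' subject gets an individual connection-probability matrix — the ground
#' truth perturbed by independent multiplicative lognormal noise and
#' renormalized (so weights stay positive and pair mass stays 1) — and each
#' run is an independent endpoint sample from that subject matrix.
#'
#' @param gt a `ground_truth`.
#' @param lv a [label_volume].
#' @param n_subjects,n_runs,n_streamlines design sizes (all >= 1).
#' @param subject_noise_sd sd of the lognormal perturbation on the log scale
#'   (0 = all subjects share the ground truth).
#' @param seed integer seed; per-(subject, run) streams are derived from it.
#' @return List of [endpoint_set] objects (subjects x runs, run fastest),
#'   with attribute `subject_matrices` (list of per-subject probability
#'   matrices).
#' @export
generate_ensemble <- function(gt, lv, n_subjects, n_runs, n_streamlines,
                              subject_noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"), inherits(lv, "label_volume"))
  if (n_subjects < 1L || n_runs < 1L) stop("need n_subjects >= 1 and n_runs >= 1")
  if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0")

  n <- nrow(gt$prob_matrix)
  sets <- vector("list", n_subjects * n_runs)
  subject_matrices <- vector("list", n_subjects)
  idx <- 1L
  for (s in seq_len(n_subjects)) {
    ps <- gt$prob_matrix
    if (subject_noise_sd > 0) {
      ps <- with_seed(derive_seed(seed, s, 0L), {
        noise <- matrix(0, n, n)
        noise[upper.tri(noise)] <- stats::rlnorm(n * (n - 1) / 2,
                                                 0, subject_noise_sd)
        noise <- noise + t(noise)
        m <- gt$prob_matrix * noise
        m / (sum(m) / 2)
      })
    }
    subject_matrices[[s]] <- ps
    for (r in seq_len(n_runs)) {
      sets[[idx]] <- sample_endpoints_impl(ps, gt, lv, n_streamlines,
                                           derive_seed(seed, s, r),
                                           subject_id = s, run_id = r)
      idx <- idx + 1L
    }
  }
  attr(sets, "subject_matrices") <- subject_matrices
  sets
}

#' Read or write endpoint records as TSV
#'
#' Columns: `subject, run, streamline_id, x1,y1,z1, x2,y2,z2, traversed`
#' (semicolon-separated label ids, possibly empty).
#' @param es an [endpoint_set] or list of them.
#' @param path file path.
#' @export
write_endpoints_tsv <- function(es, path) {
  if (inherits(es, "endpoint_set")) es <- list(es)
  tabs <- lapply(es, function(e) {
    r <- e$records
    data.frame(
      subject = e$subject_id, run = e$run_id,
      streamline_id = seq_len(nrow(r)),
      x1 = r$x1, y1 = r$y1, z1 = r$z1, x2 = r$x2, y2 = r$y2, z2 = r$z2,
      traversed = vapply(r$traversed, paste, character(1), collapse = ";")
    )
  })
  out <- do.call(rbind, tabs)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoints_tsv
#' @export
read_endpoints_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(traversed = "character"))
  split_keys <- interaction(df$subject, df$run, drop = TRUE)
  lapply(split(df, split_keys), function(g) {
    rec <- g[, c("x1", "y1", "z1", "x2", "y2", "z2")]
    rec$traversed <- lapply(strsplit(g$traversed, ";", fixed = TRUE),
                            function(v) as.integer(v[nzchar(v)]))
    endpoint_set(rec, subject_id = g$subject[1], run_id = g$run[1])
  })
}
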