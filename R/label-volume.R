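#' Label volumes
#'
#' A label volume is a 3-D integer lattice of region labels together with a
#' 4x4 affine mapping 0-based voxel indices to world millimetre coordinates
#' (the NIfTI convention). Background voxels carry label 0.
#'
#' @param grid 3-D integer array of labels.
#' @param affine invertible 4x4 voxel-index -> world-mm matrix.
#' @param parc the [parcellation] the labels refer to (optional but checked
#'   when given: every nonzero grid value must be one of its label ids and
#'   every region must occupy at least one voxel).
#' @return Object of class `label_volume`: list with `grid` and `affine`.
#' @export
label_volume <- function(grid, affine = diag(4), parc = NULL) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine must be invertible")
  storage.mode(grid) <- "integer"
  if (!is.null(parc)) {
    present <- sort(unique(as.vector(grid)))
    present <- present[present != 0L]
    unknown <- setdiff(present, parc$label_id)
    if (length(unknown) > 0) {
      stop("grid contains labels not in the parcellation: ",
           paste(unknown, collapse = ", "))
    }
    absent <- setdiff(parc$label_id, present)
    if (length(absent) > 0) {
      stop("regions with no voxels: ", paste(absent, collapse = ", "))
    }
  }
  structure(list(grid = grid, affine = affine), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("LabelVolume: %s grid, %d nonzero labels\n",
              paste(dim(x$grid), collapse = "x"),
              length(setdiff(unique(as.vector(x$grid)), 0L))))
  invisible(x)
}

#' Generate a synthetic parcellated label volume
#'
#' Partitions a brain-like ellipsoid inside the grid into regions by
#' multiplicatively weighted nearest-seed (Voronoi) assignment: each region
#' gets one seed voxel, and voxels are assigned to the region minimising
#' Euclidean distance divided by the cube root of the region volume, so voxel
#' counts grow roughly in proportion to the parcellation volumes. Voxels
#' outside the ellipsoid are background (0).
#'
#' @param parc a [parcellation].
#' @param grid_shape integer length-3 grid dimensions; must satisfy
#'   `prod(grid_shape) >= nrow(parc)`.
#' @param affine 4x4 voxel->world transform (default identity).
#' @param seed integer seed.
#' @return A [label_volume].
#' @export
make_label_volume <- function(parc, grid_shape = c(24L, 24L, 24L),
                              affine = diag(4), seed = 1L) {
  stopifnot(inherits(parc, "parcellation"))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  n <- nrow(parc)
  if (prod(as.double(grid_shape)) < n) stop("grid too small for region count")

  # 0-based voxel index grid
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]) - 1L,
                               j = seq_len(grid_shape[2]) - 1L,
                               k = seq_len(grid_shape[3]) - 1L))
  centre <- (grid_shape - 1) / 2
  semi <- pmax(grid_shape * 0.45, 0.5)
  inside <- rowSums(sweep(sweep(idx, 2, centre), 2, semi, "/")^2) <= 1
  if (sum(inside) < n) stop("grid too small: ellipsoid mask has fewer voxels than regions")
  mask_idx <- idx[inside, , drop = FALSE]

  with_seed(seed, {
    seeds <- mask_idx[sample.int(nrow(mask_idx), n), , drop = FALSE]
    r <- parc$volume_mm3^(1 / 3)
    # weighted Voronoi: argmin_k ||v - seed_k|| / r_k
    best_lab <- integer(nrow(mask_idx))
    best_d <- rep(Inf, nrow(mask_idx))
    for (k in seq_len(n)) {
      dk <- sqrt(rowSums(sweep(mask_idx, 2, seeds[k, ])^2)) / r[k]
      better <- dk < best_d
      best_d[better] <- dk[better]
      best_lab[better] <- parc$label_id[k]
    }
    grid <- array(0L, dim = grid_shape)
    grid[mask_idx + 1L] <- best_lab
    # a region's own seed voxel always belongs to it, so no region is empty
    grid[seeds + 1L] <- parc$label_id
    label_volume(grid, affine, parc)
  })
}

voxel_to_world <- function(vox0, affine) {
  h <- cbind(vox0, 1)
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(world, affine) {
  h <- cbind(world, 1)
  t(solve(affine) %*% t(h))[, 1:3, drop = FALSE]
}

# 0-based voxel indices (n x 3) of every voxel carrying `label`
label_voxels <- function(lv, label) {
  w <- which(lv$grid == label, arr.ind = TRUE)
  w - 1L
}

#' Read or write a label volume as NIfTI-1
#'
#' Labels are stored as int16 with the affine in the sform.
#' @param lv a [label_volume].
#' @param path file path (`.nii`).
#' @export
write_label_nifti <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  img <- RNifti::asNifti(lv$grid)
  RNifti::qform(img) <- structure(lv$affine, code = 2L)
  RNifti::sform(img) <- structure(lv$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_label_nifti
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- array(as.integer(round(as.vector(img))), dim = dim(img))
  affine <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(affine) <- list(dim = dim(affine))
  label_volume(grid, affine)
}
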