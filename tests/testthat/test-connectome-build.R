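make_toy_volume <- function() {
  # 4x1x1 grid, labels 1..3 in the first three voxels, background in the last
  grid <- array(0L, c(4, 1, 1))
  grid[1:3] <- 1:3
  parc <- parcellation(data.frame(label_id = 1:3, name = c("A", "B", "C"),
                                  volume_mm3 = c(2, 3, 5), is_hub = FALSE,
                                  community = 1L))
  list(lv = label_volume(grid, diag(4), parc), parc = parc)
}

toy_records <- function(pairs) {
  # pairs of voxel x-coordinates (labels live at x = 0,1,2)
  z <- numeric(nrow(pairs))
  data.frame(x1 = pairs[, 1], y1 = z, z1 = z,
             x2 = pairs[, 2], y2 = z, z2 = z)
}

test_that("endpoint labeling rounds half away from zero and handles bounds", {
  tv <- make_toy_volume()
  expect_equal(assign_endpoint_label(c(1.2, 0.9, 2.0),
                                     label_volume(array(7L, c(3, 3, 3)))), 7L)
  # rounding rule: 1.5 -> 2, -0.2 -> 0
  grid <- array(0L, c(4, 1, 1)); grid[1:4] <- c(5L, 6L, 7L, 8L)
  lv <- label_volume(grid, diag(4))
  expect_equal(assign_endpoint_label(rbind(c(1.5, 0, 0), c(0.49, 0, 0)), lv),
               c(7L, 5L))
  # out of bounds => background
  expect_equal(assign_endpoint_label(c(9, 0, 0), tv$lv), 0L)
  expect_equal(assign_endpoint_label(c(-1, 0, 0), tv$lv), 0L)
  # 2 mm isotropic affine: world (4,0,0) -> voxel (2,0,0)
  aff <- diag(c(2, 2, 2, 1))
  grid2 <- array(1L, c(3, 1, 1)); grid2[3] <- 9L
  expect_equal(assign_endpoint_label(c(4, 0, 0), label_volume(grid2, aff)), 9L)
  expect_error(assign_endpoint_label(c(NA, 0, 0), tv$lv), "finite")
})

test_that("matrix building counts symmetric pairs and tallies discards", {
  tv <- make_toy_volume()
  rec <- toy_records(rbind(c(0, 1), c(1, 0), c(1, 2),  # pairs AB, BA, BC
                           c(3, 0),                    # background endpoint
                           c(1, 1)))                   # self pair
  es <- endpoint_set(rec)
  cm <- build_matrix(es, tv$lv, tv$parc)
  expect_equal(cm$weights["A", "B"], 2)
  expect_equal(cm$weights["B", "C"], 1)
  expect_equal(cm$weights, t(cm$weights))
  expect_true(all(diag(cm$weights) == 0))
  expect_equal(unname(cm$discards["background"]), 1)
  expect_equal(unname(cm$discards["self_pair"]), 1)
  # conservation: total weight = 2 * kept, kept + discarded = input
  expect_equal(sum(cm$weights), 2 * (nrow(rec) - sum(cm$discards)))

  # subset: records touching an excluded label are tallied outside_subset
  cm2 <- build_matrix(es, tv$lv, tv$parc, keep_labels = c(1, 2))
  expect_equal(unname(cm2$discards["outside_subset"]), 1)
  expect_equal(dim(cm2), c(2L, 2L))

  empty <- build_matrix(endpoint_set(toy_records(matrix(numeric(0), 0, 2))),
                        tv$lv, tv$parc)
  expect_true(all(empty$weights == 0))
})

test_that("run and subject averaging are elementwise with sample SD", {
  m1 <- connectivity_matrix(matrix(c(0, 2, 2, 0), 2), 1:2)
  m2 <- connectivity_matrix(matrix(c(0, 4, 4, 0), 2), 1:2)
  avg <- average_runs(list(m1, m2))
  expect_equal(avg$weights[1, 2], 3)
  expect_equal(avg$kind, "run_mean")
  expect_equal(average_runs(list(m1))$weights, m1$weights)

  st <- average_subjects(list(m1, m2))
  expect_equal(st$mean_matrix$weights[1, 2], 3)
  expect_equal(st$sd_matrix[1, 2], sqrt(2))
  expect_equal(average_subjects(list(m1, m1))$sd_matrix,
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_true(all(is.na(average_subjects(list(m1))$sd_matrix)))

  # degree is linear: mean of degree vectors = degree of mean matrix
  d1 <- degree_centrality(m1)$values
  d2 <- degree_centrality(m2)$values
  expect_equal((d1 + d2) / 2, degree_centrality(st$mean_matrix)$values)

  m3 <- connectivity_matrix(matrix(0, 3, 3), 1:3)
  expect_error(average_runs(list(m1, m3)), "mismatched")
})

test_that("the three restriction modes differ exactly as intended", {
  tv <- make_toy_volume()
  w <- matrix(c(0, 5, 2, 5, 0, 1, 2, 1, 0), 3)
  cm <- connectivity_matrix(w, 1:3, c("A", "B", "C"))
  sub <- restrict_connectome(cm, keep_labels = c(1, 2), mode = "submatrix")
  expect_equal(sub$weights["A", "B"], 5)
  expect_equal(dim(sub), c(2L, 2L))

  rec <- toy_records(rbind(c(0, 2), c(0, 1)))   # pairs AC, AB
  rec$traversed <- list(integer(0), 3L)          # AB traverses C
  es <- endpoint_set(rec)
  keep <- c(1, 2)
  ep <- restrict_connectome(es, keep, mode = "endpoint_filter",
                            lv = tv$lv, parc = tv$parc)
  expect_equal(ep$weights["A", "B"], 1)          # AC dropped (endpoint), AB kept
  tr <- restrict_connectome(es, keep, mode = "traversal_filter",
                            lv = tv$lv, parc = tv$parc)
  expect_equal(tr$weights["A", "B"], 0)          # AB dropped too (traverses C)
  expect_equal(unname(tr$discards["mask_blocked"]), 1)

  expect_error(restrict_connectome(cm, keep_labels = 99, mode = "submatrix"),
               "subset")
})

test_that("volume normalization divides by endpoint-volume sums", {
  cm <- connectivity_matrix(matrix(c(0, 10, 10, 0), 2), 1:2, c("A", "B"))
  nm <- volume_normalize(cm, c(A = 2, B = 3))
  expect_equal(nm$weights["A", "B"], 2)
  expect_equal(nm$kind, "volume_normalized")
  # homogeneity: scaling volumes by c scales weights by 1/c
  nm2 <- volume_normalize(cm, c(A = 4, B = 6))
  expect_equal(nm2$weights, nm$weights / 2)
  expect_error(volume_normalize(cm, c(A = 2)), "volume")
  expect_error(volume_normalize(cm, c(A = 2, B = -1)), "volume")
})

test_that("submatrix restriction commutes with averaging", {
  set.seed(33)
  mats <- lapply(1:3, function(i) rand_cm(5, seed = i))
  keep <- c(1, 3, 5)
  a_then_r <- restrict_connectome(average_runs(mats), keep, "submatrix")
  r_then_a <- average_runs(lapply(mats, restrict_connectome, keep, "submatrix"))
  expect_equal(a_then_r$weights, r_then_a$weights)
})

test_that("recovered matrix converges to the conditional ground truth", {
  p <- make_parcellation(8, 1, seed = 2)
  lv <- make_label_volume(p, c(18, 18, 18), seed = 3)
  gt <- make_ground_truth_matrix(p)
  es <- sample_endpoints(gt, lv, 50000, seed = 4)
  cm <- build_matrix(es, lv, p)
  kept <- 50000 - sum(cm$discards)
  est <- cm$weights / kept   # a_ij (i<j) counts each unordered pair once
  pm <- gt$prob_matrix
  ut <- upper.tri(pm)
  bound <- 4 * sqrt(pm[ut] * (1 - pm[ut]) / kept)
  expect_true(all(abs(est[ut] - pm[ut]) <= bound))
})
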