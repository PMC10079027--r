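test_that("degree centrality is the row sum with the handshake identity", {
  w <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  cm <- connectivity_matrix(w, 1:3)
  d <- degree_centrality(cm)
  expect_equal(unname(d$values), c(3, 4, 5))
  expect_equal(sum(d$values), sum(w))
  expect_equal(unname(degree_centrality(connectivity_matrix(matrix(0, 3, 3), 1:3))$values),
               rep(0, 3))
})

test_that("eigenvector centrality matches closed forms and stays positive", {
  k3 <- connectivity_matrix(matrix(1, 3, 3) - diag(3), 1:3)
  expect_equal(unname(eigenvector_centrality(k3)$values), rep(1, 3))

  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1; path <- path + t(path)
  ev <- eigenvector_centrality(connectivity_matrix(path, 1:3))
  expect_equal(unname(ev$values), c(1 / sqrt(2), 1, 1 / sqrt(2)),
               tolerance = 1e-9)

  cm <- rand_connected_cm(8, seed = 21)
  v <- eigenvector_centrality(cm)$values
  expect_true(all(v > 0))          # Perron vector of a connected graph
  expect_equal(max(v), 1)

  disc <- two_cliques_cm(3)
  expect_warning(vd <- eigenvector_centrality(disc), "disconnected")
  expect_true(any(vd$values == 0))
})

test_that("shortest paths use reciprocal-weight distances and count ties", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 3] <- 1; w[1, 3] <- 0.4
  w <- w + t(w)
  sp <- shortest_paths(connectivity_matrix(w, 1:3))
  expect_equal(sp$dist[1, 3], 2)   # via B beats direct 1/0.4 = 2.5

  cyc <- matrix(0, 4, 4)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 4] <- cyc[1, 4] <- 1
  cyc <- cyc + t(cyc)
  spc <- shortest_paths(connectivity_matrix(cyc, 1:4))
  expect_equal(spc$sigma[1, 3], 2)
  expect_equal(spc$sigma[2, 4], 2)

  # disconnected pair: infinite distance, zero path count
  disc <- two_cliques_cm(3)
  spd <- shortest_paths(disc)
  expect_equal(spd$dist[1, 4], Inf)
  expect_equal(spd$sigma[1, 4], 0)
})

test_that("distances, counts, and betweenness agree with brute-force oracles", {
  for (s in 1:40) {
    n <- sample(3:6, 1)
    cm <- rand_cm(n, density = 0.7, seed = s)
    sp <- shortest_paths(cm)
    fw <- oracle_floyd_warshall(cm$weights)
    expect_lt(max(abs(sp$dist - fw)[is.finite(fw)]), 1e-9)
    pe <- oracle_path_enumeration(cm$weights)
    expect_equal(sp$sigma, pe$sigma, ignore_attr = TRUE)
    if (n >= 3) {
      b <- betweenness_centrality(cm)$values
      expect_lt(max(abs(b - oracle_betweenness(cm$weights))), 1e-9)
    }
    if (all(is.finite(fw))) {
      v <- eigenvector_centrality(cm)$values
      expect_lt(max(abs(v - oracle_eigenvector(cm$weights))), 1e-9)
    }
  }
})

test_that("a star's centre takes all the betweenness; cliques have none", {
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  b <- betweenness_centrality(connectivity_matrix(star, 1:5))$values
  expect_equal(unname(b), c(1, 0, 0, 0, 0))
  k3 <- connectivity_matrix(matrix(1, 3, 3) - diag(3), 1:3)
  expect_equal(unname(betweenness_centrality(k3)$values), rep(0, 3))
  expect_error(betweenness_centrality(connectivity_matrix(matrix(0, 2, 2), 1:2)),
               "3 nodes")
})

test_that("centralities transform correctly under scaling and relabeling", {
  cm <- rand_connected_cm(7, seed = 5)
  scaled <- connectivity_matrix(3.7 * cm$weights, cm$node_labels)
  expect_equal(degree_centrality(scaled)$values,
               3.7 * degree_centrality(cm)$values)
  expect_equal(eigenvector_centrality(scaled)$values,
               eigenvector_centrality(cm)$values, tolerance = 1e-9)
  expect_equal(betweenness_centrality(scaled)$values,
               betweenness_centrality(cm)$values, tolerance = 1e-12)

  perm <- c(3, 1, 7, 2, 6, 4, 5)
  pm <- connectivity_matrix(cm$weights[perm, perm], cm$node_labels[perm],
                            cm$node_names[perm])
  for (fn in list(degree_centrality, eigenvector_centrality,
                  betweenness_centrality)) {
    expect_equal(unname(fn(pm)$values), unname(fn(cm)$values[perm]),
                 tolerance = 1e-9)
  }
})

test_that("betweenness always lies in [0, 1]", {
  for (s in 1:20) {
    cm <- rand_cm(sample(3:7, 1), density = 0.6, seed = 100 + s)
    b <- betweenness_centrality(cm)$values
    expect_true(all(b >= 0 & b <= 1 + 1e-12))
  }
})

test_that("per-subject centralities behave under linearity and its failure", {
  m1 <- rand_cm(4, seed = 1)
  m2 <- rand_cm(4, seed = 2)
  same <- per_subject_centralities(list(m1, m1), "degree")
  expect_identical(same[[1]]$values, same[[2]]$values)

  # degree commutes with averaging ...
  d <- per_subject_centralities(list(m1, m2), "degree")
  mean_d <- (d[[1]]$values + d[[2]]$values) / 2
  expect_equal(mean_d,
               degree_centrality(average_subjects(list(m1, m2))$mean_matrix)$values)

  # ... but eigenvector centrality does not
  e1 <- eigenvector_centrality(rand_connected_cm(3, seed = 3))$values
  e2 <- eigenvector_centrality(rand_connected_cm(3, seed = 14))$values
  avg <- average_subjects(list(rand_connected_cm(3, seed = 3),
                               rand_connected_cm(3, seed = 14)))
  e_avg <- eigenvector_centrality(avg$mean_matrix)$values
  expect_gt(max(abs((e1 + e2) / 2 - e_avg)), 1e-6)
})

test_that("ranking tables normalize by the maximum mean and break ties by name", {
  mk <- function(vals, names) {
    cm <- connectivity_matrix(matrix(0, 3, 3), 1:3, names)
    structure(list(values = stats::setNames(vals, names), measure = "degree",
                   node_labels = 1:3), class = "centrality_vector")
  }
  rt <- rank_structures(list(mk(c(2, 4, 8), c("a", "b", "c"))))
  expect_equal(rt$normalized_mean, c(1, 0.5, 0.25))
  expect_equal(rt$name, c("c", "b", "a"))
  expect_equal(rt$rank, 1:3)
  expect_equal(rt$normalized_mean[1], 1)

  tie <- rank_structures(list(mk(c(5, 5, 1), c("zeta", "alpha", "omega"))))
  expect_equal(tie$name[1:2], c("alpha", "zeta"))
  expect_equal(tie$normalized_mean[1], tie$normalized_mean[2])

  expect_error(rank_structures(list(mk(c(0, 0, 0), c("a", "b", "c")))),
               "zero")

  # cross-subject mean and SD columns
  two <- rank_structures(list(mk(c(2, 1, 0.5), c("a", "b", "c")),
                              mk(c(4, 1, 0.5), c("a", "b", "c"))))
  expect_equal(two$mean[two$name == "a"], 3)
  expect_equal(two$sd[two$name == "a"], sqrt(2))
  expect_equal(nrow(rank_structures(list(mk(c(2, 4, 8), letters[1:3])), top = 2)), 2)
})
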