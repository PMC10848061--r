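test_that("weighted distances follow the reciprocal length map", {
  w <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(distance_matrix(connectome(w))[1, 2], 0.5)

  # a strong two-hop detour beats a weak direct edge
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 4
  w[3, 2] <- w[2, 3] <- 4
  expect_equal(distance_matrix(connectome(w))[1, 2], 0.5)
})

test_that("path-based metrics match brute-force and igraph oracles on random graphs", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    w <- random_weights(n, p = runif(1, 0.2, 0.9))
    conn <- connectome(w)
    d <- distance_matrix(conn)
    expect_equal(unname(d), oracle_distances(w), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(w > 0, 1 / w, 0), mode = "undirected", weighted = TRUE)
    d_ig <- igraph::distances(g, algorithm = "dijkstra")
    dimnames(d_ig) <- NULL
    expect_equal(unname(d), d_ig, tolerance = 1e-12)
    expect_equal(global_efficiency(conn), oracle_eglob(w), tolerance = 1e-12)
    expect_equal(local_efficiency(conn), oracle_eloc(w), tolerance = 1e-12)
    expect_equal(clustering_coefficient(conn)$nodal, oracle_clustering(w),
                 tolerance = 1e-12)
  }
})

test_that("network strength is the mean node strength", {
  expect_equal(network_strength(connectome(matrix(c(0, 3, 3, 0), 2))), 3)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 2
  tri[2, 3] <- tri[3, 2] <- 3
  expect_equal(network_strength(connectome(tri)), 4)  # strengths 3, 4, 5
  expect_equal(network_strength(connectome(matrix(0, 4, 4))), 0)
})

test_that("efficiency hand values and conventions hold", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(connectome(matrix(c(0, 1, 1, 0), 2))), 1)
  expect_equal(global_efficiency(connectome(path3)), 5 / 6)
  expect_equal(global_efficiency(connectome(matrix(0, 2, 2))), 0)

  expect_equal(unname(nodal_efficiency(connectome(path3))), c(0.75, 1, 0.75))
  # identity: mean nodal efficiency equals global efficiency
  set.seed(3)
  w <- random_weights(7, 0.5)
  expect_equal(mean(nodal_efficiency(connectome(w))),
               global_efficiency(connectome(w)))

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(local_efficiency(connectome(tri)), 1)
  star <- matrix(0, 5, 5); star[1, -1] <- star[-1, 1] <- 1
  expect_equal(local_efficiency(connectome(star)), 0)
})

test_that("characteristic path length averages finite pairs with explicit policy", {
  expect_equal(characteristic_path_length(connectome(matrix(c(0, 2, 2, 0), 2))),
               0.5)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(characteristic_path_length(connectome(path3)), 8 / 6)

  disc <- matrix(0, 3, 3)
  disc[1, 2] <- disc[2, 1] <- 1
  expect_warning(lp <- characteristic_path_length(connectome(disc)),
                 "unreachable")
  expect_equal(lp, 1)
  expect_error(characteristic_path_length(connectome(disc),
                                          on_disconnect = "error"),
               "disconnected")
  expect_error(characteristic_path_length(connectome(matrix(0, 3, 3))),
               "finite")
})

test_that("Onnela clustering hand values hold", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficient(connectome(tri))$cp, 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(clustering_coefficient(connectome(path3))$cp, 0)
  triw <- matrix(0, 3, 3)
  triw[1, 2] <- triw[2, 1] <- 1
  triw[1, 3] <- triw[3, 1] <- 2
  triw[2, 3] <- triw[3, 2] <- 4
  expect_equal(clustering_coefficient(connectome(triw))$nodal,
               rep(0.5, 3))      # (0.25 * 0.5 * 1)^(1/3) per node
})

test_that("degree distribution skewness reflects hub structure", {
  ring <- matrix(0, 6, 6)
  for (i in 1:6) { j <- i %% 6 + 1; ring[i, j] <- ring[j, i] <- 1 }
  expect_equal(degree_distribution(connectome(ring))$skewness, 0)
  star <- matrix(0, 6, 6); star[1, -1] <- star[-1, 1] <- 1
  expect_gt(degree_distribution(connectome(star))$skewness, 0)
  empty <- degree_distribution(connectome(matrix(0, 4, 4)))
  expect_equal(unname(empty$degree), rep(0, 4))
})

test_that("metrics obey scale and relabeling symmetries", {
  set.seed(17)
  for (i in 1:10) {
    w <- random_weights(8, 0.6)
    conn <- connectome(w)
    scaled <- connectome(3 * w)
    expect_equal(characteristic_path_length(scaled, on_disconnect = "ignore"),
                 characteristic_path_length(conn, on_disconnect = "ignore") / 3)
    expect_equal(global_efficiency(scaled), 3 * global_efficiency(conn))
    expect_equal(unname(nodal_efficiency(scaled)), unname(3 * nodal_efficiency(conn)))
    expect_equal(clustering_coefficient(scaled)$cp,
                 clustering_coefficient(conn)$cp)
    expect_equal(degree_distribution(scaled)$degree,
                 degree_distribution(conn)$degree)

    perm <- sample(8)
    wp <- w[perm, perm]
    expect_equal(unname(nodal_efficiency(connectome(wp))),
                 unname(nodal_efficiency(conn)[perm]))
    expect_equal(global_efficiency(connectome(wp)), global_efficiency(conn))
    expect_equal(network_strength(connectome(wp)), network_strength(conn))
  }
})

test_that("global efficiency is weakly monotone in any single weight", {
  set.seed(23)
  for (i in 1:10) {
    w <- random_weights(7, 0.5)
    e0 <- global_efficiency(connectome(w))
    idx <- which(upper.tri(w), arr.ind = TRUE)
    pick <- idx[sample.int(nrow(idx), 1), ]
    w[pick[1], pick[2]] <- w[pick[2], pick[1]] <- w[pick[1], pick[2]] + 5
    expect_gte(global_efficiency(connectome(w)) + 1e-12, e0)
  }
})

test_that("small-world coefficients self-normalise to 1", {
  set.seed(9)
  conn <- connectome(random_weights(8, 0.6))
  sw <- small_world_metrics(conn, list(conn, conn, conn))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_error(small_world_metrics(conn, list()), "empty")
})
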