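# Cohort of b subjects over a fixed 4-node pattern where edge (1,2) is present
# in `m` of them.
presence_cohort <- function(m, n_sub = 10, n = 4) {
  lapply(seq_len(n_sub), function(s) {
    w <- matrix(0, n, n)
    if (s <= m) { w[1, 2] <- w[2, 1] <- 5 }
    w[3, 4] <- w[4, 3] <- 2  # always-present edge keeps the backbone nonempty
    connectome(w)
  })
}

test_that("backbone sign test gives the closed-form binomial tail", {
  bb <- backbone_network(presence_cohort(10), correction = "none")
  expect_equal(bb$p_values[1, 2], 0.5^10)
  expect_true(bb$adjacency[1, 2] == 1)   # p ~ 9.8e-4 < 0.05

  bb2 <- backbone_network(presence_cohort(2), correction = "none")
  expect_equal(bb2$p_values[1, 2], 0.25)
  expect_equal(bb2$adjacency[1, 2], 0)

  bb0 <- backbone_network(presence_cohort(0), correction = "none")
  expect_equal(bb0$p_values[1, 2], 1)
  expect_equal(bb0$adjacency[1, 2], 0)

  expect_error(backbone_network(presence_cohort(1, n_sub = 1)), "2 subjects")
})

test_that("backbone is monotone in alpha", {
  set.seed(13)
  subs <- lapply(1:12, function(i) connectome(random_weights(8, 0.5)))
  for (corr in c("BH", "bonferroni")) {
    a1 <- backbone_network(subs, alpha = 0.001, correction = corr)$adjacency
    a2 <- backbone_network(subs, alpha = 0.05, correction = corr)$adjacency
    expect_true(all(a2[a1 == 1] == 1))
  }
})

test_that("hub rule selects nodes a standard deviation above mean degree", {
  star <- matrix(0, 5, 5); star[1, -1] <- star[-1, 1] <- 1
  expect_equal(identify_hubs(connectome(star)), 1)  # degrees (4,1,1,1,1)

  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_warning(hubs <- identify_hubs(connectome(tri)), "degenerate")
  expect_equal(hubs, 1:3)

  expect_equal(identify_hubs(connectome(matrix(0, 4, 4))), integer(0))
})

test_that("edge classification partitions present edges by hub membership", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 2
  w[3, 4] <- w[4, 3] <- 1
  conn <- connectome(w)
  cls <- classify_edges(conn, c(1, 2))
  expect_equal(cls[1, 2], "rich")
  expect_equal(cls[1, 3], "feeder")
  expect_equal(cls[3, 4], "local")
  expect_equal(cls[2, 4], "absent")

  expect_true(all(classify_edges(conn, integer(0))[w > 0] == "local"))
  expect_true(all(classify_edges(conn, 1:4)[w > 0] == "rich"))
  expect_error(classify_edges(conn, 9), "out of range")
})

test_that("class strengths, ratios and weight conservation hold", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 5
  w[1, 3] <- w[3, 1] <- 2
  w[3, 4] <- w[4, 3] <- 1
  cs <- connection_strengths(connectome(w), c(1, 2))
  expect_equal(cs$strength_rich, 5)
  expect_equal(cs$strength_feeder, 2)
  expect_equal(cs$strength_local, 1)
  expect_equal(cs$ratio_rich_feeder, 2.5)
  expect_equal(cs$ratio_rich_local, 5)

  # no feeder edges -> undefined ratio flag
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 5
  w2[3, 4] <- w2[4, 3] <- 1
  cs2 <- connection_strengths(connectome(w2), c(1, 2))
  expect_true(is.na(cs2$ratio_rich_feeder))
  expect_false(cs2$ratio_defined[["rich_feeder"]])

  set.seed(19)
  for (i in 1:10) {
    w <- random_weights(8, 0.5)
    hubs <- sample(8, 3)
    cs <- connection_strengths(connectome(w), hubs)
    expect_equal(cs$strength_rich + cs$strength_feeder + cs$strength_local,
                 sum(w) / 2)
  }
})

test_that("weighted rich-club coefficient matches its definition and oracle", {
  # hub-hub edges are exactly the strongest -> phi = 1
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 9
  w[3, 4] <- w[4, 3] <- 2
  expect_equal(weighted_rich_club_coefficient(connectome(w), 1:2)$phi, 1)

  # hubs {1,2,3}, hub-hub weights {4,4}; strongest two are {10,4}
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 4
  w[1, 3] <- w[3, 1] <- 4
  w[4, 5] <- w[5, 4] <- 10
  res <- weighted_rich_club_coefficient(connectome(w), 1:3)
  expect_equal(res$phi, 8 / 14)
  expect_equal(res$n_rich_edges, 2)

  out <- weighted_rich_club_coefficient(connectome(matrix(0, 3, 3)), 1:2)
  expect_false(out$defined)

  set.seed(29)
  for (i in 1:25) {
    w <- random_weights(8, 0.6)
    hubs <- sort(sample(8, sample(2:4, 1)))
    got <- weighted_rich_club_coefficient(connectome(w), hubs)$phi
    expect_equal(got, oracle_phi(w, hubs))
    # scale invariance
    expect_equal(weighted_rich_club_coefficient(connectome(2.5 * w), hubs)$phi,
                 got)
    # enlarging the club by the next-highest-degree node still matches
    k <- rowSums(w > 0)
    nxt <- setdiff(order(k, decreasing = TRUE), hubs)[1]
    hubs2 <- sort(c(hubs, nxt))
    expect_equal(weighted_rich_club_coefficient(connectome(w), hubs2)$phi,
                 oracle_phi(w, hubs2))
  }
})

test_that("normalised rich club is 1 against copies and errors when undefined", {
  set.seed(37)
  conn <- connectome(random_weights(8, 0.6))
  hubs <- identify_hubs(conn)
  nr <- normalized_rich_club(conn, hubs, list(conn, conn))
  expect_equal(nr$phi_norm, 1)

  w <- matrix(0, 4, 4); w[3, 4] <- w[4, 3] <- 1
  expect_error(normalized_rich_club(connectome(w), 1:2, list(conn)),
               "no hub-hub")
})

test_that("a weight-shuffled random network shows no rich-club effect", {
  set.seed(47)
  # iid weights on an Erdos-Renyi topology: phi_norm should sit near 1
  w <- random_weights(30, 0.3, wmax = 100)
  conn <- connectome(w)
  hubs <- identify_hubs(conn)
  ens <- matched_ensemble(conn, n = 100, seed = 8)
  nr <- normalized_rich_club(conn, hubs, ens)
  phis <- vapply(ens$networks,
                 function(g) weighted_rich_club_coefficient(g, hubs)$phi,
                 numeric(1))
  se <- sd(phis, na.rm = TRUE) / sqrt(sum(!is.na(phis)))
  expect_lt(abs(nr$phi - nr$phi_rand_mean), 2.5 * se * sqrt(sum(!is.na(phis))))
})
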