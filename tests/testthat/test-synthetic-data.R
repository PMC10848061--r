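small_config <- function(...) {
  cohort_config(n_nodes = 30, n_hubs = 5, n_vulnerable = 6, n_resistant = 6,
                ...)
}

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_nodes = 10, n_hubs = 10), "n_hubs")
  expect_error(cohort_config(p_hub_hub = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(p_hub_hub = 0.1, p_hub_periph = 0.5,
                             p_periph_periph = 0.9), "p_hub_hub")
  expect_error(cohort_config(delta_rich = 0), "delta_rich")
  expect_error(cohort_config(delta_rich = 1.4), "delta_rich")
  expect_error(cohort_config(lapse_dispersion = -1), "dispersion")
})

test_that("degenerate probability limits give complete or tree topologies", {
  full <- cohort_config(n_nodes = 12, n_hubs = 3, p_hub_hub = 1,
                        p_hub_periph = 1, p_periph_periph = 1, seed = 2)
  topo <- generate_template_topology(full)
  expect_equal(sum(topo$adjacency) / 2, choose(12, 2))

  none <- cohort_config(n_nodes = 12, n_hubs = 3, p_hub_hub = 0,
                        p_hub_periph = 0, p_periph_periph = 0, seed = 2)
  tree <- generate_template_topology(none)
  # forced connectivity: a spanning structure with n - 1 bridging edges
  expect_equal(sum(tree$adjacency) / 2, 11)
  g <- igraph::graph_from_adjacency_matrix(tree$adjacency > 0, "undirected")
  expect_equal(igraph::components(g)$no, 1)
})

test_that("hubs have higher degree than the periphery across seeds", {
  diffs <- vapply(1:20, function(sd) {
    topo <- generate_template_topology(cohort_config(seed = sd))
    k <- rowSums(topo$adjacency)
    mean(k[topo$hub_flags]) - mean(k[!topo$hub_flags])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("cohorts are deterministic, symmetric, integer-weighted", {
  cfg <- small_config(seed = 11)
  c1 <- generate_lapse_scores(generate_cohort(cfg))
  c2 <- generate_lapse_scores(generate_cohort(cfg))
  expect_identical(lapply(c1$subjects, `[[`, "weights"),
                   lapply(c2$subjects, `[[`, "weights"))
  expect_identical(c1$lapse_sd, c2$lapse_sd)
  for (s in c1$subjects) {
    expect_equal(s$weights, t(s$weights))
    expect_equal(s$weights, round(s$weights))
    expect_true(all(s$weights >= 0))
    expect_equal(diag(s$weights), rep(0, 30), ignore_attr = TRUE)
  }
  expect_error(
    generate_cohort(cohort_config(n_nodes = 30, n_hubs = 5,
                                  n_vulnerable = 0, n_resistant = 0)),
    "empty cohort"
  )
})

test_that("subject networks keep a right-skewed degree distribution", {
  skews <- vapply(1:20, function(sd) {
    co <- generate_cohort(cohort_config(seed = sd, n_vulnerable = 1,
                                        n_resistant = 0))
    degree_distribution(apply_fiber_threshold(co$subjects[[1]], 10))$skewness
  }, numeric(1))
  expect_gte(mean(skews > 0), 0.9)
})

test_that("delta_rich controls the planted hub-hub strength ratio", {
  # no planted effect: groups exchangeable in expectation
  cfg1 <- cohort_config(delta_rich = 1, n_vulnerable = 40, n_resistant = 40,
                        seed = 3)
  co1 <- generate_cohort(cfg1)
  hh <- function(co) {
    s <- vapply(co$subjects, function(x) {
      hp <- outer(co$hub_flags, co$hub_flags, `&`)
      sum(x$weights[hp & upper.tri(x$weights)])
    }, numeric(1))
    tapply(s, co$group, mean)
  }
  m1 <- hh(co1)
  expect_equal(unname(m1["vulnerable"] / m1["resistant"]), 1, tolerance = 0.05)

  cfg2 <- cohort_config(delta_rich = 0.7, n_vulnerable = 200,
                        n_resistant = 200, seed = 4)
  m2 <- hh(generate_cohort(cfg2))
  expect_equal(unname(m2["vulnerable"] / m2["resistant"]), 0.7,
               tolerance = 0.05)

  # monotone in delta
  means <- vapply(c(1, 0.8, 0.6), function(d) {
    co <- generate_cohort(cohort_config(delta_rich = d, seed = 5))
    unname(hh(co)["vulnerable"])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("lapse scores track group baselines and rich-club strength", {
  # null link: group means near configured baselines
  cfg <- cohort_config(behavior_link_slope = 0, n_vulnerable = 200,
                       n_resistant = 200, seed = 6)
  co <- generate_lapse_scores(generate_cohort(cfg))
  expect_equal(mean(co$lapse_sd[co$group == "vulnerable"]), 9.56,
               tolerance = 1.5)
  expect_equal(mean(co$lapse_sd[co$group == "resistant"]), 0.54,
               tolerance = 0.3)

  # negative link: pooled Spearman between strength and lapses negative
  neg <- vapply(1:25, function(sd) {
    co <- generate_lapse_scores(generate_cohort(cohort_config(seed = sd)))
    s <- vapply(co$subjects, function(x) {
      hp <- outer(co$hub_flags, co$hub_flags, `&`)
      sum(x$weights[hp & upper.tri(x$weights)])
    }, numeric(1))
    spearman_test(s, co$lapse_sd)$rho
  }, numeric(1))
  expect_gte(mean(neg < 0), 0.95)

  # degenerate all-zero networks: scores fall back to the baselines
  mats <- rep(list(matrix(0, 10, 10)), 6)
  coh <- make_cohort(mats, rep(c("vulnerable", "resistant"), each = 3))
  coh$hub_flags <- rep(c(TRUE, FALSE), c(3, 7))
  coh$config <- cohort_config(seed = 8)
  scored <- generate_lapse_scores(coh, coh$config)
  expect_true(all(is.finite(scored$lapse_sd)))

  empty <- coh; empty$subjects <- list()
  expect_error(generate_lapse_scores(empty, coh$config), "no connectomes")
})

test_that("cohorts round-trip through the on-disk format", {
  cfg <- small_config(seed = 13)
  co <- generate_lapse_scores(generate_cohort(cfg))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), length(co$subjects))
  expect_equal(back$group, co$group)
  expect_equal(back$lapse_sd, co$lapse_sd)
  for (i in seq_along(co$subjects)) {
    expect_equal(back$subjects[[i]]$weights, co$subjects[[i]]$weights,
                 tolerance = 1e-10)
  }
})
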