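# Brute-force oracles, independent of the package's computation paths.
# All operate on plain weight matrices.

# Floyd-Warshall in plain R on lengths 1/w.
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_eglob <- function(w) {
  d <- oracle_distances(w)
  n <- nrow(w)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (n * (n - 1))
}

oracle_eloc <- function(w) {
  n <- nrow(w)
  total <- 0
  for (i in seq_len(n)) {
    nbr <- setdiff(which(w[i, ] > 0), i)
    if (length(nbr) >= 2) total <- total + oracle_eglob(w[nbr, nbr, drop = FALSE])
  }
  total / n
}

# Onnela weighted clustering by explicit triple loop.
oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# Sort-based weighted rich-club coefficient.
oracle_phi <- function(w, hubs) {
  n <- nrow(w)
  rich <- c()
  all_w <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (w[i, j] > 0) {
      all_w <- c(all_w, w[i, j])
      if (i %in% hubs && j %in% hubs) rich <- c(rich, w[i, j])
    }
  }
  if (length(rich) == 0) return(NA_real_)
  sum(rich) / sum(sort(all_w, decreasing = TRUE)[seq_along(rich)])
}

# Connected components of an edge set by label propagation (union-find).
oracle_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# Random integer-weighted symmetric connectome matrix.
random_weights <- function(n, p = 0.5, wmax = 20) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(stats::runif(sum(ut)) < p,
                 sample.int(wmax, sum(ut), replace = TRUE), 0)
  w[ut] <- vals
  w + t(w)
}

# Assemble a cohort object from a list of weight matrices.
make_cohort <- function(mats, group, lapse_rw = NULL, lapse_sd = NULL) {
  subjects <- lapply(mats, connectome)
  structure(
    list(subjects = subjects,
         group = factor(group, levels = c("vulnerable", "resistant")),
         subject_id = sprintf("S%03d", seq_along(mats)),
         hub_flags = NULL, template = NULL, config = NULL,
         node_metadata = NULL, lapse_rw = lapse_rw, lapse_sd = lapse_sd),
    class = "cohort"
  )
}
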