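# Extract the per-subject weight vectors of the tested edges.
# Returns list(X = n_subjects x n_edges matrix, idx = 2-col index of edges).
edge_data <- function(cohort, edge_mask) {
  n <- cohort$subjects[[1]]$n_nodes
  idx <- which(upper.tri(matrix(0, n, n)) & edge_mask, arr.ind = TRUE)
  X <- vapply(cohort$subjects, function(s) s$weights[idx],
              numeric(nrow(idx)))
  list(X = t(X), idx = idx)
}

# Union of the two group backbones: the default candidate-edge mask for NBS.
union_backbone_mask <- function(cohort, alpha = 0.05, correction = "BH") {
  bb_v <- backbone_network(cohort$subjects[cohort$group == "vulnerable"],
                           alpha = alpha, correction = correction)
  bb_r <- backbone_network(cohort$subjects[cohort$group == "resistant"],
                           alpha = alpha, correction = correction)
  (bb_v$adjacency + bb_r$adjacency) > 0
}

# Vectorised pooled two-sample t over the columns of X (group a minus b).
pooled_t_columns <- function(X, a_rows, b_rows) {
  na <- length(a_rows); nb <- length(b_rows)
  ma <- colMeans(X[a_rows, , drop = FALSE])
  mb <- colMeans(X[b_rows, , drop = FALSE])
  va <- colSums(sweep(X[a_rows, , drop = FALSE], 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(X[b_rows, , drop = FALSE], 2, mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  zero <- sp2 == 0
  tt[zero & ma == mb] <- 0
  tt[zero & ma != mb] <- Inf * sign((ma - mb)[zero & ma != mb])
  tt
}

#' Edge-wise group t statistics
#'
#' Pooled two-sample t statistic (resistant minus vulnerable) for every
#' candidate edge. Candidates default to the union of the two group sign-test
#' backbones, restricting tests to edges with reliable group-level support.
#'
#' @param cohort a `cohort` with both groups of size >= 2.
#' @param edge_mask optional logical/0-1 N x N matrix of candidate edges;
#'   `NULL` uses the union backbone.
#' @return list with `t_matrix` (N x N, `NA` on untested pairs), `df`,
#'   `edge_index` (2-column matrix), `t` (vector aligned with `edge_index`),
#'   `edge_mask`.
#' @export
edgewise_group_t <- function(cohort, edge_mask = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  a <- which(cohort$group == "resistant")
  b <- which(cohort$group == "vulnerable")
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  if (is.null(edge_mask)) edge_mask <- union_backbone_mask(cohort)
  ed <- edge_data(cohort, edge_mask)
  tt <- pooled_t_columns(ed$X, a, b)
  n <- cohort$subjects[[1]]$n_nodes
  tm <- matrix(NA_real_, n, n)
  tm[ed$idx] <- tt
  tm[ed$idx[, c(2, 1), drop = FALSE]] <- tt
  list(t_matrix = tm, df = length(a) + length(b) - 2,
       edge_index = ed$idx, t = tt, edge_mask = edge_mask)
}

#' Supra-threshold connected components
#'
#' Graph components formed by the edges whose t statistic meets the one-tailed
#' primary threshold (`t >= t_thresh`, resistant above vulnerable). Component
#' size is the edge count.
#'
#' @param t_matrix symmetric matrix of edge t statistics (`NA` = untested).
#' @param t_thresh primary threshold in t units.
#' @return list of components, each a list with `edges` (data.frame `i`, `j`,
#'   `t`), `nodes`, `n_edges`; ordered by decreasing size. Empty list if no
#'   edge survives.
#' @export
supra_threshold_components <- function(t_matrix, t_thresh) {
  n <- nrow(t_matrix)
  ut <- upper.tri(t_matrix)
  keep <- ut & !is.na(t_matrix) & t_matrix >= t_thresh
  if (!any(keep)) return(list())
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  edge_comp <- memb[idx[, 1]]
  comps <- lapply(unique(edge_comp), function(cid) {
    rows <- edge_comp == cid
    e <- data.frame(i = idx[rows, 1], j = idx[rows, 2],
                    t = t_matrix[idx[rows, , drop = FALSE]])
    list(edges = e, nodes = sort(unique(c(e$i, e$j))), n_edges = nrow(e))
  })
  comps[order(vapply(comps, `[[`, integer(1), "n_edges"), decreasing = TRUE)]
}

max_component_size <- function(t_vec, idx, t_thresh) {
  keep <- !is.na(t_vec) & t_vec >= t_thresh
  if (!any(keep)) return(0L)
  e <- idx[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[e[, 1]]))
}

#' Network-based statistic (max-component permutation test)
#'
#' Family-wise-error-controlled search for a connected subnetwork with lower
#' connectivity in the vulnerable group. Edge-wise pooled t statistics
#' (resistant minus vulnerable) are thresholded at the one-tailed primary
#' threshold; group labels are then permuted `n_perm` times, recording the
#' maximal supra-threshold component size (edge count) each time. Each
#' observed component gets the FWE p-value
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param cohort a `cohort`.
#' @param t_thresh primary threshold in t units; `NULL` derives it from
#'   `edge_p`.
#' @param edge_p one-tailed edge-wise p used to derive the default threshold
#'   (default 0.01).
#' @param n_perm number of permutations (default 5000; fewer than 100 warns).
#' @param seed integer seed for the permutation stream.
#' @param edge_mask optional candidate-edge mask (default: union backbone).
#' @return list of class `"nbs_result"`: `t_matrix`, `primary_threshold`,
#'   `components`, `component_p`, `max_component_size_null`, `observed_max`,
#'   `df`, `seed`.
#' @export
nbs_permutation <- function(cohort, t_thresh = NULL, edge_p = 0.01,
                            n_perm = 5000, seed = 1, edge_mask = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null", call. = FALSE)
  ew <- edgewise_group_t(cohort, edge_mask = edge_mask)
  if (is.null(t_thresh)) t_thresh <- stats::qt(1 - edge_p, df = ew$df)
  comps <- supra_threshold_components(ew$t_matrix, t_thresh)

  n_sub <- length(cohort$subjects)
  n_res <- sum(cohort$group == "resistant")
  ed <- edge_data(cohort, ew$edge_mask)
  set.seed(seed)
  null_sizes <- vapply(seq_len(n_perm), function(p) {
    perm <- sample.int(n_sub)
    a <- perm[seq_len(n_res)]
    b <- perm[-seq_len(n_res)]
    tt <- pooled_t_columns(ed$X, a, b)
    max_component_size(tt, ed$idx, t_thresh)
  }, integer(1))

  comp_p <- vapply(comps, function(cp) {
    (1 + sum(null_sizes >= cp$n_edges)) / (1 + n_perm)
  }, numeric(1))
  structure(
    list(t_matrix = ew$t_matrix, primary_threshold = t_thresh,
         components = comps, component_p = comp_p,
         max_component_size_null = null_sizes,
         observed_max = if (length(comps)) comps[[1]]$n_edges else 0L,
         df = ew$df, seed = seed),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs: %d component(s) at t >= %.3f", length(x$components),
              x$primary_threshold))
  if (length(x$components)) {
    cat(sprintf("; largest %d edges / %d nodes, p = %.4g",
                x$components[[1]]$n_edges, length(x$components[[1]]$nodes),
                x$component_p[1]))
  }
  cat(sprintf(", %d permutations>\n", length(x$max_component_size_null)))
  invisible(x)
}
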