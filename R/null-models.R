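#' Degree-preserving rewired null network
#'
#' Randomises topology by repeated double-edge swaps (two edges (a,b), (c,d)
#' are replaced by (a,d), (c,b) when no self-loop or multi-edge would result),
#' which preserves every node's binary degree exactly. The original edge
#' weights are then randomly permuted over the rewired edge set, so the weight
#' multiset is preserved as well. This is the "matched random network" used to
#' normalise clustering, path length and the rich-club coefficient.
#'
#' @param conn a `connectome` with at least 2 edges.
#' @param n_rewires_per_edge swap attempts per edge (default 10, a standard
#'   mixing heuristic).
#' @return a rewired `connectome` (labels/volumes/coords carried over).
#' @export
rewire_degree_preserving <- function(conn, n_rewires_per_edge = 10) {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  ut <- upper.tri(w)
  present <- which(ut & w > 0, arr.ind = TRUE)
  ne <- nrow(present)
  if (ne < 2) {
    warning("fewer than 2 edges: no legal swap exists, returning a copy",
            call. = FALSE)
    return(conn)
  }
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected",
                                           diag = FALSE)
  g2 <- igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE,
                              niter = n_rewires_per_edge * ne)
  )
  el <- igraph::as_edgelist(g2, names = FALSE)
  wt <- w[present]                 # weight multiset of the source
  wt <- wt[sample.int(ne)]         # permute weights over the new edges
  w2 <- matrix(0, nrow(w), ncol(w))
  w2[el] <- wt
  w2 <- w2 + t(w2)
  if (identical(unname(w2 > 0), unname(w > 0)) &&
      ne == choose(nrow(w), 2)) {
    warning("complete graph: topology is swap-invariant, weights permuted only",
            call. = FALSE)
  }
  out <- conn
  out$weights <- w2
  dimnames(out$weights) <- dimnames(w)
  out
}

#' Ensemble of matched random networks
#'
#' Generates `n` independent degree- and weight-matched rewired networks.
#' Member `i` is produced from a seed derived deterministically from
#' `(seed, i)`, so the ensemble is reproducible and individual members can be
#' regenerated in isolation.
#'
#' @param conn source `connectome`.
#' @param n ensemble size (the full design uses 1000).
#' @param seed integer seed.
#' @param n_rewires_per_edge swap attempts per edge per member.
#' @return object of class `"null_ensemble"`: list with `networks`, `seed`,
#'   `n_rewires_per_edge`.
#' @export
matched_ensemble <- function(conn, n = 1000, seed = 1, n_rewires_per_edge = 10) {
  stopifnot(inherits(conn, "connectome"))
  if (n < 1) stop("ensemble size must be at least 1", call. = FALSE)
  networks <- lapply(seq_len(n), function(i) {
    set.seed(as.integer((as.numeric(seed) * 10007 + i) %% 2147483647))
    rewire_degree_preserving(conn, n_rewires_per_edge)
  })
  structure(list(networks = networks, seed = seed,
                 n_rewires_per_edge = n_rewires_per_edge),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble: %d matched random networks (seed %d)>\n",
              length(x$networks), x$seed))
  invisible(x)
}
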