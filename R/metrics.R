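#' Weighted shortest-path distance matrix
#'
#' Streamline-count weights are converted to lengths by the reciprocal map
#' `l_ij = 1 / w_ij` (stronger connections are shorter), and all-pairs
#' shortest-path distances are computed on the resulting length matrix.
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param conn a `connectome` or a nonnegative symmetric weight matrix.
#' @return N x N matrix of weighted distances.
#' @export
distance_matrix <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  .fw_distances(len)
}

#' Network strength
#'
#' Mean node strength `Sp = mean_i sum_j w_ij`.
#'
#' @inheritParams distance_matrix
#' @return scalar strength.
#' @export
network_strength <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  mean(rowSums(w))
}

#' Global efficiency
#'
#' Average inverse shortest weighted path length over ordered node pairs,
#' `E_glob = 1 / (N (N - 1)) * sum_{i != j} 1 / d_ij`, with unreachable pairs
#' contributing 0.
#'
#' @inheritParams distance_matrix
#' @param d optional precomputed distance matrix (see [distance_matrix()]).
#' @return scalar efficiency.
#' @export
global_efficiency <- function(conn, d = NULL) {
  if (is.null(d)) d <- distance_matrix(conn)
  n <- nrow(d)
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' Per-node mean inverse shortest distance to every other node,
#' `E_nodal(i) = 1 / (N - 1) * sum_{j != i} 1 / d_ij`. Its mean over nodes
#' equals the global efficiency.
#'
#' @inheritParams global_efficiency
#' @return numeric vector of length N.
#' @export
nodal_efficiency <- function(conn, d = NULL) {
  if (is.null(d)) d <- distance_matrix(conn)
  n <- nrow(d)
  if (n < 2) stop("nodal efficiency needs at least 2 nodes", call. = FALSE)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph (the node itself excluded, original weights retained); nodes with
#' fewer than two neighbours contribute 0.
#'
#' @inheritParams distance_matrix
#' @return scalar efficiency.
#' @export
local_efficiency <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  .local_efficiency_cpp(w)
}

#' Characteristic path length
#'
#' Mean shortest weighted distance over ordered node pairs. Networks in this
#' design are connected; if some pairs are unreachable the mean is taken over
#' the finite pairs with a warning (configurable to an error).
#'
#' @inheritParams global_efficiency
#' @param on_disconnect `"warn"` (default) averages finite pairs with a
#'   warning; `"error"` aborts; `"ignore"` averages finite pairs silently.
#' @return scalar path length (weighted-length units).
#' @export
characteristic_path_length <- function(conn, d = NULL,
                                       on_disconnect = c("warn", "error", "ignore")) {
  on_disconnect <- match.arg(on_disconnect)
  if (is.null(d)) d <- distance_matrix(conn)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) stop("no finite path between any pair of nodes", call. = FALSE)
  if (!all(finite)) {
    if (on_disconnect == "error") {
      stop("network is disconnected: ", sum(!finite), " unreachable pairs",
           call. = FALSE)
    }
    if (on_disconnect == "warn") {
      warning(sum(!finite), " unreachable pairs excluded from path length",
              call. = FALSE)
    }
  }
  mean(off[finite])
}

#' Weighted clustering coefficient
#'
#' Onnela's geometric-mean form: with weights normalised by the network
#' maximum, `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)`,
#' bounded in \[0, 1\]; nodes with degree < 2 get 0. `Cp` is the mean over all
#' nodes.
#'
#' @inheritParams distance_matrix
#' @return list with `cp` (mean) and `nodal` (per-node values).
#' @export
clustering_coefficient <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  n <- nrow(w)
  k <- rowSums(w > 0)
  mx <- max(w)
  if (mx == 0) return(list(cp = 0, nodal = rep(0, n)))
  m <- (w / mx)^(1 / 3)
  tri <- diag(m %*% m %*% m)          # sum over ordered (j, h) triangle terms
  nodal <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  list(cp = mean(nodal), nodal = as.numeric(nodal))
}

#' Binary degree distribution and skewness
#'
#' Degrees are counted on the nonzero (thresholded) edges. A right-skewed
#' distribution (positive sample skewness) indicates a minority of highly
#' connected hub regions.
#'
#' @inheritParams distance_matrix
#' @return list with `degree` (per-node), `histogram` (table) and `skewness`
#'   (bias-corrected sample skewness; `NA` for constant degrees).
#' @export
degree_distribution <- function(conn) {
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  k <- rowSums(w > 0)
  list(degree = k, histogram = table(k), skewness = sample_skewness(k))
}

sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - mean(x))^3) / (mean((x - mean(x))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Small-world coefficients
#'
#' Normalises the clustering coefficient and characteristic path length
#' against an ensemble of matched random networks with the same size and
#' degree sequence: `gamma = Cp / mean(Cp_rand)`,
#' `lambda = Lp / mean(Lp_rand)`. `gamma > 1` with `lambda ~ 1` is the
#' small-world regime.
#'
#' @param conn a `connectome`.
#' @param ensemble a [matched_ensemble()] or a list of null `connectome`s.
#' @return list with `gamma`, `lambda`, `cp`, `lp`, `cp_rand`, `lp_rand`.
#' @export
small_world_metrics <- function(conn, ensemble) {
  nulls <- if (inherits(ensemble, "null_ensemble")) ensemble$networks else ensemble
  if (length(nulls) == 0) stop("null ensemble is empty", call. = FALSE)
  cp <- clustering_coefficient(conn)$cp
  lp <- characteristic_path_length(conn, on_disconnect = "ignore")
  cp_rand <- vapply(nulls, function(g) clustering_coefficient(g)$cp, numeric(1))
  lp_rand <- vapply(nulls, function(g) {
    characteristic_path_length(g, on_disconnect = "ignore")
  }, numeric(1))
  mc <- mean(cp_rand)
  ml <- mean(lp_rand)
  if (mc == 0) stop("mean null clustering is 0; gamma undefined", call. = FALSE)
  if (ml == 0) stop("mean null path length is 0; lambda undefined", call. = FALSE)
  list(gamma = cp / mc, lambda = lp / ml, cp = cp, lp = lp,
       cp_rand = mean(cp_rand), lp_rand = mean(lp_rand))
}

#' All global metrics for one subject
#'
#' Convenience wrapper computing strength, global/local efficiency,
#' characteristic path length and clustering in one pass over the distance
#' matrix. `gamma`/`lambda` require a null ensemble and are `NA` unless one is
#' supplied.
#'
#' @inheritParams small_world_metrics
#' @param ensemble optional null ensemble for `gamma`/`lambda`.
#' @return one-row data.frame with columns `Sp`, `Eglob`, `Eloc`, `Lp`, `Cp`,
#'   `gamma`, `lambda`.
#' @export
global_metrics <- function(conn, ensemble = NULL) {
  d <- distance_matrix(conn)
  out <- data.frame(
    Sp = network_strength(conn),
    Eglob = global_efficiency(conn, d = d),
    Eloc = local_efficiency(conn),
    Lp = characteristic_path_length(conn, d = d, on_disconnect = "ignore"),
    Cp = clustering_coefficient(conn)$cp,
    gamma = NA_real_, lambda = NA_real_
  )
  if (!is.null(ensemble)) {
    sw <- small_world_metrics(conn, ensemble)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
  }
  out
}
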