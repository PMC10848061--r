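#' Weighted structural connectome
#'
#' A connectome is one subject's whole-brain white-matter network: nodes are
#' parcellated grey-matter regions, edges carry nonnegative weights (streamline
#' counts before region-volume correction, reals after). The weight matrix
#' must be symmetric with a zero diagonal.
#'
#' @param weights N x N numeric matrix of nonnegative edge weights.
#' @param labels optional character vector of region labels (default
#'   `"R001"..."RNNN"`).
#' @param volumes optional positive region volumes (mm^3), used by
#'   [roi_volume_correction()].
#' @param coords optional N x 3 matrix of region coordinates (MNI mm), used by
#'   the BrainNet Viewer export.
#' @param symmetrize_tol relative tolerance below which a slightly asymmetric
#'   input is symmetrized by averaging; asymmetry above it is an error.
#'
#' @return An object of class `"connectome"`: a list with elements `weights`,
#'   `labels`, `volumes`, `coords`, `n_nodes`.
#' @export
connectome <- function(weights, labels = NULL, volumes = NULL, coords = NULL,
                       symmetrize_tol = 1e-6) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be a square matrix, got ",
         nrow(weights), " x ", ncol(weights), call. = FALSE)
  }
  if (!is.numeric(weights)) stop("weights must be numeric", call. = FALSE)
  if (anyNA(weights)) stop("weights contain missing values", call. = FALSE)
  if (any(weights < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  n <- nrow(weights)

  asym <- max(abs(weights - t(weights)))
  scale <- max(abs(weights), 1)
  if (asym > symmetrize_tol * scale) {
    stop("weight matrix is asymmetric beyond tolerance (max |w_ij - w_ji| = ",
         format(asym), ")", call. = FALSE)
  }
  if (asym > 0) weights <- (weights + t(weights)) / 2

  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal forced to 0", call. = FALSE)
    diag(weights) <- 0
  }

  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n))
  if (length(labels) != n) stop("labels length must equal n_nodes", call. = FALSE)
  if (!is.null(volumes)) {
    if (length(volumes) != n) stop("volumes length must equal n_nodes", call. = FALSE)
    if (any(!is.finite(volumes)) || any(volumes <= 0)) {
      stop("volumes must be positive and finite", call. = FALSE)
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3) {
      stop("coords must be an N x 3 matrix", call. = FALSE)
    }
  }
  dimnames(weights) <- list(labels, labels)
  structure(
    list(weights = weights, labels = labels, volumes = volumes,
         coords = coords, n_nodes = n),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome: %d nodes, %d edges, total weight %.6g>\n",
              x$n_nodes, ne, sum(x$weights) / 2))
  invisible(x)
}

#' @export
as.matrix.connectome <- function(x, ...) x$weights

n_edges <- function(conn) sum(conn$weights[upper.tri(conn$weights)] > 0)

#' Read a connectivity matrix from a plain-text file
#'
#' Reads an N x N numeric table (whitespace- or comma-delimited; the dialect
#' is auto-detected from the first line) and validates it as a [connectome()].
#' An optional node metadata table supplies labels, coordinates and volumes.
#'
#' @param path path to the matrix file.
#' @param metadata_path optional node metadata TSV with header
#'   `label  x  y  z  volume` (see [read_node_metadata()]).
#' @return A `connectome`.
#' @export
read_connectome <- function(path, metadata_path = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   strip.white = TRUE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  meta <- if (!is.null(metadata_path)) read_node_metadata(metadata_path)
  connectome(
    m,
    labels  = if (!is.null(meta)) meta$label,
    volumes = if (!is.null(meta)) meta$volume,
    coords  = if (!is.null(meta)) as.matrix(meta[, c("x", "y", "z")])
  )
}

#' Write a connectivity matrix to a plain-text file
#'
#' Serializes the weight matrix whitespace-delimited with 12 significant
#' digits, so that `read_connectome(write_connectome(x))` is the identity on
#' valid input.
#'
#' @param conn a `connectome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "connectome"))
  lines <- apply(conn$weights, 1L, function(r) {
    paste(format(r, digits = 12, scientific = FALSE, trim = TRUE),
          collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a node metadata table
#'
#' @param path TSV with header `label  x  y  z  volume`.
#' @return data.frame with those columns.
#' @export
read_node_metadata <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "volume")
  if (!all(need %in% names(meta))) {
    stop("node metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  meta
}

#' Write node metadata
#' @param meta data.frame with columns label, x, y, z, volume.
#' @param path output TSV path.
#' @export
write_node_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export BrainNet Viewer .node / .edge files
#'
#' The `.node` file has one line per region (x, y, z, color, size, label);
#' the `.edge` file is the weight matrix, tab-delimited. Node size defaults to
#' the node strength.
#'
#' @param conn a `connectome` with coordinates present.
#' @param prefix output path prefix; writes `<prefix>.node` and `<prefix>.edge`.
#' @param node_size per-node sizes (default: node strength).
#' @param node_color per-node color codes (default 1).
#' @return character vector of the two paths, invisibly.
#' @export
write_brainnet <- function(conn, prefix, node_size = NULL, node_color = NULL) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$coords)) {
    stop("node coordinates are required for .node export", call. = FALSE)
  }
  if (is.null(node_size)) node_size <- rowSums(conn$weights)
  if (is.null(node_color)) node_color <- rep(1, conn$n_nodes)
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  node <- data.frame(conn$coords[, 1], conn$coords[, 2], conn$coords[, 3],
                     node_color, node_size, conn$labels)
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(conn$weights, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Threshold edges by fiber count
#'
#' Low streamline counts are dominated by tractography false positives; edges
#' with fewer than `t` streamlines are removed (set to 0). The rule is
#' inclusive: an edge with exactly `t` streamlines survives, and `t = 0` keeps
#' every strictly positive edge, so applying the same threshold twice equals
#' applying it once.
#'
#' @param conn a `connectome` (raw streamline counts).
#' @param t nonnegative threshold; the study design sweeps 0, 10, 50, 100.
#' @return thresholded `connectome`.
#' @export
apply_fiber_threshold <- function(conn, t) {
  stopifnot(inherits(conn, "connectome"))
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("threshold must be a single nonnegative number", call. = FALSE)
  }
  w <- conn$weights
  w[w < t] <- 0
  conn$weights <- w
  conn
}

#' Correct edge weights for region volume
#'
#' Larger regions accumulate more streamlines purely by size; dividing each
#' fiber count by the mean volume of the two connected regions,
#' `w'_ij = w_ij / ((v_i + v_j) / 2)`, removes that bias. Applied after
#' fiber-count thresholding (the threshold targets raw counts).
#'
#' @param conn a `connectome` with positive `volumes`.
#' @return corrected `connectome` (real-valued weights).
#' @export
roi_volume_correction <- function(conn) {
  stopifnot(inherits(conn, "connectome"))
  if (is.null(conn$volumes)) {
    stop("node volumes are required for ROI volume correction", call. = FALSE)
  }
  v <- conn$volumes
  denom <- outer(v, v, `+`) / 2
  conn$weights <- conn$weights / denom
  diag(conn$weights) <- 0
  conn
}
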