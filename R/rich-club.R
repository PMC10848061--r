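#' Group backbone network
#'
#' Edges that are reliably present across the subjects of a group. For each
#' node pair a one-tailed sign test against a zero median is applied: with
#' zeros dropped, all `m` subjects with a positive weight lie above zero, so
#' the exact tail probability is `p = 0.5^m`. The p-values are corrected
#' across all N(N-1)/2 candidate pairs and an edge is retained when the
#' corrected p-value is below `alpha`.
#'
#' @param group_connectomes list of `connectome`s from one group (>= 2).
#' @param alpha significance level (default 0.05).
#' @param correction `"BH"` (Benjamini-Hochberg FDR, default), `"bonferroni"`,
#'   or `"none"`.
#' @return object of class `"backbone"`: list with `adjacency` (0/1 matrix),
#'   `p_values`, `p_adjusted`, `degree`, `n_subjects`.
#' @export
backbone_network <- function(group_connectomes, alpha = 0.05,
                             correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (length(group_connectomes) < 2) {
    stop("backbone requires at least 2 subjects", call. = FALSE)
  }
  n <- group_connectomes[[1]]$n_nodes
  counts <- Reduce(`+`, lapply(group_connectomes, function(s) {
    if (s$n_nodes != n) stop("inconsistent matrix sizes", call. = FALSE)
    (s$weights > 0) * 1L
  }))
  ut <- upper.tri(counts)
  p <- matrix(1, n, n)
  p[ut] <- 0.5^counts[ut]
  padj <- matrix(1, n, n)
  padj[ut] <- switch(correction,
    BH = stats::p.adjust(p[ut], method = "BH"),
    bonferroni = stats::p.adjust(p[ut], method = "bonferroni"),
    none = p[ut]
  )
  adj <- matrix(0L, n, n)
  adj[ut] <- as.integer(padj[ut] < alpha)
  adj <- adj + t(adj)
  p <- pmin(p, t(p))
  padj <- pmin(padj, t(padj))
  diag(p) <- diag(padj) <- 1
  labels <- group_connectomes[[1]]$labels
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, p_values = p, p_adjusted = padj,
                 degree = rowSums(adj), n_subjects = length(group_connectomes)),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone: %d nodes, %d edges retained from %d subjects>\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$n_subjects))
  invisible(x)
}

#' Identify rich-club hub regions
#'
#' Hubs are the nodes whose backbone degree is at least one sample standard
#' deviation above the mean backbone degree, `k_i >= mean(k) + sd(k)`. When
#' every node has the same degree (sd = 0) the literal rule admits all nodes;
#' this degenerate case is flagged with a warning. An empty graph yields an
#' empty hub set.
#'
#' @param backbone a [backbone_network()] result, a `connectome`, or a 0/1
#'   adjacency matrix.
#' @return integer vector of hub node indices.
#' @export
identify_hubs <- function(backbone) {
  k <- if (inherits(backbone, "backbone")) {
    backbone$degree
  } else if (inherits(backbone, "connectome")) {
    rowSums(backbone$weights > 0)
  } else {
    rowSums(as.matrix(backbone) > 0)
  }
  if (all(k == 0)) return(integer(0))
  s <- stats::sd(k)
  if (s == 0) {
    warning("degenerate degree sequence (sd = 0): every node meets the hub rule",
            call. = FALSE)
  }
  as.integer(which(k >= mean(k) + s))
}

#' Classify edges as rich, feeder, or local
#'
#' Present edges are partitioned by the hub membership of their endpoints:
#' rich (hub-hub), feeder (hub-peripheral), local (peripheral-peripheral).
#'
#' @param conn a `connectome`.
#' @param hub_set integer vector of hub node indices.
#' @return character N x N matrix with entries `"rich"`, `"feeder"`,
#'   `"local"`, or `"absent"` (absent edges and the diagonal).
#' @export
classify_edges <- function(conn, hub_set) {
  stopifnot(inherits(conn, "connectome"))
  n <- conn$n_nodes
  if (length(hub_set) && (any(hub_set < 1) || any(hub_set > n))) {
    stop("hub indices out of range", call. = FALSE)
  }
  is_hub <- seq_len(n) %in% hub_set
  nh <- outer(is_hub, is_hub, `+`)   # number of hub endpoints per pair
  cls <- matrix("absent", n, n)
  present <- conn$weights > 0
  cls[present & nh == 2] <- "rich"
  cls[present & nh == 1] <- "feeder"
  cls[present & nh == 0] <- "local"
  diag(cls) <- "absent"
  dimnames(cls) <- dimnames(conn$weights)
  cls
}

#' Connection strength by edge class
#'
#' Sums the edge weights within each class and forms the rich/feeder and
#' rich/local strength ratios. A ratio with a zero denominator is returned as
#' `NA` with `ratio_defined = FALSE`.
#'
#' @param conn a `connectome`.
#' @param edge_class matrix from [classify_edges()], or a hub set (a numeric
#'   vector), in which case classes are computed internally.
#' @return list with `strength_rich`, `strength_feeder`, `strength_local`,
#'   `ratio_rich_feeder`, `ratio_rich_local`, `ratio_defined` (logical pair).
#' @export
connection_strengths <- function(conn, edge_class) {
  stopifnot(inherits(conn, "connectome"))
  if (is.numeric(edge_class)) edge_class <- classify_edges(conn, edge_class)
  ut <- upper.tri(conn$weights)
  w <- conn$weights
  s_rich <- sum(w[ut & edge_class == "rich"])
  s_feed <- sum(w[ut & edge_class == "feeder"])
  s_loc <- sum(w[ut & edge_class == "local"])
  rf <- if (s_feed > 0) s_rich / s_feed else NA_real_
  rl <- if (s_loc > 0) s_rich / s_loc else NA_real_
  list(strength_rich = s_rich, strength_feeder = s_feed,
       strength_local = s_loc,
       ratio_rich_feeder = rf, ratio_rich_local = rl,
       ratio_defined = c(rich_feeder = s_feed > 0, rich_local = s_loc > 0))
}

#' Weighted rich-club coefficient
#'
#' With `n` the number of edges among the hub set, phi is the sum of those
#' hub-hub weights divided by the sum of the `n` strongest edge weights in the
#' whole network (hub-hub edges included in the candidate pool). phi is in
#' (0, 1]; it is undefined (`NA` with a warning suppressed to a flag) when no
#' hub-hub edge exists.
#'
#' @param conn a `connectome`.
#' @param hub_set integer vector of hub node indices.
#' @return list with `phi`, `n_rich_edges`, `defined`.
#' @export
weighted_rich_club_coefficient <- function(conn, hub_set) {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  ut <- upper.tri(w)
  is_hub <- seq_len(conn$n_nodes) %in% hub_set
  hub_pair <- outer(is_hub, is_hub, `&`)
  rich_w <- w[ut & hub_pair & w > 0]
  n_rich <- length(rich_w)
  if (n_rich == 0) {
    return(list(phi = NA_real_, n_rich_edges = 0L, defined = FALSE))
  }
  all_w <- sort(w[ut & w > 0], decreasing = TRUE)
  phi <- sum(rich_w) / sum(all_w[seq_len(n_rich)])
  list(phi = phi, n_rich_edges = n_rich, defined = TRUE)
}

#' Normalised rich-club coefficient
#'
#' Ratio of the observed phi to the mean phi of matched random networks with
#' the same degree sequence and weight multiset. Values above 1 indicate
#' rich-club organisation beyond what degree alone explains. Ensemble members
#' whose rewired topology has no hub-hub edge are skipped and counted.
#'
#' @param conn a `connectome`.
#' @param hub_set integer vector of hub node indices.
#' @param ensemble a [matched_ensemble()] or list of null `connectome`s.
#' @return list with `phi_norm`, `phi`, `phi_rand_mean`, `n_null_used`,
#'   `n_null_undefined`.
#' @export
normalized_rich_club <- function(conn, hub_set, ensemble) {
  nulls <- if (inherits(ensemble, "null_ensemble")) ensemble$networks else ensemble
  obs <- weighted_rich_club_coefficient(conn, hub_set)
  if (!obs$defined) {
    stop("observed rich-club coefficient undefined: no hub-hub edges",
         call. = FALSE)
  }
  phi_rand <- vapply(nulls, function(g) {
    weighted_rich_club_coefficient(g, hub_set)$phi
  }, numeric(1))
  ok <- !is.na(phi_rand)
  if (!any(ok)) {
    stop("rich-club coefficient undefined in every null network", call. = FALSE)
  }
  list(phi_norm = obs$phi / mean(phi_rand[ok]), phi = obs$phi,
       phi_rand_mean = mean(phi_rand[ok]),
       n_null_used = sum(ok), n_null_undefined = sum(!ok))
}
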