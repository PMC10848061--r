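#' Configuration for a synthetic connectome cohort
#'
#' Defines the generative model for a two-group (vulnerable / resistant)
#' cohort of weighted structural connectomes with a planted rich-club group
#' difference and linked psychomotor-vigilance lapse counts. Topology is a
#' planted-hub stochastic block model: a small set of hub regions is densely
#' interconnected (the rich club), hubs connect to the periphery at an
#' intermediate rate, and peripheral pairs connect sparsely. Edge weights are
#' integer streamline counts: a shared log-normal baseline per edge times
#' per-subject multiplicative log-normal noise, rounded. Vulnerable subjects
#' have their hub-hub weights attenuated by `delta_rich` before rounding.
#'
#' @param n_nodes number of regions (default 90, an AAL-style parcellation).
#' @param n_hubs number of planted hub regions (default 12).
#' @param p_hub_hub,p_hub_periph,p_periph_periph block edge probabilities;
#'   must satisfy `p_hub_hub > p_hub_periph > p_periph_periph`. Defaults
#'   (0.9, 0.2, 0.08) give a connection density near 0.12 and a right-skewed
#'   degree distribution, both typical of fiber-count networks thresholded at
#'   10 streamlines.
#' @param weight_log_mean,weight_log_sd log-normal parameters of the baseline
#'   streamline counts (defaults log(30) and 0.9: median 30 fibers, heavy
#'   right tail into the hundreds).
#' @param weight_hub_factor multiplicative enrichment of hub-hub baseline
#'   weights (default 3). Rich-club edges in structural brain networks carry
#'   the strongest connections; without this coupling between topology and
#'   weight, a degree- and weight-matched null reproduces the observed
#'   rich-club coefficient and phi_norm sits at 1.
#' @param locality_scale index-distance decay scale of peripheral
#'   connectivity (default 8). Peripheral pairs connect with probability
#'   proportional to `exp(-|i - j| / locality_scale)`, rescaled so the mean
#'   equals `p_periph_periph`; this emulates the distance-dependent
#'   connection probability of cortical networks and produces clustering
#'   above degree-matched random networks (the small-world regime). `Inf`
#'   gives a uniform periphery.
#' @param subject_noise_sd per-subject multiplicative log-scale noise SD
#'   (default 0.25).
#' @param delta_rich attenuation in (0, 1] applied to vulnerable subjects'
#'   hub-hub weights (default 0.6; 1 means no group difference).
#' @param n_vulnerable,n_resistant group sizes (defaults 25 and 24).
#' @param lapse_mean_vulnerable,lapse_mean_resistant expected post-deprivation
#'   lapse counts per group (defaults 9.56 and 0.54, the two-group design's
#'   separation).
#' @param lapse_rw_mean expected lapse count at rested wakefulness, identical
#'   for both groups (default 1).
#' @param lapse_dispersion negative-binomial size parameter (default 3;
#'   `Inf` gives the Poisson limit).
#' @param behavior_link_slope log-scale coefficient linking a subject's
#'   standardised rich-club strength to expected lapses (default -0.5;
#'   negative values make weak rich clubs lapse-prone).
#' @param seed integer RNG seed.
#' @return validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_nodes = 90, n_hubs = 12,
                          p_hub_hub = 0.9, p_hub_periph = 0.2,
                          p_periph_periph = 0.08,
                          weight_log_mean = log(30), weight_log_sd = 0.9,
                          weight_hub_factor = 3,
                          locality_scale = 8,
                          subject_noise_sd = 0.25,
                          delta_rich = 0.6,
                          n_vulnerable = 25, n_resistant = 24,
                          lapse_mean_vulnerable = 9.56,
                          lapse_mean_resistant = 0.54,
                          lapse_rw_mean = 1,
                          lapse_dispersion = 3,
                          behavior_link_slope = -0.5,
                          seed = 1) {
  cfg <- as.list(environment())
  if (n_hubs >= n_nodes) stop("n_hubs must be smaller than n_nodes", call. = FALSE)
  probs <- c(p_hub_hub, p_hub_periph, p_periph_periph)
  if (any(probs < 0 | probs > 1)) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!(p_hub_hub > p_hub_periph && p_hub_periph > p_periph_periph) &&
      !all(probs == 0) && !all(probs == 1)) {
    if (!(p_hub_hub >= p_hub_periph && p_hub_periph >= p_periph_periph)) {
      stop("need p_hub_hub >= p_hub_periph >= p_periph_periph", call. = FALSE)
    }
  }
  if (delta_rich <= 0 || delta_rich > 1) {
    stop("delta_rich must lie in (0, 1]", call. = FALSE)
  }
  if (n_vulnerable < 0 || n_resistant < 0) {
    stop("group sizes must be nonnegative", call. = FALSE)
  }
  if (subject_noise_sd < 0 || weight_log_sd < 0) {
    stop("noise SDs must be nonnegative", call. = FALSE)
  }
  if (lapse_dispersion <= 0) stop("lapse_dispersion must be positive", call. = FALSE)
  if (weight_hub_factor <= 0) {
    stop("weight_hub_factor must be positive", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Planted-hub template topology
#'
#' Samples the binary stochastic-block topology shared by all subjects of a
#' cohort: hub-hub, hub-periphery and periphery-periphery pairs are connected
#' independently with the configured probabilities. If the sampled graph is
#' disconnected, components are joined by random bridging edges (the metrics
#' downstream assume finite path lengths). Hub nodes end up with
#' stochastically higher degree, giving the right-skewed degree distribution
#' characteristic of structural brain networks.
#'
#' @param config a [cohort_config()].
#' @return list of class `"binary_topology"`: `adjacency` (0/1, symmetric,
#'   zero diagonal) and `hub_flags` (logical).
#' @export
generate_template_topology <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  hub <- seq_len(n) <= config$n_hubs
  nh <- outer(hub, hub, `+`)
  pmat <- matrix(config$p_periph_periph, n, n)
  if (is.finite(config$locality_scale) && config$p_periph_periph > 0 &&
      config$p_periph_periph < 1) {
    # distance-dependent periphery: same mean density, local concentration
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    decay <- exp(-d / config$locality_scale)
    pp <- nh == 0 & upper.tri(pmat)
    pmat[nh == 0] <- pmin(1, config$p_periph_periph *
                            exp(-d[nh == 0] / config$locality_scale) /
                            mean(decay[pp]))
  }
  pmat[nh == 1] <- config$p_hub_periph
  pmat[nh == 2] <- config$p_hub_hub
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- as.integer(stats::runif(sum(ut)) < pmat[ut])
  adj <- adj + t(adj)
  adj <- connect_components(adj)
  structure(list(adjacency = adj, hub_flags = hub), class = "binary_topology")
}

# Join disconnected components with random bridging edges.
connect_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    giant <- which.max(comp$csize)
    other <- which(comp$membership != giant)
    a <- other[sample.int(length(other), 1)]
    inside <- which(comp$membership == giant)
    b <- inside[sample.int(length(inside), 1)]
    adj[a, b] <- adj[b, a] <- 1L
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
  }
  adj
}

# Deterministic synthetic region metadata (MNI-style coordinates, volumes).
synthetic_node_metadata <- function(config) {
  set.seed(subject_seed(config$seed, 999983L))
  n <- config$n_nodes
  data.frame(
    label = sprintf("R%03d", seq_len(n)),
    x = round(stats::runif(n, -70, 70), 1),
    y = round(stats::runif(n, -100, 70), 1),
    z = round(stats::runif(n, -60, 80), 1),
    volume = round(stats::rlnorm(n, log(8000), 0.4), 1)
  )
}

#' Generate a synthetic two-group connectome cohort
#'
#' Draws the template topology, a shared log-normal baseline weight per edge,
#' and per-subject integer weight matrices
#' `w = round(template * baseline * exp(noise))`, with vulnerable subjects'
#' hub-hub weights multiplied by `delta_rich` before rounding. One RNG stream
#' is derived per subject from `(seed, subject index)`, so each subject's
#' network is reproducible independently of the group sizes.
#'
#' @param config a [cohort_config()].
#' @return object of class `"cohort"`: list with `subjects` (list of
#'   [connectome()]s), `group` (factor vulnerable/resistant), `subject_id`,
#'   `hub_flags` (planted truth), `template`, `config`, and (after
#'   [generate_lapse_scores()]) `lapse_rw`, `lapse_sd`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_sub <- config$n_vulnerable + config$n_resistant
  if (n_sub == 0) stop("empty cohort: both group sizes are 0", call. = FALSE)
  topo <- generate_template_topology(config)
  n <- config$n_nodes
  ut <- upper.tri(topo$adjacency)

  set.seed(subject_seed(config$seed, 0L))
  base <- matrix(0, n, n)
  base[ut] <- stats::rlnorm(sum(ut), config$weight_log_mean,
                            config$weight_log_sd)
  base <- (base + t(base)) * topo$adjacency   # baseline on template edges

  hub_pair <- outer(topo$hub_flags, topo$hub_flags, `&`)
  base[hub_pair] <- base[hub_pair] * config$weight_hub_factor
  group <- factor(rep(c("vulnerable", "resistant"),
                      c(config$n_vulnerable, config$n_resistant)),
                  levels = c("vulnerable", "resistant"))
  meta <- synthetic_node_metadata(config)

  subjects <- lapply(seq_len(n_sub), function(i) {
    set.seed(subject_seed(config$seed, i))
    noise <- matrix(0, n, n)
    noise[ut] <- stats::rnorm(sum(ut), 0, config$subject_noise_sd)
    noise <- noise + t(noise)
    w <- base * exp(noise)
    if (group[i] == "vulnerable") {
      w[hub_pair] <- w[hub_pair] * config$delta_rich
    }
    w <- round(w)
    connectome(w, labels = meta$label, volumes = meta$volume,
               coords = as.matrix(meta[, c("x", "y", "z")]))
  })

  structure(
    list(subjects = subjects, group = group,
         subject_id = sprintf("S%03d", seq_len(n_sub)),
         hub_flags = topo$hub_flags, template = topo, config = config,
         node_metadata = meta, lapse_rw = NULL, lapse_sd = NULL),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d subjects (%d vulnerable / %d resistant), %d nodes>\n",
              length(x$subjects), sum(x$group == "vulnerable"),
              sum(x$group == "resistant"), x$config$n_nodes))
  invisible(x)
}

# Sum of hub-hub edge weights for one subject, given planted hub flags.
rich_club_strength_planted <- function(conn, hub_flags) {
  hub_pair <- outer(hub_flags, hub_flags, `&`)
  sum(conn$weights[hub_pair & upper.tri(conn$weights)])
}

#' Attach behavioural lapse scores to a cohort
#'
#' Draws per-subject psychomotor-vigilance lapse counts. Rested-wakefulness
#' counts are negative binomial at a common low baseline. Post-deprivation
#' counts are negative binomial with log-mean equal to the group baseline plus
#' `behavior_link_slope` times the subject's within-group standardised
#' rich-club strength (a mean-preserving log-normal adjustment, so group
#' means stay at their configured baselines), so a negative slope makes
#' subjects with weak rich-club connectivity lapse more — a negative
#' population Spearman correlation between rich-club strength and lapses.
#' With zero strength variance across subjects, the z-scores fall back to 0
#' and counts are drawn at the group baselines.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config the same [cohort_config()].
#' @return the cohort with `lapse_rw` and `lapse_sd` filled in.
#' @export
generate_lapse_scores <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort$subjects) == 0) {
    stop("cohort has no connectomes", call. = FALSE)
  }
  strength <- vapply(cohort$subjects, rich_club_strength_planted,
                     numeric(1), hub_flags = cohort$hub_flags)
  z <- rep(0, length(strength))
  for (g in levels(cohort$group)) {
    rows <- cohort$group == g
    s <- stats::sd(strength[rows])
    if (sum(rows) > 1 && !is.na(s) && s > 0) {
      z[rows] <- (strength[rows] - mean(strength[rows])) / s
    }
  }
  baseline <- ifelse(cohort$group == "vulnerable",
                     config$lapse_mean_vulnerable,
                     config$lapse_mean_resistant)
  slope <- config$behavior_link_slope
  mu_sd <- baseline * exp(slope * z - slope^2 / 2)  # mean-preserving link
  size <- config$lapse_dispersion

  draw_nb <- function(mu, seed_idx) {
    set.seed(subject_seed(config$seed, 500000L + seed_idx))
    if (is.infinite(size)) stats::rpois(1, mu) else
      stats::rnbinom(1, size = size, mu = mu)
  }
  n_sub <- length(cohort$subjects)
  cohort$lapse_rw <- vapply(seq_len(n_sub), function(i) {
    draw_nb(config$lapse_rw_mean, i)
  }, numeric(1))
  cohort$lapse_sd <- vapply(seq_len(n_sub), function(i) {
    draw_nb(mu_sd[i], 100000L + i)
  }, numeric(1))
  cohort
}

#' Write a cohort to disk
#'
#' Per-subject whitespace-delimited N x N matrices, a cohort manifest TSV
#' (`subject_id`, `group`, `lapse_rw`, `lapse_sd`, `file`), and a node
#' metadata TSV (`label`, `x`, `y`, `z`, `volume`).
#'
#' @param cohort a `cohort` (scores optional).
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.txt", cohort$subject_id)
  for (i in seq_along(cohort$subjects)) {
    write_connectome(cohort$subjects[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    subject_id = cohort$subject_id,
    group = as.character(cohort$group),
    lapse_rw = if (is.null(cohort$lapse_rw)) NA else cohort$lapse_rw,
    lapse_sd = if (is.null(cohort$lapse_sd)) NA else cohort$lapse_sd,
    file = files
  )
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_node_metadata(cohort$node_metadata, file.path(dir, "nodes.tsv"))
  invisible(manifest_path)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]: reads the manifest, node metadata and every
#' subject matrix. The planted hub flags are not recoverable from disk;
#' downstream hub identification uses the group backbone as in the analysis
#' proper.
#'
#' @param dir directory containing `manifest.tsv`, `nodes.tsv` and matrices.
#' @return a `cohort` (with `hub_flags = NULL`, `config = NULL`).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  meta_path <- file.path(dir, "nodes.tsv")
  subjects <- lapply(manifest$file, function(f) {
    read_connectome(file.path(dir, f), metadata_path = meta_path)
  })
  sizes <- vapply(subjects, function(s) s$n_nodes, integer(1))
  if (length(unique(sizes)) > 1) {
    stop("inconsistent matrix sizes across subjects", call. = FALSE)
  }
  structure(
    list(subjects = subjects,
         group = factor(manifest$group,
                        levels = c("vulnerable", "resistant")),
         subject_id = manifest$subject_id,
         hub_flags = NULL, template = NULL, config = NULL,
         node_metadata = read_node_metadata(meta_path),
         lapse_rw = manifest$lapse_rw, lapse_sd = manifest$lapse_sd),
    class = "cohort"
  )
}
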