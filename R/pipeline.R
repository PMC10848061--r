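#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis. Input is either a
#' synthetic [cohort_config()] or a directory of matrices with a manifest
#' (see [read_cohort()]).
#'
#' @param cohort_config a [cohort_config()] for synthetic input, or `NULL`.
#' @param input_dir directory for on-disk input, or `NULL`.
#' @param fiber_threshold minimum streamline count per edge (default 10).
#' @param roi_correction divide weights by mean region volume (default FALSE).
#' @param n_null matched random networks per subject for phi_norm and
#'   gamma/lambda (default 1000; 0 skips normalisation).
#' @param nbs_edge_p one-tailed edge-wise p defining the NBS primary
#'   threshold (default 0.01).
#' @param nbs_t_thresh explicit primary threshold overriding `nbs_edge_p`.
#' @param n_perm NBS permutations (default 5000).
#' @param alpha significance level for backbones and reports (default 0.05).
#' @param correction backbone multiple-comparison correction (default "BH").
#' @param do_nbs,do_nodal,do_rich_club stage switches (all TRUE).
#' @param seed integer seed governing every stochastic stage.
#' @param out_dir optional output directory for TSV/JSON reports.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(cohort_config = NULL, input_dir = NULL,
                            fiber_threshold = 10, roi_correction = FALSE,
                            n_null = 1000, nbs_edge_p = 0.01,
                            nbs_t_thresh = NULL, n_perm = 5000,
                            alpha = 0.05, correction = "BH",
                            do_nbs = TRUE, do_nodal = TRUE,
                            do_rich_club = TRUE,
                            seed = 1, out_dir = NULL) {
  if (is.null(cohort_config) && is.null(input_dir)) {
    stop("provide either cohort_config (synthetic) or input_dir", call. = FALSE)
  }
  if (fiber_threshold < 0 || n_null < 0 || n_perm < 0) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from a flat key-value YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; keys under
#' `cohort_config:` are passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cohort_config)) {
    raw$cohort_config <- do.call(cohort_config, raw$cohort_config)
  }
  do.call(analysis_config, raw)
}

#' Classify subjects as vulnerable or resistant
#'
#' The behavioural split underlying the two-group design: subjects whose
#' lapse count rises most after total sleep deprivation are vulnerable. The
#' default is a median split on the change `lapse_sd - lapse_rw`; a fixed
#' cutoff on the change is available.
#'
#' @param lapse_rw lapse counts at rested wakefulness.
#' @param lapse_sd lapse counts after sleep deprivation.
#' @param method `"median_split"` (default) or `"fixed_cutoff"`.
#' @param cutoff change cutoff for `"fixed_cutoff"`; change > cutoff is
#'   vulnerable.
#' @return factor with levels vulnerable, resistant.
#' @export
classify_vulnerability <- function(lapse_rw, lapse_sd,
                                   method = c("median_split", "fixed_cutoff"),
                                   cutoff = NULL) {
  method <- match.arg(method)
  if (anyNA(lapse_rw) || anyNA(lapse_sd)) {
    stop("missing lapse scores", call. = FALSE)
  }
  if (length(lapse_rw) != length(lapse_sd)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  change <- lapse_sd - lapse_rw
  if (method == "median_split") {
    if (stats::sd(change) == 0) {
      stop("all lapse changes identical: no split possible", call. = FALSE)
    }
    cutoff <- stats::median(change)
  } else if (is.null(cutoff)) {
    stop("fixed_cutoff method requires a cutoff", call. = FALSE)
  }
  factor(ifelse(change > cutoff, "vulnerable", "resistant"),
         levels = c("vulnerable", "resistant"))
}

# One-sided p for resistant > vulnerable from a pooled t result.
one_sided_p <- function(test) {
  if (!is.finite(test$statistic)) return(if (test$statistic > 0) 0 else 1)
  stats::pt(test$statistic, test$df, lower.tail = FALSE)
}

group_metric_tests <- function(metrics, group) {
  res <- lapply(c("Sp", "Eglob", "Eloc", "Lp", "Cp"), function(m) {
    tst <- two_sample_t(metrics[[m]][group == "resistant"],
                        metrics[[m]][group == "vulnerable"])
    data.frame(metric = m, t = tst$statistic, df = tst$df,
               p = tst$p_value, p_one_sided = one_sided_p(tst))
  })
  do.call(rbind, res)
}

#' Run the full connectome group analysis
#'
#' Executes the whole pipeline on one cohort: load or generate, fiber
#' thresholding (and optional region-volume correction), per-subject global
#' and nodal metrics, group t tests on global metrics, nodal-efficiency
#' tests with FDR across regions, the network-based statistic, per-group
#' sign-test backbones with hub identification, per-subject rich-club /
#' feeder / local strengths with phi (and phi_norm when `n_null > 0`), group
#' tests on class strengths and ratios, and Spearman correlations of each
#' class strength with the lapse change across all subjects.
#'
#' @param config an [analysis_config()].
#' @return list of class `"sdnet_report"` with elements `metrics` (per-subject
#'   data.frame), `global_tests`, `nodal` (tests + FDR), `nbs`, `rich_club`
#'   (per-subject data.frame + hubs + group tests + correlations), `config
#'   digest`, `seed`. Written as JSON/TSV when `config$out_dir` is set.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- if (!is.null(config$cohort_config)) {
    co <- generate_cohort(config$cohort_config)
    generate_lapse_scores(co)
  } else {
    read_cohort(config$input_dir)
  }
  n_groups <- table(cohort$group)
  if (any(n_groups < 2)) stop("each group needs at least 2 subjects", call. = FALSE)

  # --- preprocessing -------------------------------------------------------
  subjects <- lapply(cohort$subjects, apply_fiber_threshold,
                     t = config$fiber_threshold)
  if (config$roi_correction) {
    subjects <- lapply(subjects, roi_volume_correction)
  }
  cohort$subjects <- subjects
  n_sub <- length(subjects)
  n_nodes <- subjects[[1]]$n_nodes

  # --- per-subject metrics -------------------------------------------------
  metric_rows <- vector("list", n_sub)
  e_nodal <- matrix(NA_real_, n_sub, n_nodes,
                    dimnames = list(cohort$subject_id, subjects[[1]]$labels))
  for (i in seq_len(n_sub)) {
    d <- distance_matrix(subjects[[i]])
    metric_rows[[i]] <- data.frame(
      subject_id = cohort$subject_id[i], group = as.character(cohort$group[i]),
      Sp = network_strength(subjects[[i]]),
      Eglob = global_efficiency(subjects[[i]], d = d),
      Eloc = local_efficiency(subjects[[i]]),
      Lp = characteristic_path_length(subjects[[i]], d = d,
                                      on_disconnect = "ignore"),
      Cp = clustering_coefficient(subjects[[i]])$cp
    )
    e_nodal[i, ] <- nodal_efficiency(subjects[[i]], d = d)
  }
  metrics <- do.call(rbind, metric_rows)
  global_tests <- group_metric_tests(metrics, cohort$group)

  # --- nodal efficiency with FDR across regions ---------------------------
  nodal <- NULL
  if (config$do_nodal) {
    res_rows <- cohort$group == "resistant"
    tests <- lapply(seq_len(n_nodes), function(j) {
      tst <- two_sample_t(e_nodal[res_rows, j], e_nodal[!res_rows, j])
      data.frame(region = subjects[[1]]$labels[j], t = tst$statistic,
                 p = tst$p_value)
    })
    nod <- do.call(rbind, tests)
    fdr <- fdr_bh(nod$p, q = config$alpha)
    nod$p_fdr <- fdr$p_adjusted
    nod$significant <- fdr$significant
    nodal <- nod
  }

  # --- network-based statistic --------------------------------------------
  nbs <- NULL
  if (config$do_nbs) {
    nbs <- nbs_permutation(cohort, t_thresh = config$nbs_t_thresh,
                           edge_p = config$nbs_edge_p,
                           n_perm = config$n_perm, seed = config$seed)
  }

  # --- rich club -----------------------------------------------------------
  rich_club <- NULL
  if (config$do_rich_club) {
    rich_club <- rich_club_stage(cohort, config)
  }

  report <- structure(
    list(metrics = metrics, global_tests = global_tests, nodal = nodal,
         nbs = nbs, rich_club = rich_club,
         lapse = data.frame(subject_id = cohort$subject_id,
                            group = as.character(cohort$group),
                            lapse_rw = cohort$lapse_rw,
                            lapse_sd = cohort$lapse_sd),
         fiber_threshold = config$fiber_threshold,
         roi_correction = config$roi_correction,
         seed = config$seed),
    class = "sdnet_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Per-group backbones, hubs, per-subject class strengths, phi, phi_norm,
# group tests, behaviour correlations.
rich_club_stage <- function(cohort, config) {
  groups <- levels(cohort$group)
  backbones <- lapply(groups, function(g) {
    backbone_network(cohort$subjects[cohort$group == g],
                     alpha = config$alpha, correction = config$correction)
  })
  names(backbones) <- groups
  hubs <- lapply(backbones, identify_hubs)

  n_sub <- length(cohort$subjects)
  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    g <- as.character(cohort$group[i])
    hub_set <- hubs[[g]]
    conn <- cohort$subjects[[i]]
    cs <- connection_strengths(conn, hub_set)
    wrc <- weighted_rich_club_coefficient(conn, hub_set)
    phi_norm <- NA_real_
    if (config$n_null > 0 && wrc$defined) {
      ens <- matched_ensemble(conn, n = config$n_null,
                              seed = subject_seed(config$seed, 900000L + i))
      phi_norm <- normalized_rich_club(conn, hub_set, ens)$phi_norm
    }
    rows[[i]] <- data.frame(
      subject_id = cohort$subject_id[i], group = g,
      strength_rich = cs$strength_rich, strength_feeder = cs$strength_feeder,
      strength_local = cs$strength_local,
      ratio_rich_feeder = cs$ratio_rich_feeder,
      ratio_rich_local = cs$ratio_rich_local,
      phi = wrc$phi, phi_norm = phi_norm
    )
  }
  per_subject <- do.call(rbind, rows)

  vars <- c("strength_rich", "strength_feeder", "strength_local",
            "ratio_rich_feeder", "ratio_rich_local")
  res <- per_subject$group == "resistant"
  class_tests <- do.call(rbind, lapply(vars, function(v) {
    x <- per_subject[[v]][res]; y <- per_subject[[v]][!res]
    if (anyNA(c(x, y))) {
      return(data.frame(measure = v, t = NA, df = NA, p = NA,
                        p_one_sided = NA))
    }
    tst <- two_sample_t(x, y)
    data.frame(measure = v, t = tst$statistic, df = tst$df, p = tst$p_value,
               p_one_sided = one_sided_p(tst))
  }))

  correlations <- NULL
  if (!is.null(cohort$lapse_sd)) {
    change <- cohort$lapse_sd - (if (is.null(cohort$lapse_rw)) 0 else
                                 cohort$lapse_rw)
    correlations <- do.call(rbind, lapply(
      c("strength_rich", "strength_feeder", "strength_local"), function(v) {
        sp <- spearman_test(per_subject[[v]], change)
        data.frame(measure = v, rho = sp$rho, p = sp$p_value)
      }))
  }
  list(backbones = backbones, hubs = hubs, per_subject = per_subject,
       class_tests = class_tests, correlations = correlations)
}

#' @export
print.sdnet_report <- function(x, ...) {
  cat("<sdnet analysis report>\n")
  cat(sprintf("  fiber threshold %g%s, seed %d\n", x$fiber_threshold,
              if (x$roi_correction) " + ROI volume correction" else "",
              x$seed))
  print(x$global_tests, row.names = FALSE)
  if (!is.null(x$nbs)) print(x$nbs)
  if (!is.null(x$rich_club)) {
    print(x$rich_club$class_tests, row.names = FALSE)
  }
  invisible(x)
}

# JSON summary (machine comparison) + TSV tables + plain-text log.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(out_dir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$global_tests, file.path(out_dir, "global_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$nodal)) {
    utils::write.table(report$nodal, file.path(out_dir, "nodal_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$rich_club)) {
    utils::write.table(report$rich_club$per_subject,
                       file.path(out_dir, "rich_club.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$nbs) && length(report$nbs$components)) {
    comp <- report$nbs$components[[1]]
    utils::write.table(comp$edges, file.path(out_dir, "nbs_component.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    seed = report$seed,
    fiber_threshold = report$fiber_threshold,
    roi_correction = report$roi_correction,
    global_tests = report$global_tests,
    nbs = if (!is.null(report$nbs)) list(
      primary_threshold = report$nbs$primary_threshold,
      n_components = length(report$nbs$components),
      max_component_edges = report$nbs$observed_max,
      p = if (length(report$nbs$component_p)) min(report$nbs$component_p) else NA
    ),
    rich_club_tests = if (!is.null(report$rich_club))
      report$rich_club$class_tests,
    correlations = if (!is.null(report$rich_club))
      report$rich_club$correlations
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  writeLines(
    c(sprintf("seed: %d", report$seed),
      sprintf("fiber_threshold: %g", report$fiber_threshold),
      sprintf("roi_correction: %s", report$roi_correction),
      sprintf("generated: by sdnet %s",
              as.character(utils::packageVersion("sdnet")))),
    file.path(out_dir, "run.log")
  )
  invisible(out_dir)
}

#' Reproducibility sweep over fiber thresholds and ROI correction
#'
#' Reruns the group comparison for fiber thresholds 0, 10, 50 and 100, with
#' and without region-volume correction, and tabulates the direction and
#' p-value of every global-metric group difference. A robust finding keeps
#' its sign across the sweep.
#'
#' @param config an [analysis_config()]; its `fiber_threshold` and
#'   `roi_correction` are overridden by the sweep grid.
#' @param thresholds fiber thresholds to sweep (default `c(0, 10, 50, 100)`).
#' @param roi both with and without correction (default `c(FALSE, TRUE)`).
#' @param heavy_stages run NBS/rich-club in each sweep cell (default FALSE:
#'   the sweep targets the global metrics).
#' @return data.frame with one row per (threshold, roi, metric).
#' @export
reproducibility_sweep <- function(config, thresholds = c(0, 10, 50, 100),
                                  roi = c(FALSE, TRUE), heavy_stages = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  grid <- expand.grid(fiber_threshold = thresholds, roi_correction = roi)
  out <- lapply(seq_len(nrow(grid)), function(r) {
    cfg <- config
    cfg$fiber_threshold <- grid$fiber_threshold[r]
    cfg$roi_correction <- grid$roi_correction[r]
    cfg$out_dir <- NULL
    if (!heavy_stages) {
      cfg$do_nbs <- FALSE
      cfg$do_rich_club <- FALSE
      cfg$do_nodal <- FALSE
    }
    rep <- run_analysis(cfg)
    cbind(fiber_threshold = grid$fiber_threshold[r],
          roi_correction = grid$roi_correction[r],
          rep$global_tests)
  })
  do.call(rbind, out)
}
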