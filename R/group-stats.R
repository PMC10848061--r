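test_result <- function(statistic, df, p_value, tails, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 tails = tails, method = method),
            class = "sdnet_test")
}

#' @export
print.sdnet_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (%s-tailed)\n", x$method,
              x$statistic,
              if (!is.null(x$df)) sprintf(", df = %.4g", x$df) else "",
              x$p_value, x$tails))
  invisible(x)
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's t with pooled variance, computed directly from group means,
#' standard deviations and sizes — the form needed to recompute statistics
#' from published mean +/- SD tables:
#' `t = (mean_a - mean_b) / (s_p * sqrt(1/n_a + 1/n_b))` with
#' `s_p^2 = ((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2)`.
#'
#' @param mean_a,sd_a,n_a summary statistics of group a.
#' @param mean_b,sd_b,n_b summary statistics of group b.
#' @return an `sdnet_test` with two-tailed p from the t distribution. If both
#'   SDs are zero: t = 0 for equal means, `Inf` (flagged via the statistic)
#'   for unequal means.
#' @export
pooled_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) stop("both groups need n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0", call. = FALSE)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  if (sp2 == 0) {
    tstat <- if (mean_a == mean_b) 0 else Inf * sign(mean_a - mean_b)
  } else {
    tstat <- (mean_a - mean_b) / (sqrt(sp2) * sqrt(1 / n_a + 1 / n_b))
  }
  p <- if (is.finite(tstat)) 2 * stats::pt(-abs(tstat), df) else 0
  test_result(tstat, df, p, "two", "pooled two-sample t")
}

#' Pooled two-sample t test from raw samples
#'
#' Identical to [pooled_t_from_summary()] applied to the samples' means, SDs
#' and sizes.
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 2.
#' @return an `sdnet_test`.
#' @export
two_sample_t <- function(samples_a, samples_b) {
  if (length(samples_a) < 2 || length(samples_b) < 2) {
    stop("both samples need n >= 2", call. = FALSE)
  }
  pooled_t_from_summary(mean(samples_a), stats::sd(samples_a), length(samples_a),
                        mean(samples_b), stats::sd(samples_b), length(samples_b))
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction,
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1.
#'
#' @param table 2x2 nonnegative integer matrix with positive margins.
#' @return an `sdnet_test`.
#' @export
chi_square_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  ntot <- sum(tab)
  stat <- ntot * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  test_result(stat, 1, stats::pchisq(stat, 1, lower.tail = FALSE),
              "two", "chi-square (2x2, uncorrected)")
}

#' Wilcoxon rank-sum Z test
#'
#' Rank-sum test with midranks for ties; the Z statistic uses the normal
#' approximation with the tie-corrected variance. Used for skewed outcomes
#' such as lapse counts, where the t test's normality assumption fails.
#'
#' @param samples_a,samples_b numeric vectors (nonempty).
#' @return an `sdnet_test` (Z statistic, two-tailed normal p). Sign convention:
#'   positive Z means group a ranks higher.
#' @export
rank_sum_z <- function(samples_a, samples_b) {
  n1 <- length(samples_a); n2 <- length(samples_b)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty", call. = FALSE)
  r <- rank(c(samples_a, samples_b))
  w <- sum(r[seq_len(n1)])                     # rank sum of group a
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * (n + 1 - tie_term)
  z <- if (v > 0) (w - mu) / sqrt(v) else 0
  test_result(z, NULL, 2 * stats::pnorm(-abs(z)), "two",
              "Wilcoxon rank-sum (normal approximation)")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values and discovery flags at level `q`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` and `significant` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(p_adjusted = numeric(0), significant = logical(0)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  padj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = padj, significant = padj < q)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value uses the t approximation with
#' `n - 2` degrees of freedom (adequate at the cohort sizes this design uses).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs n >= 3", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance: correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
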