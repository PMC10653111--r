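# shared histogram over the union range of two samples, Freedman-Diaconis
# bin width computed on the pooled sample; returns integer counts per bin
shared_histogram <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  bw <- 2 * IQR(pooled) / n^(1 / 3)
  rng <- range(pooled)
  if (bw <= 0) bw <- max(diff(rng) / max(1, ceiling(log2(n) + 1)), 1e-8)
  breaks <- seq(rng[1], rng[2] + bw, by = bw)
  bin <- function(v) tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                           all.inside = TRUE),
                              nbins = length(breaks) - 1)
  list(breaks = breaks, width = bw, counts_x = bin(x), counts_y = bin(y))
}

#' Overlap coefficient of forward and reverse work distributions
#'
#' The overlap coefficient is the area of intersection of the two
#' probability density functions — the forward-work density and the
#' negated-reverse-work density — estimated on a shared histogram grid
#' spanning the union of both sample ranges (Freedman-Diaconis bin width on
#' the pooled sample): sum over bins of min(p_f, p_r) times the bin width.
#' It lies in \[0, 1\]: 1 for identical samples, 0 for disjoint supports.
#' Low overlap means the two-sided estimators are extrapolating; following
#' the warn-don't-reject policy, overlap below 1% raises warning W001 but
#' the estimate is still produced.
#'
#' @param ws a [work_set] with >= 2 completed samples per direction.
#' @param warn_below warning threshold on the overlap (default 0.01).
#' @return an object of class `overlap_report` with fields `overlap`,
#'   `n_forward`, `n_reverse`, `bin_width`, `n_bins`, `low_overlap_warning`.
#' @examples
#' ws <- generate_crooks_gaussian(crooks_spec(0, 1, n_forward = 2000, seed = 2))
#' overlap_coefficient(ws)$overlap
#' @export
overlap_coefficient <- function(ws, warn_below = 0.01) {
  assert_work_set(ws)
  f <- completed_works(ws, "forward")
  r <- completed_works(ws, "reverse", negate_reverse = TRUE)
  if (length(f) < 2 || length(r) < 2)
    neqfe_stop("overlap requires >= 2 completed samples per direction")
  h <- shared_histogram(f, r)
  nf <- as.numeric(length(f)); nr <- as.numeric(length(r))
  # sum of min(cf/nf, cr/nr); exact integer-valued products keep identical
  # samples at exactly 1
  ov <- sum(pmin(h$counts_x * nr, h$counts_y * nf)) / (nf * nr)
  low <- ov < warn_below
  if (low)
    neqfe_warn("W001", sprintf(
      "work-distribution overlap %.4f below %.2g for pair %s (%s leg); estimate unreliable",
      ov, warn_below, ws$pair_id, ws$leg))
  structure(list(overlap = ov, n_forward = nf, n_reverse = nr,
                 bin_width = h$width, n_bins = length(h$counts_x),
                 low_overlap_warning = low),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> overlap = %.4f (n_f = %d, n_r = %d, %d bins)%s\n",
              x$overlap, x$n_forward, x$n_reverse, x$n_bins,
              if (x$low_overlap_warning) "  ** LOW OVERLAP **" else ""))
  invisible(x)
}

#' Empirical check of the Crooks fluctuation theorem
#'
#' On shared histogram bins populated in both directions, the theorem
#' predicts log(p_f(W) / p_r(-W)) = beta (W - dG): a straight line in W
#' with slope beta = 1/kT and intercept -beta dG. This fits that line by
#' weighted least squares over bins with at least `min_count` counts in
#' each direction (weights 1 / (1/c_f + 1/c_r), the inverse variance of
#' the log count ratio).
#'
#' @param ws a [work_set].
#' @param min_count minimum per-direction bin count (default 50).
#' @return a list with `slope`, `intercept`, `beta` (the theoretical
#'   slope), `dg_implied` (= -intercept/slope), and `n_bins` used.
#' @export
fluctuation_slope <- function(ws, min_count = 50) {
  assert_work_set(ws)
  f <- completed_works(ws, "forward")
  r <- completed_works(ws, "reverse", negate_reverse = TRUE)
  h <- shared_histogram(f, r)
  keep <- h$counts_x >= min_count & h$counts_y >= min_count
  if (sum(keep) < 2)
    neqfe_stop("fewer than 2 shared bins with sufficient counts")
  centers <- (h$breaks[-1] + h$breaks[-length(h$breaks)])[keep] / 2
  cf <- h$counts_x[keep]; cr <- h$counts_y[keep]
  y <- log(cf / length(f)) - log(cr / length(r))
  fit <- lm(y ~ centers, weights = 1 / (1 / cf + 1 / cr))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  list(slope = slope, intercept = intercept, beta = beta_of(ws$temperature),
       dg_implied = -intercept / slope, n_bins = sum(keep))
}

#' Accuracy binned by work-distribution overlap
#'
#' Splits benchmark pairs into overlap bins — exactly zero, (0, 0.5], and
#' (0.5, 1] — and reports, per bin, how many pairs have an unsigned error
#' |ddG_cal - ddG_exp| worse than a threshold (default 2 kcal/mol).
#'
#' @param table a [benchmark_table] with an `overlap` column.
#' @param error_threshold kcal/mol.
#' @return a data frame with columns `bin`, `n_pairs`, `n_exceeding`,
#'   `percentage`.
#' @export
accuracy_overlap_binning <- function(table, error_threshold = 2) {
  table <- benchmark_table(table)
  if (nrow(table) == 0) neqfe_stop("empty benchmark table")
  if (!"overlap" %in% names(table) || anyNA(table$overlap))
    neqfe_stop("accuracy_overlap_binning requires an overlap column")
  if (any(table$overlap < 0 | table$overlap > 1))
    neqfe_stop("overlaps must lie in [0, 1]")
  err <- abs(table$ddg_cal - table$ddg_exp)
  bins <- list(`0` = table$overlap == 0,
               `(0,0.5]` = table$overlap > 0 & table$overlap <= 0.5,
               `(0.5,1]` = table$overlap > 0.5)
  out <- do.call(rbind, lapply(names(bins), function(b) {
    sel <- bins[[b]]
    n <- sum(sel); ne <- sum(err[sel] > error_threshold)
    data.frame(bin = b, n_pairs = n, n_exceeding = ne,
               percentage = if (n > 0) 100 * ne / n else NA_real_)
  }))
  out
}

#' Bootstrapped impact of one additional replica
#'
#' For each ensemble size N from 1 to pool size - 1, draws (independently,
#' with replacement) one resample of size N and one of size N + 1, and
#' records |mean_N - mean_(N+1)|. The statistic is the average of this
#' absolute difference over `n_boot` iterations, with 2.5% / 97.5%
#' percentile confidence bounds. The resampling uses indices only, so the
#' curve is exactly scale-equivariant at a fixed seed.
#'
#' @param pool numeric vector of per-replica dG values (an `ensemble_pool`).
#' @param n_boot bootstrap iterations per N (default 100000).
#' @param seed integer RNG seed.
#' @return a data frame of class `convergence_curve` with columns `n`,
#'   `statistic`, `ci_low`, `ci_high` and `se` (the Monte-Carlo standard
#'   error of the statistic over the `n_boot` iterations).
#' @export
replica_increment_bootstrap <- function(pool, n_boot = 100000L, seed = 1L) {
  pool <- as.numeric(pool)
  np <- length(pool)
  if (np < 2) neqfe_stop("pool size must be >= 2")
  stopifnot(all(is.finite(pool)), n_boot >= 2)
  with_seed(seed, {
    rows <- lapply(seq_len(np - 1), function(N) {
      i1 <- matrix(sample.int(np, N * n_boot, replace = TRUE), nrow = N)
      i2 <- matrix(sample.int(np, (N + 1) * n_boot, replace = TRUE),
                   nrow = N + 1)
      d <- abs(colMeans(matrix(pool[i1], nrow = N)) -
                 colMeans(matrix(pool[i2], nrow = N + 1)))
      ci <- unname(quantile(d, c(0.025, 0.975)))
      data.frame(n = N, statistic = mean(d), ci_low = ci[1], ci_high = ci[2],
                 se = sd(d) / sqrt(n_boot))
    })
    out <- do.call(rbind, rows)
    class(out) <- c("convergence_curve", "data.frame")
    out
  })
}

#' Normalize a replica-increment curve by its first point
#'
#' Divides every statistic (and confidence bound) by the N = 1 statistic,
#' so curves from pools differing only in scale collapse onto a single
#' line.
#'
#' @param curve a `convergence_curve` from [replica_increment_bootstrap()].
#' @return a `convergence_curve` with the first statistic equal to 1.
#' @export
normalized_increment_curve <- function(curve) {
  stopifnot(inherits(curve, "convergence_curve"))
  s1 <- curve$statistic[curve$n == min(curve$n)][1]
  if (!is.finite(s1) || s1 <= 0)
    neqfe_stop("cannot normalize: first-point statistic is zero")
  out <- curve
  out$statistic <- curve$statistic / s1
  out$ci_low <- curve$ci_low / s1
  out$ci_high <- curve$ci_high / s1
  if ("se" %in% names(out)) out$se <- curve$se / s1
  out
}

# deterministic uniform-stride subset: every floor(total/N)-th index
stride_indices <- function(total, N) {
  if (N > total) neqfe_stop(sprintf("N = %d exceeds the %d available", N, total))
  floor(total / N) * seq_len(N)
}

#' Convergence of dG with the number of transitions
#'
#' For each requested N, selects N transitions per direction by uniform
#' stride from the completed samples (every floor(total/N)-th, a
#' deterministic stand-in for "uniformly selected"), re-estimates dG, and
#' reports the deviation from the full-data estimate with a bootstrap
#' confidence interval. At N = total the deviation is exactly zero.
#'
#' @param ws a [work_set].
#' @param ns integer vector of transition counts per direction.
#' @param estimator passed to [estimate_dg()].
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @param random if `TRUE`, sample the N transitions at random (seeded)
#'   instead of by stride.
#' @return a `convergence_curve` data frame (`n`, `statistic` = dG_N -
#'   dG_full, `ci_low`, `ci_high`, `dg`).
#' @export
transition_count_convergence <- function(ws, ns, estimator = "bar",
                                         n_boot = 200L, seed = 1L,
                                         random = FALSE) {
  assert_work_set(ws)
  fi <- which(ws$forward$completed)
  ri <- which(ws$reverse$completed)
  full <- estimate_dg(ws, estimator)$dg
  ns <- sort(as.integer(ns))
  rows <- lapply(seq_along(ns), function(k) {
    N <- ns[k]
    if (N > min(length(fi), length(ri)))
      neqfe_stop(sprintf("N = %d exceeds completed transitions per direction", N))
    sel_f <- if (random) with_seed(seed + k, sort(sample(fi, N)))
             else fi[stride_indices(length(fi), N)]
    sel_r <- if (random) with_seed(seed + k + length(ns), sort(sample(ri, N)))
             else ri[stride_indices(length(ri), N)]
    sub <- work_set(ws$forward$work[sel_f], ws$reverse$work[sel_r],
                    ws$pair_id, ws$leg, ws$temperature,
                    forward_meta = ws$forward[sel_f, -1],
                    reverse_meta = ws$reverse[sel_r, -1])
    dg <- estimate_dg(sub, estimator)$dg
    se <- bootstrap_uncertainty(sub, estimator, n_boot = n_boot,
                                seed = seed + 1000L + k)
    data.frame(n = N, statistic = dg - full, ci_low = dg - full - 1.96 * se,
               ci_high = dg - full + 1.96 * se, dg = dg)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("convergence_curve", "data.frame")
  out
}

#' Time-dependent free energy estimate
#'
#' For each t in `t_grid`, estimates dG using only transitions whose source
#' snapshot was extracted at or before t (both directions) — the
#' equilibrium-sampling convergence diagnostic. At the final snapshot time
#' the estimate equals the full-data estimate exactly. A drift or step in
#' the curve signals unequilibrated end-point sampling.
#'
#' @param ws a [work_set] whose samples carry `snapshot_time_ps`.
#' @param t_grid increasing vector of times (ps).
#' @inheritParams transition_count_convergence
#' @return a `convergence_curve` data frame (`n` = t, `statistic` = dG(t),
#'   `ci_low`, `ci_high`).
#' @export
time_dependent_estimate <- function(ws, t_grid, estimator = "bar",
                                    n_boot = 200L, seed = 1L) {
  assert_work_set(ws)
  if (all(is.na(ws$forward$snapshot_time_ps)))
    neqfe_stop("samples carry no snapshot times")
  rows <- lapply(seq_along(t_grid), function(k) {
    sub <- filter_by_time(ws, t_grid[k])
    dg <- estimate_dg(sub, estimator)$dg
    se <- bootstrap_uncertainty(sub, estimator, n_boot = n_boot,
                                seed = seed + k)
    data.frame(n = t_grid[k], statistic = dg, ci_low = dg - 1.96 * se,
               ci_high = dg + 1.96 * se)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("convergence_curve", "data.frame")
  out
}

#' Shape diagnostics of a free energy ensemble
#'
#' Reports sample skewness, excess kurtosis, the normal-probability-plot
#' correlation coefficient (correlation of the sorted values against normal
#' quantiles; values well below 1 indicate non-normality) and the spread
#' (max - min) of a pool of per-replica dG values. Skewed, fat-tailed or
#' multimodal pools are the signature of multiple ligand conformations.
#'
#' @param pool numeric vector of per-replica dG values (>= 3 for skewness,
#'   >= 4 for kurtosis; must not be constant).
#' @return a list of class `shape_report` with `n`, `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`, `ppcc`, `spread`.
#' @export
distribution_shape <- function(pool) {
  pool <- as.numeric(pool)
  n <- length(pool)
  if (n < 3) neqfe_stop("distribution_shape requires a pool of size >= 3")
  stopifnot(all(is.finite(pool)))
  m <- mean(pool)
  s2 <- mean((pool - m)^2)
  if (s2 == 0) neqfe_stop("skewness undefined for a constant pool")
  skew <- mean((pool - m)^3) / s2^1.5
  kurt <- if (n >= 4) mean((pool - m)^4) / s2^2 - 3 else NA_real_
  ppcc <- cor(sort(pool), qnorm(ppoints(n)))
  structure(list(n = n, mean = m, sd = sd(pool), skewness = skew,
                 excess_kurtosis = kurt, ppcc = ppcc,
                 spread = max(pool) - min(pool)),
            class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  cat(sprintf(
    "<shape_report> n = %d: skew %.3f, excess kurtosis %s, ppcc %.4f, spread %.3f kcal/mol\n",
    x$n, x$skewness,
    if (is.na(x$excess_kurtosis)) "NA" else sprintf("%.3f", x$excess_kurtosis),
    x$ppcc, x$spread))
  invisible(x)
}

#' Failed-transition accounting
#'
#' Counts switching transitions that terminated before reaching the final
#' lambda state (completed = FALSE) across both directions. Failed samples
#' are excluded from every estimator; this reports how many.
#'
#' @param ws a [work_set].
#' @return a list with `n_failed`, `n_total`, `failure_rate` (percent).
#' @export
failure_accounting <- function(ws) {
  assert_work_set(ws)
  flags <- c(ws$forward$completed, ws$reverse$completed)
  list(n_failed = sum(!flags), n_total = length(flags),
       failure_rate = 100 * sum(!flags) / length(flags))
}
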