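#' Jarzynski (exponential-average) free energy estimator
#'
#' dG = -kT log < exp(-W / kT) > over work values from a single switching
#' direction, evaluated via a log-sum-exp for numerical stability. Applied
#' to forward works it estimates dG(A -> B); applied to the negated reverse
#' works it estimates dG(B -> A) = -dG(A -> B) in expectation. The
#' exponential average is dominated by the low-work tail, so the estimator
#' is biased at small n and wide distributions; for Gaussian work of
#' width sigma the population value is mu - beta sigma^2 / 2.
#'
#' @param works numeric vector of work values from one direction (kcal/mol),
#'   completed transitions only.
#' @param temperature kelvin.
#' @param estimator label stored in the result (`"jarzynski_f"` or
#'   `"jarzynski_r"`).
#' @return a [fe_estimate] (uncertainty `NA`; use [bootstrap_uncertainty()]).
#' @export
jarzynski <- function(works, temperature = 300, estimator = "jarzynski_f") {
  if (length(works) < 1) neqfe_stop("jarzynski requires at least one work value")
  stopifnot(all(is.finite(works)))
  fe_estimate(jarzynski_solve(works, beta_of(temperature)),
              estimator = estimator, n_forward = length(works),
              temperature = temperature)
}

jarzynski_solve <- function(works, b) {
  -(logsumexp(-b * works) - log(length(works))) / b
}

# intersection of the two fitted normal densities; f and rneg are the
# forward and negated-reverse works
cgi_solve <- function(f, rneg) {
  mf <- mean(f); mr <- mean(rneg)
  sf <- sd(f); sr <- sd(rneg)
  midpoint <- (mf + mr) / 2
  if (sf == 0 || sr == 0) return(list(dg = midpoint, converged = FALSE))
  if (abs(sf - sr) <= 1e-6 * max(sf, sr))
    return(list(dg = midpoint, converged = TRUE))
  # (W - mr)^2 / sr^2 - (W - mf)^2 / sf^2 = 2 log(sf / sr)
  a <- 1 / sr^2 - 1 / sf^2
  b <- -2 * (mr / sr^2 - mf / sf^2)
  cc <- mr^2 / sr^2 - mf^2 / sf^2 - 2 * log(sf / sr)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(list(dg = midpoint, converged = FALSE))
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  inside <- roots[roots > min(mf, mr) & roots < max(mf, mr)]
  if (length(inside) == 0) return(list(dg = midpoint, converged = FALSE))
  list(dg = inside[1], converged = TRUE)
}

#' Crooks Gaussian intersection (CGI) estimator
#'
#' Fits normal densities to the forward works and the negated reverse works;
#' by the Crooks fluctuation theorem the two densities cross at W = dG. With
#' equal fitted variances the intersection is the midpoint of the two means;
#' with unequal variances it is the root of the density-equality quadratic
#' lying strictly between the two means (when the distributions overlap the
#' physical intersection lies between the peaks). If no root lies between
#' the means or a direction has degenerate variance, the equal-variance
#' midpoint is returned with `converged = FALSE`.
#'
#' @param ws a [work_set] with at least 2 completed samples per direction.
#' @return a [fe_estimate].
#' @export
crooks_gaussian_intersection <- function(ws) {
  assert_work_set(ws)
  f <- completed_works(ws, "forward")
  r <- completed_works(ws, "reverse", negate_reverse = TRUE)
  if (length(f) < 2 || length(r) < 2)
    neqfe_stop("CGI requires >= 2 completed samples per direction")
  sol <- cgi_solve(f, r)
  fe_estimate(sol$dg, estimator = "cgi", n_forward = length(f),
              n_reverse = length(r), n_excluded = n_excluded(ws),
              temperature = ws$temperature, converged = sol$converged)
}

# Bennett self-consistent equation solver; wr holds the as-measured
# (1 -> 0) reverse works. The equation, with f(x) = 1/(1 + exp(x)) and
# M = log(n_f / n_r):
#   sum_f f(beta (W_f - dG) + M) = sum_r f(beta (W_r + dG) - M)
# LHS decreases and RHS increases in dG, so the root is unique.
bar_solve <- function(wf, wr, b, tolerance = 1e-8, max_iter = 500L) {
  M <- log(length(wf) / length(wr))
  g <- function(dg) sum(plogis(-(b * (wf - dg) + M))) -
    sum(plogis(-(b * (wr + dg) - M)))
  mid <- (mean(wf) + mean(-wr)) / 2
  cap <- max(abs(c(wf, wr))) + 50 / b
  half <- max(1, 4 * sd(c(wf, -wr)))
  if (!is.finite(half)) half <- 1
  lo <- mid - half; hi <- mid + half
  glo <- g(lo); ghi <- g(hi)
  while (glo * ghi > 0 && (lo > -cap || hi < cap)) {
    half <- half * 2
    lo <- max(mid - half, -cap); hi <- min(mid + half, cap)
    glo <- g(lo); ghi <- g(hi)
  }
  if (glo * ghi > 0) return(list(dg = mid, converged = FALSE, cap = cap))
  root <- uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi,
                  tol = tolerance, maxiter = max_iter)
  list(dg = root$root, converged = TRUE, cap = cap)
}

#' Bennett acceptance ratio (BAR) estimator
#'
#' Solves the Bennett self-consistent equation with the logistic (Fermi)
#' function f(x) = 1 / (1 + exp(x)): the sum over forward works of
#' f(beta (W_f - dG) + M) equals the sum over reverse works (as measured on
#' the 1 -> 0 path) of f(beta (W_r + dG) - M), with M = log(n_f / n_r).
#' The left side decreases and the right side increases in dG, so the root
#' is unique; it is located by a bracketed root search expanded from the
#' Gaussian-intersection midpoint and capped at max|W| + 50 kT. A
#' non-bracketable root indicates pathological, non-overlapping inputs and
#' yields the midpoint estimate with `converged = FALSE` and a warning
#' rather than a rejection. Swapping the roles of the two directions
#' negates the estimate exactly (to solver tolerance).
#'
#' @param ws a [work_set] with at least one completed sample per direction.
#' @param tolerance root-location tolerance on dG, kcal/mol.
#' @param max_iter maximum solver iterations.
#' @return a [fe_estimate].
#' @examples
#' bar(work_set(c(1.2), c(-1.2)))$dg # reversible limit: exactly 1.2
#' @export
bar <- function(ws, tolerance = 1e-8, max_iter = 500L) {
  assert_work_set(ws)
  wf <- completed_works(ws, "forward")
  wr <- completed_works(ws, "reverse") # as measured, B -> A sign
  if (length(wf) < 1 || length(wr) < 1)
    neqfe_stop(paste("BAR requires completed samples in both directions;",
                     "with one direction only, use jarzynski() on that",
                     "direction instead"), class = "neqfe_one_sided")
  sol <- bar_solve(wf, wr, beta_of(ws$temperature), tolerance, max_iter)
  if (!sol$converged)
    neqfe_warn("W001", sprintf(
      "BAR root not bracketable within +/-%.1f kcal/mol for pair %s (%s leg); returning Gaussian-intersection midpoint",
      sol$cap, ws$pair_id, ws$leg))
  fe_estimate(sol$dg, estimator = "bar", n_forward = length(wf),
              n_reverse = length(wr), n_excluded = n_excluded(ws),
              temperature = ws$temperature, converged = sol$converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate dG from a work set with a chosen estimator
#'
#' Dispatcher used across the diagnostics: runs one of the work-based
#' estimators on the completed samples of a work set and (optionally)
#' attaches a bootstrap standard error so that uncertainties are homogeneous
#' across estimators.
#'
#' @param ws a [work_set].
#' @param estimator `"bar"`, `"cgi"`, `"jarzynski_f"` or `"jarzynski_r"`.
#' @param uncertainty if `TRUE`, attach [bootstrap_uncertainty()].
#' @param n_boot bootstrap resamples for the uncertainty.
#' @param seed RNG seed for the bootstrap (`NULL` = ambient stream).
#' @param ... passed to the estimator (e.g. `tolerance` for BAR).
#' @return a [fe_estimate].
#' @export
estimate_dg <- function(ws, estimator = c("bar", "cgi", "jarzynski_f",
                                          "jarzynski_r"),
                        uncertainty = FALSE, n_boot = 1000L, seed = NULL,
                        ...) {
  assert_work_set(ws)
  estimator <- match.arg(estimator)
  est <- switch(estimator,
    bar = bar(ws, ...),
    cgi = crooks_gaussian_intersection(ws),
    jarzynski_f = {
      e <- jarzynski(completed_works(ws, "forward"), ws$temperature,
                     "jarzynski_f")
      e$n_excluded <- n_excluded(ws); e
    },
    jarzynski_r = {
      # the as-measured reverse works estimate dG(B -> A); flip the sign
      # to report on the forward axis
      e <- jarzynski(completed_works(ws, "reverse"),
                     ws$temperature, "jarzynski_r")
      e$dg <- -e$dg
      e$n_reverse <- e$n_forward; e$n_forward <- 0L
      e$n_excluded <- n_excluded(ws); e
    })
  if (uncertainty)
    est$uncertainty <- bootstrap_uncertainty(ws, estimator, n_boot = n_boot,
                                             seed = seed, ...)
  est
}

#' Bootstrap standard error of a work-based estimator
#'
#' Resamples completed work values with replacement, independently per
#' direction, re-runs the estimator and returns the standard deviation of
#' the resampled dG values.
#'
#' @inheritParams estimate_dg
#' @return standard error in kcal/mol.
#' @export
bootstrap_uncertainty <- function(ws, estimator = c("bar", "cgi",
                                                    "jarzynski_f",
                                                    "jarzynski_r"),
                                  n_boot = 1000L, seed = NULL, ...) {
  assert_work_set(ws)
  estimator <- match.arg(estimator)
  if (n_boot < 2) neqfe_stop("n_boot must be >= 2")
  wf <- completed_works(ws, "forward")
  wr <- completed_works(ws, "reverse")
  b <- beta_of(ws$temperature)
  with_seed(seed, {
    dgs <- vapply(seq_len(n_boot), function(i) {
      f <- wf[sample.int(length(wf), replace = TRUE)]
      r <- wr[sample.int(length(wr), replace = TRUE)]
      switch(estimator,
        jarzynski_f = jarzynski_solve(f, b),
        jarzynski_r = -jarzynski_solve(r, b),
        cgi = cgi_solve(f, -r)$dg,
        bar = bar_solve(f, r, b, ...)$dg)
    }, numeric(1))
    sd(dgs)
  })
}
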