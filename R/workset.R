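#' Labelled nonequilibrium work samples for one (pair, leg)
#'
#' A `work_set` holds the work values recorded during fast alchemical
#' switching transitions for a single ligand pair in one leg of the
#' thermodynamic cycle. Forward works correspond to the lambda 0 -> 1 path;
#' reverse works are stored in the as-measured (1 -> 0) sign convention, so
#' estimators negate them internally. Each sample carries the replica it was
#' spawned from, the source snapshot time in the end-point equilibrium
#' trajectory, and a completion flag; transitions that terminated before
#' reaching the final lambda state are flagged `completed = FALSE` and are
#' excluded from every estimator (but tallied by [failure_accounting()]).
#'
#' @param forward numeric vector of forward work values (kcal/mol).
#' @param reverse numeric vector of reverse work values, as measured on the
#'   reverse path (kcal/mol).
#' @param pair_id identifier of the ligand pair.
#' @param leg `"complex"` or `"solvent"`.
#' @param temperature simulation temperature in kelvin.
#' @param forward_meta,reverse_meta optional data frames with columns
#'   `replica_id`, `snapshot_time_ps`, `completed`, one row per sample.
#' @return an object of class `work_set`.
#' @seealso [bar()], [crooks_gaussian_intersection()], [jarzynski()],
#'   [overlap_coefficient()]
#' @export
work_set <- function(forward, reverse, pair_id = "pair",
                     leg = c("complex", "solvent"), temperature = 300,
                     forward_meta = NULL, reverse_meta = NULL) {
  leg <- match.arg(leg)
  stopifnot(is.numeric(forward), is.numeric(reverse),
            is.numeric(temperature), length(temperature) == 1, temperature > 0)
  if (any(!is.finite(forward)) || any(!is.finite(reverse)))
    neqfe_stop("work values must be finite")
  mk_meta <- function(n, meta, direction) {
    if (is.null(meta)) {
      meta <- data.frame(replica_id = rep(1L, n),
                         snapshot_time_ps = rep(NA_real_, n),
                         completed = rep(TRUE, n))
    }
    meta <- as.data.frame(meta)
    need <- c("replica_id", "snapshot_time_ps", "completed")
    miss <- setdiff(need, names(meta))
    for (m in miss) {
      meta[[m]] <- switch(m, replica_id = 1L, snapshot_time_ps = NA_real_,
                          completed = TRUE)
    }
    if (nrow(meta) != n)
      neqfe_stop(sprintf("%s metadata has %d rows for %d samples",
                         direction, nrow(meta), n))
    meta$completed <- as.logical(meta$completed)
    if (anyNA(meta$completed)) neqfe_stop("completed flags must be TRUE/FALSE")
    meta[need]
  }
  fm <- mk_meta(length(forward), forward_meta, "forward")
  rm_ <- mk_meta(length(reverse), reverse_meta, "reverse")
  structure(list(
    pair_id = pair_id, leg = leg, temperature = temperature,
    forward = cbind(data.frame(work = as.numeric(forward)), fm),
    reverse = cbind(data.frame(work = as.numeric(reverse)), rm_)
  ), class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("<work_set> pair %s, %s leg, T = %g K\n",
              x$pair_id, x$leg, x$temperature))
  cat(sprintf("  forward: %d samples (%d completed)\n",
              nrow(x$forward), sum(x$forward$completed)))
  cat(sprintf("  reverse: %d samples (%d completed)\n",
              nrow(x$reverse), sum(x$reverse$completed)))
  invisible(x)
}

# completed work values for one direction; reverse optionally negated so both
# directions live on the forward-work axis
completed_works <- function(ws, direction = c("forward", "reverse"),
                            negate_reverse = FALSE) {
  direction <- match.arg(direction)
  d <- ws[[direction]]
  w <- d$work[d$completed]
  if (direction == "reverse" && negate_reverse) -w else w
}

n_excluded <- function(ws) {
  sum(!ws$forward$completed) + sum(!ws$reverse$completed)
}

assert_work_set <- function(ws) {
  if (!inherits(ws, "work_set")) neqfe_stop("expected a work_set object")
  invisible(ws)
}

#' Subset a work set by source snapshot time
#'
#' Keeps only transitions initiated from snapshots taken at or before `t`
#' (both directions). Used by [time_dependent_estimate()].
#'
#' @param ws a [work_set].
#' @param t upper snapshot time bound in ps.
#' @return a `work_set` with the retained samples.
#' @export
filter_by_time <- function(ws, t) {
  assert_work_set(ws)
  take <- function(d) d[!is.na(d$snapshot_time_ps) & d$snapshot_time_ps <= t, ,
                        drop = FALSE]
  f <- take(ws$forward); r <- take(ws$reverse)
  if (nrow(f) == 0 || nrow(r) == 0)
    neqfe_stop(sprintf("no samples with snapshot_time_ps <= %g in both directions", t))
  work_set(f$work, r$work, ws$pair_id, ws$leg, ws$temperature,
           forward_meta = f[-1], reverse_meta = r[-1])
}

#' A free energy estimate with provenance
#'
#' Container for a single free energy difference: the value, its
#' uncertainty (bootstrap standard error unless stated otherwise), which
#' estimator produced it, how many samples per direction were used (failed
#' transitions excluded), and whether the solver converged.
#'
#' @param dg free energy difference in kcal/mol.
#' @param uncertainty standard error in kcal/mol; `NA` when not computed.
#' @param estimator one of `"jarzynski_f"`, `"jarzynski_r"`, `"cgi"`,
#'   `"bar"`, `"ti"`.
#' @param n_forward,n_reverse numbers of completed samples used.
#' @param n_excluded number of samples excluded as failed.
#' @param temperature kelvin.
#' @param converged logical solver status.
#' @return an object of class `fe_estimate`.
#' @export
fe_estimate <- function(dg, uncertainty = NA_real_, estimator,
                        n_forward = 0L, n_reverse = 0L, n_excluded = 0L,
                        temperature = 300, converged = TRUE) {
  if (!is.na(uncertainty) && uncertainty < 0)
    neqfe_stop("uncertainty must be >= 0")
  structure(list(dg = dg, uncertainty = uncertainty, estimator = estimator,
                 n_forward = as.integer(n_forward),
                 n_reverse = as.integer(n_reverse),
                 n_excluded = as.integer(n_excluded),
                 temperature = temperature, converged = isTRUE(converged)),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  u <- if (is.na(x$uncertainty)) "" else sprintf(" +/- %.3f", x$uncertainty)
  cat(sprintf("dG = %.4f%s kcal/mol  [%s, n_f = %d, n_r = %d%s%s]\n",
              x$dg, u, x$estimator, x$n_forward, x$n_reverse,
              if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else "",
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
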