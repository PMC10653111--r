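#' dH/dlambda sample table
#'
#' Validates and classes a long-format table of equilibrium energy-derivative
#' samples: one row per sample with columns `pair_id`, `leg`, `replica_id`,
#' `lambda` and `dhdl` (kcal/mol). The lambda values must form a finite grid
#' including both end points 0 and 1.
#'
#' @param df a data frame with the columns above.
#' @return the table with class `dhdl_table`.
#' @export
dhdl_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("pair_id", "leg", "replica_id", "lambda", "dhdl")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    neqfe_stop(paste("dhdl table missing columns:", paste(miss, collapse = ", ")))
  if (any(!is.finite(df$lambda)) || any(df$lambda < 0 | df$lambda > 1))
    neqfe_stop("lambda values must be finite and in [0, 1]")
  if (any(!is.finite(df$dhdl))) neqfe_stop("dhdl values must be finite")
  class(df) <- c("dhdl_table", "data.frame")
  df
}

# per-window mean and SEM, pooled across replicas (or for one replica)
window_stats <- function(df) {
  lam <- sort(unique(df$lambda))
  agg <- lapply(lam, function(l) {
    x <- df$dhdl[df$lambda == l]
    data.frame(lambda = l, mean = mean(x), n = length(x),
               sem = if (length(x) > 1) sd(x) / sqrt(length(x)) else 0)
  })
  do.call(rbind, agg)
}

# composite trapezoid weights for a (possibly uneven) sorted grid
trapezoid_weights <- function(lambda) {
  n <- length(lambda)
  w <- numeric(n)
  w[1] <- (lambda[2] - lambda[1]) / 2
  w[n] <- (lambda[n] - lambda[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (lambda[3:n] - lambda[1:(n - 2)]) / 2
  w
}

#' Thermodynamic integration over the lambda-window grid
#'
#' dG = integral over \[0, 1\] of the ensemble average dH/dlambda,
#' approximated by the composite trapezoid rule over the window grid of
#' per-window means (pooled across replicas). The uncertainty propagates
#' the per-window standard errors of the mean through the trapezoid weights,
#' treating windows as independent.
#'
#' @param table a [dhdl_table] for a single (pair, leg).
#' @return a [fe_estimate] with `estimator = "ti"`.
#' @examples
#' tab <- generate_dhdl(dhdl_spec(c(0, 0, 3), noise_sd = 0, seed = 1))
#' ti_estimate(tab) # trapezoid of 3 lambda^2 on 13 windows
#' @export
ti_estimate <- function(table) {
  if (!inherits(table, "dhdl_table")) table <- dhdl_table(table)
  ws <- window_stats(table)
  if (nrow(ws) < 2) neqfe_stop("TI requires at least 2 lambda windows")
  if (abs(ws$lambda[1]) > 1e-12 || abs(ws$lambda[nrow(ws)] - 1) > 1e-12)
    neqfe_stop("incomplete lambda grid: end points 0 and 1 are required")
  w <- trapezoid_weights(ws$lambda)
  fe_estimate(sum(w * ws$mean), uncertainty = sqrt(sum(w^2 * ws$sem^2)),
              estimator = "ti", n_forward = sum(ws$n),
              temperature = NA_real_)
}

#' Ensemble (TIES-style) thermodynamic integration
#'
#' Computes one TI estimate per replica plus the pooled estimate over all
#' samples. Under a balanced design (equal per-window sample counts in
#' every replica) the pooled dG equals the mean of the per-replica dG
#' values; the replica scatter is the basis of ensemble uncertainty
#' quantification.
#'
#' @param table a [dhdl_table] for a single (pair, leg).
#' @return a list with elements `pooled` (a [fe_estimate]) and
#'   `per_replica` (a named list of [fe_estimate], one per replica).
#' @export
ensemble_ti <- function(table) {
  if (!inherits(table, "dhdl_table")) table <- dhdl_table(table)
  reps <- sort(unique(table$replica_id))
  if (length(reps) < 1) neqfe_stop("ensemble_ti requires >= 1 replica")
  per <- lapply(reps, function(r)
    ti_estimate(table[table$replica_id == r, , drop = FALSE]))
  names(per) <- paste0("replica_", reps)
  list(pooled = ti_estimate(table), per_replica = per)
}
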