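#' Construct a lambda switching schedule
#'
#' Discretizes the alchemical path for a nonequilibrium transition of a
#' given total duration: lambda changes by `delta_lambda` after every
#' segment of equal duration, visiting `round(1 / delta_lambda) + 1` grid
#' points including both end points. A per-lambda duration below 2 ps is
#' known to destabilise switching simulations and raises an advisory
#' warning (code W002), never an error.
#'
#' @param total_duration_ps total transition duration in ps.
#' @param delta_lambda lambda step; `1 / delta_lambda` must be an integer.
#' @param direction `"forward"` (0 -> 1) or `"reverse"` (1 -> 0).
#' @return an object of class `lambda_schedule` with fields
#'   `total_duration`, `delta_lambda`, `n_points`, `per_lambda_duration`,
#'   `direction`, `lambda` (the grid).
#' @examples
#' make_lambda_schedule(2000, 0.002) # 501 points, 4 ps per lambda
#' @export
make_lambda_schedule <- function(total_duration_ps, delta_lambda,
                                 direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(total_duration_ps > 0, delta_lambda > 0, delta_lambda <= 1)
  inv <- 1 / delta_lambda
  if (abs(inv - round(inv)) > 1e-9)
    neqfe_stop(sprintf("1/delta_lambda = %g is not an integer", inv))
  n_points <- as.integer(round(inv)) + 1L
  per <- total_duration_ps / (n_points - 1L)
  # require equal per-lambda segments at full precision
  if (abs(per * (n_points - 1L) - total_duration_ps) > 1e-9)
    neqfe_stop("total duration does not divide into equal per-lambda segments")
  if (per < 2)
    neqfe_warn("W002", sprintf(
      "per-lambda duration %.3g ps is below the 2 ps stability threshold; transitions may fail", per))
  lam <- seq(0, 1, length.out = n_points)
  if (direction == "reverse") lam <- rev(lam)
  structure(list(total_duration = total_duration_ps,
                 delta_lambda = delta_lambda, n_points = n_points,
                 per_lambda_duration = per, direction = direction,
                 lambda = lam),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf(
    "<lambda_schedule> %s: %d points (delta = %g), %g ps per lambda, %g ps total\n",
    x$direction, x$n_points, x$delta_lambda, x$per_lambda_duration,
    x$total_duration))
  invisible(x)
}

#' Snapshot extraction schedule from ensemble equilibrium runs
#'
#' Distributes `n_snapshots` extraction points over `n_replicas` equilibrium
#' runs: each replica receives an equal quota (remainders assigned
#' round-robin to the first replicas), with extraction times evenly spaced
#' within the run and the final extraction at the end of the run, snapped to
#' the nearest saved-frame time (frames are written every
#' `frame_interval_ps`).
#'
#' @param n_replicas number of equilibrium replicas.
#' @param run_length_ps production run length per replica, ps.
#' @param n_snapshots total snapshots to extract.
#' @param frame_interval_ps trajectory frame save interval, ps.
#' @return a data frame of class `snapshot_schedule` with columns
#'   `replica_id`, `time_ps`.
#' @examples
#' make_snapshot_schedule(5, 10000, 100, 20) # 20 per replica, every 500 ps
#' @export
make_snapshot_schedule <- function(n_replicas, run_length_ps, n_snapshots,
                                   frame_interval_ps) {
  stopifnot(n_replicas >= 1, run_length_ps > 0, n_snapshots >= 1,
            frame_interval_ps > 0)
  frames_per_replica <- floor(run_length_ps / frame_interval_ps)
  quota <- rep(n_snapshots %/% n_replicas, n_replicas)
  rem <- n_snapshots %% n_replicas
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1L
  if (any(quota > frames_per_replica))
    neqfe_stop(sprintf(
      "requested %d snapshots from a replica with only %d saved frames",
      max(quota), frames_per_replica))
  rows <- lapply(seq_len(n_replicas), function(r) {
    k <- quota[r]
    if (k == 0) return(NULL)
    t_raw <- seq_len(k) * (run_length_ps / k)
    t_snap <- pmax(1, round(t_raw / frame_interval_ps)) * frame_interval_ps
    data.frame(replica_id = r, time_ps = pmin(t_snap, frames_per_replica *
                                                frame_interval_ps))
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out)) neqfe_stop("snapshot schedule contains duplicates")
  class(out) <- c("snapshot_schedule", "data.frame")
  out
}

#' Protocol specification for cost accounting
#'
#' Describes either an equilibrium (ensemble TI) protocol — replicas x
#' lambda windows x production per window — or a nonequilibrium protocol —
#' ensemble equilibrium runs at the two end points followed by switching
#' transitions in both directions. Defaults are the standard protocols:
#' equilibrium 5 replicas, 13 windows, 4 ns each; nonequilibrium 2 end
#' points x 5 replicas x 10 ns plus 2 directions x 100 transitions x 250 ps.
#'
#' @param method `"equilibrium"` or `"nonequilibrium"`.
#' @param n_replicas replicas (per lambda window, or per end point).
#' @param n_lambda_windows equilibrium only.
#' @param production_per_window_ns equilibrium only.
#' @param n_endpoints nonequilibrium only (2 for a thermodynamic leg).
#' @param eq_duration_per_replica_ns nonequilibrium only.
#' @param n_transitions_per_direction nonequilibrium only.
#' @param transition_length_ns nonequilibrium only.
#' @param n_directions nonequilibrium only (forward and reverse).
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(method = c("equilibrium", "nonequilibrium"),
                          n_replicas = 5, n_lambda_windows = 13,
                          production_per_window_ns = 4, n_endpoints = 2,
                          eq_duration_per_replica_ns = 10,
                          n_transitions_per_direction = 100,
                          transition_length_ns = 0.25, n_directions = 2) {
  method <- match.arg(method)
  stopifnot(n_replicas >= 1, n_lambda_windows >= 1, n_endpoints >= 1,
            n_transitions_per_direction >= 1, n_directions >= 1,
            production_per_window_ns > 0, eq_duration_per_replica_ns > 0,
            transition_length_ns > 0)
  structure(as.list(environment()), class = "protocol_spec")
}

#' Total production simulation time of a protocol
#'
#' Equilibrium: replicas x lambda windows x production per window.
#' Nonequilibrium: end points x replicas x equilibrium duration, plus
#' directions x transitions x transition length. All in ns of simulated
#' time; wall-clock time is hardware-specific and not computed.
#'
#' @param spec a [protocol_spec].
#' @return an object of class `cost_summary` with a per-stage breakdown
#'   (`stages`: data frame of `stage`, `ns`) and `total_ns`.
#' @examples
#' protocol_cost(protocol_spec("equilibrium"))$total_ns # 260
#' protocol_cost(protocol_spec("nonequilibrium"))$total_ns # 150
#' @export
protocol_cost <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  stages <- if (spec$method == "equilibrium") {
    data.frame(stage = "lambda_window_production",
               ns = spec$n_replicas * spec$n_lambda_windows *
                 spec$production_per_window_ns)
  } else {
    data.frame(
      stage = c("endpoint_equilibrium", "nonequilibrium_transitions"),
      ns = c(spec$n_endpoints * spec$n_replicas *
               spec$eq_duration_per_replica_ns,
             spec$n_directions * spec$n_transitions_per_direction *
               spec$transition_length_ns))
  }
  structure(list(method = spec$method, stages = stages,
                 total_ns = sum(stages$ns)),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("<cost_summary> %s protocol, total %g ns\n", x$method,
              x$total_ns))
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-28s %g ns\n", x$stages$stage[i], x$stages$ns[i]))
  invisible(x)
}

#' Advisory checks of a nonequilibrium protocol draft
#'
#' Compares a draft protocol against the recommended minima for reliable
#' nonequilibrium RBFE calculations: at least 5 equilibrium replicas per end
#' point, 10 ns equilibrium runs, 100 transitions per direction, 250 ps per
#' transition, and no less than 2 ps at each lambda value. Findings are
#' advisory (warning code W003), never blocking.
#'
#' @param n_replicas equilibrium replicas per end point.
#' @param eq_duration_ns equilibrium run duration per replica, ns.
#' @param n_transitions transitions per direction.
#' @param transition_length_ps switching transition duration, ps.
#' @param delta_lambda optional lambda step, used to check the per-lambda
#'   duration.
#' @param warn emit a W003 warning when findings are non-empty.
#' @return a data frame of findings (`parameter`, `value`, `recommended`,
#'   `message`); zero rows when the draft meets all recommendations.
#' @examples
#' recommend_protocol(5, 10, 100, 250) # no findings
#' @export
recommend_protocol <- function(n_replicas, eq_duration_ns, n_transitions,
                               transition_length_ps, delta_lambda = NULL,
                               warn = FALSE) {
  findings <- data.frame(parameter = character(), value = numeric(),
                         recommended = numeric(), message = character())
  add <- function(parameter, value, recommended, message)
    rbind(findings, data.frame(parameter = parameter, value = value,
                               recommended = recommended, message = message))
  if (n_replicas < 5)
    findings <- add("n_replicas", n_replicas, 5,
                    "ensemble size below the minimum of 5 replicas per end point")
  if (eq_duration_ns < 10)
    findings <- add("eq_duration_ns", eq_duration_ns, 10,
                    "equilibrium end-point runs shorter than the recommended 10 ns")
  if (n_transitions < 100)
    findings <- add("n_transitions", n_transitions, 100,
                    "fewer than 100 transitions per direction")
  if (transition_length_ps < 250)
    findings <- add("transition_length_ps", transition_length_ps, 250,
                    "transitions shorter than the recommended 250 ps")
  if (!is.null(delta_lambda)) {
    per <- transition_length_ps * delta_lambda
    if (per < 2)
      findings <- add("per_lambda_ps", per, 2,
                      "less than 2 ps at each lambda value; switching runs may fail")
  }
  if (warn && nrow(findings) > 0)
    neqfe_warn("W003", paste("protocol below recommendations:",
                             paste(findings$parameter, collapse = ", ")))
  findings
}
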