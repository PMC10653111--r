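#' Specification of a synthetic Crooks-consistent work distribution
#'
#' Describes a pair of forward/reverse work distributions that satisfy the
#' Crooks fluctuation theorem P_f(W) / P_r(-W) = exp(beta (W - dG)) by
#' construction, at a stated temperature. Two shapes are supported:
#' `"gaussian"` (equal-variance normal work distributions, the analytically
#' solvable case) and `"skew_mixture"` (a Gaussian-mixture forward density,
#' emulating the skewed, asymmetric, fat-tailed work distributions seen in
#' real switching simulations; the reverse density is derived analytically
#' from the fluctuation theorem).
#'
#' @param true_dg the exact free energy difference in kcal/mol.
#' @param sigma_f,sigma_r standard deviations of the forward and
#'   negated-reverse work distributions (kcal/mol). The Gaussian shape
#'   requires `sigma_f == sigma_r` for exact closure of the theorem.
#' @param n_forward,n_reverse sample counts per direction.
#' @param temperature kelvin.
#' @param shape `"gaussian"` or `"skew_mixture"`.
#' @param mixture_params for `"skew_mixture"`: a data frame (or list of
#'   3-vectors) with columns `weight`, `offset`, `sd` describing the forward
#'   Gaussian mixture. Offsets fix the shape only; the mixture is rigidly
#'   shifted so that the exact Jarzynski average reproduces `true_dg`.
#' @param seed integer RNG seed.
#' @param n_replicas,run_length_ps provenance emulation: samples are
#'   attributed round-robin to replicas, with snapshot times evenly spaced
#'   over each replica's equilibrium run.
#' @param failure_rate fraction of transitions flagged as failed
#'   (terminated before the final lambda state), drawn independently.
#' @return an object of class `crooks_spec`.
#' @export
crooks_spec <- function(true_dg, sigma_f, sigma_r = sigma_f,
                        n_forward, n_reverse = n_forward, temperature = 300,
                        shape = c("gaussian", "skew_mixture"),
                        mixture_params = NULL, seed = 1L,
                        n_replicas = 5L, run_length_ps = 10000,
                        failure_rate = 0) {
  shape <- match.arg(shape)
  stopifnot(sigma_f > 0, sigma_r > 0, n_forward >= 1, n_reverse >= 1,
            temperature > 0, failure_rate >= 0, failure_rate < 1,
            n_replicas >= 1, run_length_ps > 0)
  if (shape == "skew_mixture") {
    if (is.null(mixture_params)) neqfe_stop("skew_mixture requires mixture_params")
    mixture_params <- as_mixture(mixture_params)
    if (abs(sum(mixture_params$weight) - 1) > 1e-8)
      neqfe_stop("mixture weights must sum to 1")
    if (any(mixture_params$sd <= 0)) neqfe_stop("mixture sds must be > 0")
  }
  structure(list(true_dg = true_dg, sigma_f = sigma_f, sigma_r = sigma_r,
                 n_forward = as.integer(n_forward),
                 n_reverse = as.integer(n_reverse),
                 temperature = temperature, shape = shape,
                 mixture_params = mixture_params, seed = as.integer(seed),
                 n_replicas = as.integer(n_replicas),
                 run_length_ps = run_length_ps, failure_rate = failure_rate),
            class = "crooks_spec")
}

as_mixture <- function(mp) {
  if (is.data.frame(mp)) {
    stopifnot(all(c("weight", "offset", "sd") %in% names(mp)))
    return(mp[c("weight", "offset", "sd")])
  }
  m <- do.call(rbind, lapply(mp, function(x) as.numeric(x[1:3])))
  data.frame(weight = m[, 1], offset = m[, 2], sd = m[, 3])
}

# provenance metadata shared by both generators: replica round-robin and
# evenly spaced snapshot times within each replica's run
synth_meta <- function(n, n_replicas, run_length_ps, failure_rate) {
  replica <- rep_len(seq_len(n_replicas), n)
  k <- tabulate(replica, n_replicas)
  time <- numeric(n)
  for (r in seq_len(n_replicas)) {
    idx <- which(replica == r)
    time[idx] <- seq_along(idx) * (run_length_ps / k[r])
  }
  completed <- if (failure_rate > 0) runif(n) >= failure_rate else rep(TRUE, n)
  data.frame(replica_id = replica, snapshot_time_ps = time,
             completed = completed)
}

#' Generate Gaussian work samples satisfying the Crooks theorem
#'
#' With equal spread sigma in the two directions, the fluctuation theorem is
#' closed exactly by Gaussian work distributions: forward work is
#' N(dG + beta sigma^2 / 2, sigma) and negated-reverse work is
#' N(dG - beta sigma^2 / 2, sigma); beta sigma^2 / 2 is the mean dissipated
#' work. Reverse samples are stored in the as-measured (1 -> 0) sign
#' convention, i.e. negated.
#'
#' @param spec a [crooks_spec] with `shape = "gaussian"` and
#'   `sigma_f == sigma_r`.
#' @return a [work_set].
#' @examples
#' ws <- generate_crooks_gaussian(crooks_spec(1, 1, n_forward = 100, seed = 7))
#' bar(ws)
#' @export
generate_crooks_gaussian <- function(spec) {
  stopifnot(inherits(spec, "crooks_spec"))
  if (spec$shape != "gaussian") neqfe_stop("spec shape must be 'gaussian'")
  if (abs(spec$sigma_f - spec$sigma_r) > 1e-12)
    neqfe_stop("gaussian shape requires sigma_f == sigma_r for exact Crooks closure")
  b <- beta_of(spec$temperature)
  s <- spec$sigma_f
  diss <- b * s^2 / 2
  with_seed(spec$seed, {
    wf <- rnorm(spec$n_forward, spec$true_dg + diss, s)
    wr_neg <- rnorm(spec$n_reverse, spec$true_dg - diss, s)
    fm <- synth_meta(spec$n_forward, spec$n_replicas, spec$run_length_ps,
                     spec$failure_rate)
    rm_ <- synth_meta(spec$n_reverse, spec$n_replicas, spec$run_length_ps,
                      spec$failure_rate)
    work_set(wf, -wr_neg, pair_id = "synthetic", leg = "complex",
             temperature = spec$temperature, forward_meta = fm,
             reverse_meta = rm_)
  })
}

# exact mixture pair closing the Crooks theorem at spec$true_dg:
# forward density sum_i w_i N(mu_i, s_i) (rigidly shifted so that
# -kT log <exp(-beta W)>_f = true_dg); negated-reverse density obtained by
# multiplying by exp(-beta (W - dG)), which maps each Gaussian component to
# N(mu_i - beta s_i^2, s_i) with reweighted weight w_i exp(-beta mu_i +
# beta^2 s_i^2 / 2) (normalized). Always normalizable for Gaussian
# components.
mixture_pair <- function(spec) {
  b <- beta_of(spec$temperature)
  mp <- spec$mixture_params
  mu_raw <- spec$true_dg + mp$offset
  # log <exp(-beta W)> for the raw mixture, stably
  lz <- logsumexp(log(mp$weight) - b * mu_raw + b^2 * mp$sd^2 / 2)
  # shift so -kT * log Z(shifted) = true_dg, i.e. lz_shift = -b * true_dg
  shift <- (lz + b * spec$true_dg) / b
  mu_f <- mu_raw + shift
  lw_r <- log(mp$weight) - b * mu_f + b^2 * mp$sd^2 / 2
  w_r <- exp(lw_r - logsumexp(lw_r))
  list(forward = data.frame(weight = mp$weight, mean = mu_f, sd = mp$sd),
       reverse_neg = data.frame(weight = w_r, mean = mu_f - b * mp$sd^2,
                                sd = mp$sd))
}

sample_mixture <- function(n, mix) {
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  rnorm(n, mix$mean[comp], mix$sd[comp])
}

# analytic central moments of a Gaussian mixture
mixture_moments <- function(mix) {
  m1 <- sum(mix$weight * mix$mean)
  m2 <- sum(mix$weight * (mix$mean^2 + mix$sd^2))
  m3 <- sum(mix$weight * (mix$mean^3 + 3 * mix$mean * mix$sd^2))
  m4 <- sum(mix$weight * (mix$mean^4 + 6 * mix$mean^2 * mix$sd^2 + 3 * mix$sd^4))
  c2 <- m2 - m1^2
  c3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  c4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  list(mean = m1, var = c2, skewness = c3 / c2^1.5,
       excess_kurtosis = c4 / c2^2 - 3)
}

#' Generate skewed/multimodal work samples satisfying the Crooks theorem
#'
#' The forward work density is the requested Gaussian mixture; the reverse
#' density is derived exactly from the fluctuation theorem (for Gaussian
#' components it is again a Gaussian mixture with analytically reweighted
#' weights and shifted means) and sampled exactly, with no rejection step.
#' The forward mixture is rigidly shifted so that the implied free energy
#' difference equals `true_dg` exactly; `mixture_params$offset` therefore
#' controls shape (skewness, multimodality), not the location.
#'
#' @param spec a [crooks_spec] with `shape = "skew_mixture"`.
#' @return a [work_set].
#' @export
generate_crooks_mixture <- function(spec) {
  stopifnot(inherits(spec, "crooks_spec"))
  if (spec$shape != "skew_mixture") neqfe_stop("spec shape must be 'skew_mixture'")
  pair <- mixture_pair(spec)
  with_seed(spec$seed, {
    wf <- sample_mixture(spec$n_forward, pair$forward)
    wr_neg <- sample_mixture(spec$n_reverse, pair$reverse_neg)
    fm <- synth_meta(spec$n_forward, spec$n_replicas, spec$run_length_ps,
                     spec$failure_rate)
    rm_ <- synth_meta(spec$n_reverse, spec$n_replicas, spec$run_length_ps,
                      spec$failure_rate)
    work_set(wf, -wr_neg, pair_id = "synthetic", leg = "complex",
             temperature = spec$temperature, forward_meta = fm,
             reverse_meta = rm_)
  })
}

#' Work-distribution width as a function of transition duration
#'
#' Longer switching transitions dissipate less work, narrowing the forward
#' and reverse work distributions. This helper models the width as
#' `sigma_ref * (tau_ref / tau)^exponent` so that duration-dependent work
#' sets can be generated; the default square-root exponent corresponds to
#' near-equilibrium (linear-response) switching.
#'
#' @param sigma_ref width at the reference duration (kcal/mol).
#' @param tau transition duration (ps).
#' @param tau_ref reference duration (ps).
#' @param exponent decay exponent, default 0.5.
#' @return sigma at duration `tau`.
#' @export
dissipation_sigma <- function(sigma_ref, tau, tau_ref, exponent = 0.5) {
  stopifnot(sigma_ref > 0, all(tau > 0), tau_ref > 0)
  sigma_ref * (tau_ref / tau)^exponent
}

#' Specification of a synthetic dH/dlambda table
#'
#' @param profile_coefficients polynomial coefficients (increasing powers)
#'   of the true ensemble-average dH/dlambda curve, kcal/mol.
#' @param n_windows number of lambda windows spanning \[0, 1\] (default 13,
#'   the standard TIES grid).
#' @param n_replicas replicas per window.
#' @param samples_per_window samples per (replica, window) cell.
#' @param noise_sd per-sample Gaussian noise sd, kcal/mol.
#' @param seed integer RNG seed.
#' @return an object of class `dhdl_spec`.
#' @export
dhdl_spec <- function(profile_coefficients, n_windows = 13L, n_replicas = 5L,
                      samples_per_window = 200L, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_windows >= 2, n_replicas >= 1, samples_per_window >= 1,
            noise_sd >= 0)
  structure(list(profile_coefficients = as.numeric(profile_coefficients),
                 n_windows = as.integer(n_windows),
                 n_replicas = as.integer(n_replicas),
                 samples_per_window = as.integer(samples_per_window),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dhdl_spec")
}

#' Generate synthetic per-window dH/dlambda samples
#'
#' Emulates the equilibrium arm: at each lambda on an even grid over
#' \[0, 1\], every replica contributes `samples_per_window` draws equal to
#' the polynomial profile at lambda plus independent Gaussian noise.
#'
#' @param spec a [dhdl_spec].
#' @return a `dhdl_table` data frame with columns `pair_id`, `leg`,
#'   `replica_id`, `lambda`, `dhdl`.
#' @export
generate_dhdl <- function(spec) {
  stopifnot(inherits(spec, "dhdl_spec"))
  lam <- seq(0, 1, length.out = spec$n_windows)
  grid <- expand.grid(replica_id = seq_len(spec$n_replicas), lambda = lam,
                      sample = seq_len(spec$samples_per_window))
  mu <- polyval_inc(spec$profile_coefficients, grid$lambda)
  val <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) mu + rnorm(nrow(grid), 0, spec$noise_sd) else mu
  })
  dhdl_table(data.frame(pair_id = "synthetic", leg = "complex",
                        replica_id = grid$replica_id, lambda = grid$lambda,
                        dhdl = val))
}

#' Generate a pool of per-replica free energy values
#'
#' Emulates the spread of dG values obtained from independent replica
#' simulations of the same system; either Gaussian or a Gaussian mixture
#' (for bimodal/skewed ensembles).
#'
#' @param n_replicas pool size.
#' @param mean,sd Gaussian law parameters (kcal/mol); ignored when
#'   `mixture` is supplied (the mixture is centred at `mean + offset`).
#' @param mixture optional data frame `weight`, `offset`, `sd`.
#' @param seed integer RNG seed.
#' @return a numeric vector of class `ensemble_pool`.
#' @export
generate_replica_pool <- function(n_replicas, mean = 0, sd = 1,
                                  mixture = NULL, seed = 1L) {
  stopifnot(n_replicas >= 1, sd >= 0)
  x <- with_seed(seed, {
    if (is.null(mixture)) rnorm(n_replicas, mean, sd)
    else {
      mix <- as_mixture(mixture)
      sample_mixture(n_replicas, data.frame(weight = mix$weight,
                                            mean = mean + mix$offset,
                                            sd = mix$sd))
    }
  })
  structure(x, class = "ensemble_pool")
}

#' Specification of a synthetic prediction-vs-experiment benchmark
#'
#' Emulates the empirical inverse relation between prediction accuracy and
#' the forward/reverse work-distribution overlap: each pair draws an overlap
#' coefficient, a true ddG, and a calculated ddG whose error sd is
#' `prediction_noise_fn(overlap)`, a decreasing function.
#'
#' @param n_pairs number of ligand pairs (default 503).
#' @param ddg_range range (lo, hi) of true ddG values, kcal/mol.
#' @param prediction_noise_fn maps overlap in \[0,1\] to the prediction
#'   error sd in kcal/mol; must be non-increasing.
#' @param experimental_noise_sd sd of experimental measurement noise.
#' @param overlap_sampler function(n) returning n overlaps in \[0,1\];
#'   the default places a point mass at exactly zero (pairs with disjoint
#'   work distributions) and is uniform otherwise.
#' @param n_targets number of protein targets to label pairs with.
#' @param seed integer RNG seed.
#' @return an object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_pairs = 503L, ddg_range = c(-3, 3),
                           prediction_noise_fn = function(ov) 2.5 * (1 - ov) + 0.3,
                           experimental_noise_sd = 0.4,
                           overlap_sampler = function(n)
                             ifelse(runif(n) < 0.06, 0, runif(n)),
                           n_targets = 14L, seed = 1L) {
  stopifnot(n_pairs >= 1, length(ddg_range) == 2, ddg_range[1] <= ddg_range[2],
            experimental_noise_sd >= 0, is.function(prediction_noise_fn),
            is.function(overlap_sampler), n_targets >= 1)
  structure(list(n_pairs = as.integer(n_pairs), ddg_range = ddg_range,
                 prediction_noise_fn = prediction_noise_fn,
                 experimental_noise_sd = experimental_noise_sd,
                 overlap_sampler = overlap_sampler,
                 n_targets = as.integer(n_targets), seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a synthetic benchmark table
#'
#' @param spec a [benchmark_spec].
#' @return a `benchmark_table` data frame with columns `pair_id`,
#'   `target_name`, `ddg_cal`, `ddg_exp`, `overlap`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, {
    ov <- spec$overlap_sampler(spec$n_pairs)
    if (any(ov < 0 | ov > 1)) neqfe_stop("sampled overlaps must lie in [0, 1]")
    true <- runif(spec$n_pairs, spec$ddg_range[1], spec$ddg_range[2])
    sd_pred <- spec$prediction_noise_fn(ov)
    if (any(sd_pred < 0)) neqfe_stop("prediction noise sd must be >= 0")
    cal <- true + rnorm(spec$n_pairs, 0, 1) * sd_pred
    exp_ <- true + if (spec$experimental_noise_sd > 0)
      rnorm(spec$n_pairs, 0, spec$experimental_noise_sd) else 0
    benchmark_table(data.frame(
      pair_id = sprintf("pair_%04d", seq_len(spec$n_pairs)),
      target_name = sprintf("target_%02d",
                            rep_len(seq_len(spec$n_targets), spec$n_pairs)),
      ddg_cal = cal, ddg_exp = exp_, overlap = ov))
  })
}
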