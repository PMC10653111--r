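# shared fixture builders -- all synthetic, generated at test time

# shortcut: Gaussian Crooks work set with exact known dG
gauss_ws <- function(true_dg, sigma, n, seed, temperature = 300, ...) {
  generate_crooks_gaussian(crooks_spec(
    true_dg, sigma, n_forward = n, n_reverse = n, temperature = temperature,
    seed = seed, ...))
}

# bare work set from explicit forward / as-measured reverse values
ws_of <- function(forward, reverse, ...) work_set(forward, reverse, ...)

BETA300 <- 1 / (0.0019872041 * 300)

# analytic central moments of a Gaussian mixture (independent oracle used
# by shape/skewness tests; plain textbook formulas)
mix_moments_oracle <- function(weight, mean, sd) {
  m1 <- sum(weight * mean)
  m2 <- sum(weight * (mean^2 + sd^2))
  m3 <- sum(weight * (mean^3 + 3 * mean * sd^2))
  c2 <- m2 - m1^2
  c3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  list(mean = m1, var = c2, skewness = c3 / c2^1.5)
}

# benchmark table with prescribed per-bin counts of |error| > threshold;
# overlaps placed at representative points of each bin
binned_benchmark <- function(n_zero, bad_zero, n_mid, bad_mid, n_high,
                             bad_high, threshold = 2) {
  mk <- function(n, bad, ov) {
    err <- c(rep(threshold + 1, bad), rep(threshold / 2, n - bad))
    data.frame(ddg_exp = 0, ddg_cal = err, overlap = ov)
  }
  df <- rbind(mk(n_zero, bad_zero, 0), mk(n_mid, bad_mid, 0.25),
              mk(n_high, bad_high, 0.75))
  df$pair_id <- seq_len(nrow(df))
  benchmark_table(df)
}
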