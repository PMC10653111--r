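test_that("Gaussian generator places the work means at dG +/- beta sigma^2 / 2", {
  n <- 1e6
  ws <- gauss_ws(0, 1, n, seed = 101)
  diss <- BETA300 / 2 # beta sigma^2 / 2 with sigma = 1
  tol <- 3 / sqrt(n) # 3 sigma / sqrt(n)
  expect_lt(abs(mean(ws$forward$work) - diss), tol)
  expect_lt(abs(mean(-ws$reverse$work) + diss), tol)
  expect_equal(ws$temperature, 300)
  expect_equal(nrow(ws$forward), n)
})

test_that("zero-dissipation limit collapses both directions onto the true dG", {
  ws <- gauss_ws(1.5, 1e-6, 50, seed = 7)
  expect_true(all(abs(ws$forward$work - 1.5) < 1e-4))
  expect_true(all(abs(-ws$reverse$work - 1.5) < 1e-4))
})

test_that("generators reject invalid Crooks specifications", {
  expect_error(crooks_spec(0, sigma_f = -1, n_forward = 10), "sigma")
  expect_error(crooks_spec(0, 1, n_forward = 0), "n_forward")
  expect_error(generate_crooks_gaussian(
    crooks_spec(0, sigma_f = 1, sigma_r = 2, n_forward = 10)),
    "sigma_f == sigma_r")
  expect_error(crooks_spec(0, 1, n_forward = 10, shape = "skew_mixture"),
               "mixture_params")
  expect_error(crooks_spec(0, 1, n_forward = 10, shape = "skew_mixture",
                           mixture_params = data.frame(weight = c(0.5, 0.2),
                                                       offset = c(0, 1),
                                                       sd = c(1, 1))),
               "sum to 1")
})

test_that("generators are deterministic given spec and seed", {
  a <- gauss_ws(1, 1, 500, seed = 42)
  b <- gauss_ws(1, 1, 500, seed = 42)
  expect_identical(a, b)
  mp <- data.frame(weight = c(0.7, 0.3), offset = c(-1, 2), sd = c(0.5, 0.8))
  sp <- crooks_spec(0, 1, n_forward = 500, shape = "skew_mixture",
                    mixture_params = mp, seed = 9)
  expect_identical(generate_crooks_mixture(sp), generate_crooks_mixture(sp))
})

test_that("single-component mixture reproduces the Gaussian generator family", {
  # one component with offset beta sigma^2 / 2 is exactly the Gaussian case:
  # after the internal normalization shift the forward density must be
  # N(dG + beta sigma^2 / 2, sigma)
  s <- 0.8
  mp <- data.frame(weight = 1, offset = 0, sd = s)
  sp <- crooks_spec(0.5, s, n_forward = 2e4, shape = "skew_mixture",
                    mixture_params = mp, seed = 11)
  ws <- generate_crooks_mixture(sp)
  diss <- BETA300 * s^2 / 2
  expect_lt(abs(mean(ws$forward$work) - (0.5 + diss)), 3 * s / sqrt(2e4))
  expect_lt(abs(sd(ws$forward$work) - s), 0.02)
  expect_lt(abs(mean(-ws$reverse$work) - (0.5 - diss)), 3 * s / sqrt(2e4))
})

test_that("well-separated mixture components produce visibly skewed work", {
  mp <- data.frame(weight = c(0.8, 0.2), offset = c(0, 3), sd = c(0.5, 0.5))
  sp <- crooks_spec(0, 1, n_forward = 2e4, shape = "skew_mixture",
                    mixture_params = mp, seed = 13)
  ws <- generate_crooks_mixture(sp)
  sh <- distribution_shape(ws$forward$work)
  expect_gt(abs(sh$skewness), 0.2)
  # the sample skewness should agree with the analytic mixture skewness;
  # the internal shift leaves central moments untouched
  oracle <- mix_moments_oracle(mp$weight, mp$offset, mp$sd)
  expect_lt(abs(sh$skewness - oracle$skewness), 3 * sqrt(6 / 2e4) * 3)
})

test_that("both generators close the Crooks fluctuation theorem", {
  # slope of the log density ratio = beta; intercept = -beta dG
  ws <- gauss_ws(0.5, 1, 5e4, seed = 17)
  fs <- fluctuation_slope(ws)
  expect_lt(abs(fs$slope - BETA300) / BETA300, 0.05)
  expect_lt(abs(fs$intercept - (-BETA300 * 0.5)) / (BETA300 * 0.5), 0.1)
  mp <- data.frame(weight = c(0.6, 0.4), offset = c(-1, 1.5), sd = c(0.6, 0.9))
  wm <- generate_crooks_mixture(crooks_spec(
    0.5, 1, n_forward = 5e4, shape = "skew_mixture", mixture_params = mp,
    seed = 19))
  fm <- fluctuation_slope(wm)
  expect_lt(abs(fm$slope - BETA300) / BETA300, 0.05)
})

test_that("dissipation width shrinks with transition duration", {
  s <- dissipation_sigma(2, tau = c(50, 250, 2000), tau_ref = 250)
  expect_equal(s[2], 2)
  expect_true(all(diff(s) < 0))
  expect_equal(dissipation_sigma(2, 1000, 250), 1) # sqrt(1/4)
})

test_that("dhdl generator reproduces the requested profile", {
  # constant, noiseless
  tab <- generate_dhdl(dhdl_spec(4.2, n_windows = 5, n_replicas = 2,
                                 samples_per_window = 3, noise_sd = 0))
  expect_true(all(tab$dhdl == 4.2))
  # 3 lambda^2 over 13 windows, noiseless: window means hit the polynomial
  tab2 <- generate_dhdl(dhdl_spec(c(0, 0, 3), noise_sd = 0))
  means <- tapply(tab2$dhdl, tab2$lambda, mean)
  lam <- as.numeric(names(means))
  expect_equal(length(lam), 13)
  expect_equal(as.numeric(means), 3 * (0:12 / 12)^2, tolerance = 1e-12)
  # with noise: window means within 3 standard errors
  sp <- dhdl_spec(c(0, 0, 3), n_replicas = 5, samples_per_window = 200,
                  noise_sd = 0.5, seed = 23)
  tab3 <- generate_dhdl(sp)
  m3 <- tapply(tab3$dhdl, tab3$lambda, mean)
  se <- 0.5 / sqrt(5 * 200)
  expect_true(all(abs(m3 - 3 * (0:12 / 12)^2) < 3 * se + 1e-12))
})

test_that("replica pool generator honours its law", {
  expect_true(all(generate_replica_pool(10, mean = 2, sd = 0) == 2))
  p <- generate_replica_pool(20, 0, 1, seed = 29)
  expect_lt(abs(mean(p)), 3 / sqrt(20))
  # bimodal mixture: mass on each side of the midpoint matches the weights
  mix <- data.frame(weight = c(0.5, 0.5), offset = c(-4, 4), sd = c(0.5, 0.5))
  big <- generate_replica_pool(1e4, 0, 1, mixture = mix, seed = 31)
  frac_low <- mean(big < 0)
  expect_lt(abs(frac_low - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("benchmark generator wires overlap into prediction accuracy", {
  # zero noise: calculated equals experimental for every pair
  sp0 <- benchmark_spec(n_pairs = 50, prediction_noise_fn = function(ov) 0,
                        experimental_noise_sd = 0, seed = 37)
  tb0 <- generate_benchmark(sp0)
  expect_equal(tb0$ddg_cal, tb0$ddg_exp)
  # decreasing noise function: high-overlap pairs are more accurate
  sp <- benchmark_spec(n_pairs = 500, experimental_noise_sd = 0, seed = 41)
  tb <- generate_benchmark(sp)
  err <- abs(tb$ddg_cal - tb$ddg_exp)
  expect_lt(mean(err[tb$overlap > 0.5]), mean(err[tb$overlap == 0]))
  # determinism: byte-identical tables at a fixed seed
  expect_identical(tb, generate_benchmark(sp))
})
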