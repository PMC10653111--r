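test_that("overlap coefficient hits its exact limits", {
  x <- rnorm(500, 1, 0.5)
  expect_identical(overlap_coefficient(ws_of(x, -x))$overlap, 1)
  far <- ws_of(runif(200), -(100 + runif(200)))
  expect_warning(ov <- overlap_coefficient(far), class = "neqfe_w001")
  expect_identical(ov$overlap, 0)
  expect_true(ov$low_overlap_warning)
})

test_that("overlap matches the Gaussian closed form 2 Phi(-|dmu|/2 sigma)", {
  set.seed(307)
  ws <- ws_of(rnorm(2e4, 0, 1), -rnorm(2e4, 2, 1))
  expect_lt(abs(overlap_coefficient(ws)$overlap - 2 * pnorm(-1)), 0.03)
})

test_that("overlap is symmetric and shift invariant", {
  set.seed(311)
  a <- rnorm(3000, 0, 1); b <- rnorm(3000, 1, 1.5)
  o1 <- overlap_coefficient(ws_of(a, -b))$overlap
  o2 <- overlap_coefficient(ws_of(b, -a))$overlap
  expect_equal(o1, o2)
  o3 <- overlap_coefficient(ws_of(a + 7, -(b + 7)))$overlap
  expect_equal(o1, o3, tolerance = 1e-12)
})

test_that("accuracy-overlap binning reproduces hand counts", {
  tab <- binned_benchmark(30, 19, 279, 53, 194, 5)
  out <- accuracy_overlap_binning(tab)
  expect_equal(out$n_pairs, c(30, 279, 194))
  expect_equal(out$n_exceeding, c(19, 53, 5))
  expect_equal(round(out$percentage, 1), c(63.3, 19.0, 2.6))
  # all-accurate table
  good <- benchmark_table(data.frame(pair_id = 1:6, ddg_cal = 0, ddg_exp = 0,
                                     overlap = c(0, 0, 0.3, 0.3, 0.8, 0.8)))
  expect_equal(accuracy_overlap_binning(good)$percentage, c(0, 0, 0))
  # 6-row table spanning all bins, against direct enumeration
  six <- benchmark_table(data.frame(
    pair_id = 1:6, ddg_exp = 0, ddg_cal = c(3, 1, 2.5, 0.5, 2.1, 0.1),
    overlap = c(0, 0, 0.2, 0.5, 0.9, 0.6)))
  o6 <- accuracy_overlap_binning(six)
  expect_equal(o6$n_pairs, c(2, 2, 2))
  expect_equal(o6$n_exceeding, c(1, 1, 1))
  expect_error(accuracy_overlap_binning(six[0, ]), "empty")
})

test_that("replica-increment bootstrap: degenerate, equivariance and oracle", {
  # identical values: statistic and CI collapse to zero
  flat <- replica_increment_bootstrap(rep(1.3, 6), n_boot = 100, seed = 1)
  expect_true(all(flat$statistic == 0))
  expect_true(all(flat$ci_low == 0 & flat$ci_high == 0))
  pool <- generate_replica_pool(12, 0, 1, seed = 313)
  cv <- replica_increment_bootstrap(pool, n_boot = 5000, seed = 7)
  # power-of-two scaling commutes exactly with the resampling arithmetic
  cv2 <- replica_increment_bootstrap(2 * pool, n_boot = 5000, seed = 7)
  expect_identical(2 * cv$statistic, cv2$statistic)
  expect_identical(2 * cv$ci_high, cv2$ci_high)
  # brute-force re-implementation at the same seed matches exactly
  n_boot <- 2000
  oracle <- local({
    set.seed(11)
    out <- numeric(length(pool) - 1)
    for (N in seq_len(length(pool) - 1)) {
      i1 <- matrix(sample.int(length(pool), N * n_boot, replace = TRUE),
                   nrow = N)
      i2 <- matrix(sample.int(length(pool), (N + 1) * n_boot, replace = TRUE),
                   nrow = N + 1)
      d <- numeric(n_boot)
      for (k in seq_len(n_boot))
        d[k] <- abs(mean(pool[i1[, k]]) - mean(pool[i2[, k]]))
      out[N] <- mean(d)
    }
    out
  })
  got <- replica_increment_bootstrap(pool, n_boot = n_boot, seed = 11)
  expect_equal(got$statistic, oracle, tolerance = 1e-12)
  # a different seed agrees within Monte-Carlo error
  other <- replica_increment_bootstrap(pool, n_boot = n_boot, seed = 12)
  expect_true(all(abs(other$statistic - oracle) <
                    3 * (other$se + got$se)))
})

test_that("normalized increment curves collapse across scales", {
  cv <- replica_increment_bootstrap(generate_replica_pool(10, 0, 1, seed = 317),
                                    n_boot = 2000, seed = 3)
  nc <- normalized_increment_curve(cv)
  expect_equal(nc$statistic[1], 1)
  pa <- generate_replica_pool(15, 0, 0.5, seed = 331)
  pb <- generate_replica_pool(15, 0, 2, seed = 331)
  na <- normalized_increment_curve(
    replica_increment_bootstrap(pa, n_boot = 2000, seed = 5))
  nb <- normalized_increment_curve(
    replica_increment_bootstrap(pb, n_boot = 2000, seed = 5))
  expect_identical(na$statistic, nb$statistic)
  expect_error(normalized_increment_curve(
    replica_increment_bootstrap(rep(1, 4), n_boot = 100, seed = 1)), "zero")
})

test_that("transition-count convergence selects by stride and vanishes at N
           = total", {
  ws <- gauss_ws(0.8, 1, 500, seed = 337)
  cv <- transition_count_convergence(ws, c(50, 100, 500), n_boot = 100,
                                     seed = 1)
  expect_identical(cv$statistic[cv$n == 500], 0)
  expect_true(all(abs(cv$statistic) < 3 * (cv$ci_high - cv$statistic) / 1.96 +
                    1e-9))
  # stride oracle: N = 50 must use every 10th completed transition
  sub <- work_set(ws$forward$work[10 * (1:50)], ws$reverse$work[10 * (1:50)])
  expect_equal(cv$dg[cv$n == 50], bar(sub)$dg)
  expect_error(transition_count_convergence(ws, 501), "exceeds")
})

test_that("time-dependent estimates detect (only) genuine drift", {
  ws <- gauss_ws(0.5, 1, 2000, seed = 347, n_replicas = 5,
                 run_length_ps = 10000)
  tg <- c(2000, 4000, 6000, 8000, 10000)
  td <- time_dependent_estimate(ws, tg, n_boot = 100, seed = 1)
  full <- bar(ws)$dg
  expect_identical(td$statistic[td$n == 10000], full)
  # stationary works: flat within the bootstrap CI
  expect_true(all(td$ci_low - 0.2 < full & full < td$ci_high + 0.2))
  # inject a +5 kcal/mol shift in forward works sampled after 5 ns
  shifted <- ws
  late <- shifted$forward$snapshot_time_ps > 5000
  shifted$forward$work[late] <- shifted$forward$work[late] + 5
  td2 <- time_dependent_estimate(shifted, c(5000, 10000), n_boot = 100,
                                 seed = 2)
  se2 <- (td2$ci_high - td2$statistic) / 1.96
  expect_gt(abs(td2$statistic[2] - td2$statistic[1]), 3 * max(se2))
  expect_error(time_dependent_estimate(ws, 1), "snapshot")
})

test_that("distribution shape statistics behave on canonical pools", {
  sh <- distribution_shape(c(-1, 0, 1))
  expect_equal(sh$skewness, 0)
  expect_equal(sh$spread, 2)
  expect_error(distribution_shape(rep(2, 10)), "constant")
  expect_error(distribution_shape(c(1, 2)), ">= 3")
  # analytic mixture skewness oracle at n = 1e4
  mix <- data.frame(weight = c(0.75, 0.25), offset = c(-1, 3), sd = c(0.5, 1))
  pool <- generate_replica_pool(1e4, 0, 1, mixture = mix, seed = 349)
  oracle <- mix_moments_oracle(mix$weight, mix$offset, mix$sd)
  expect_lt(abs(distribution_shape(pool)$skewness - oracle$skewness),
            3 * sqrt(6 / 1e4) * 3)
  expect_true(distribution_shape(pool)$ppcc > 0 &&
                distribution_shape(pool)$ppcc <= 1)
})

test_that("failure accounting tallies incomplete transitions", {
  ws <- gauss_ws(0, 1, 100, seed = 353)
  expect_equal(failure_accounting(ws)$failure_rate, 0)
  meta <- data.frame(completed = c(rep(TRUE, 99), FALSE))
  ws1 <- work_set(rnorm(100), rnorm(100), forward_meta = meta)
  fa <- failure_accounting(ws1)
  expect_equal(fa$n_failed, 1)
  expect_equal(fa$n_total, 200)
  expect_equal(fa$failure_rate, 0.5)
  # generator failure flags at 5% over 1e4 samples: binomial check
  big <- gauss_ws(0, 1, 5000, seed = 359, failure_rate = 0.05)
  rate <- failure_accounting(big)$failure_rate / 100
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))
  # failed samples are invisible to estimators
  est <- bar(big)
  expect_equal(est$n_forward + est$n_reverse + est$n_excluded, 10000L)
})
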