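test_that("Jarzynski estimator is exact in the zero-variance limit", {
  expect_equal(jarzynski(c(0.5, 0.5, 0.5))$dg, 0.5)
  expect_equal(jarzynski(0)$dg, 0)
  expect_error(jarzynski(numeric(0)), "at least one")
})

test_that("Jarzynski matches the Gaussian closed form mu - beta sigma^2 / 2", {
  n <- 1e6
  set.seed(103)
  w <- rnorm(n, 2.0, 0.5)
  est <- jarzynski(w, temperature = 300)
  closed <- 2.0 - BETA300 * 0.5^2 / 2 # 1.7903
  # jackknife standard error oracle, computed directly from leave-one-out
  # log-sum-exp values
  kt <- 1 / BETA300
  x <- -w / kt
  m <- max(x)
  S <- sum(exp(x - m))
  loo <- -kt * (m + log(S - exp(x - m)) - log(n - 1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  expect_lt(abs(est$dg - closed), 3 * se)
})

test_that("CGI reduces to the midpoint for equal-variance fits", {
  eps <- 1e-9
  ws <- ws_of(c(2 - eps, 2, 2 + eps), c(eps, 0, -eps))
  expect_equal(crooks_gaussian_intersection(ws)$dg, 1.0)
  # identical forward and negated-reverse distributions: dG = common mean
  x <- rnorm(100)
  ws2 <- ws_of(x, -x)
  expect_equal(crooks_gaussian_intersection(ws2)$dg, mean(x))
})

test_that("CGI flags degenerate variance and falls back to the midpoint", {
  ws <- ws_of(c(2, 2, 2), c(-0.1, 0, 0.1))
  est <- crooks_gaussian_intersection(ws)
  expect_false(est$converged)
  expect_equal(est$dg, (2 + 0) / 2)
  expect_error(crooks_gaussian_intersection(ws_of(1, c(0, 1))), ">= 2")
})

test_that("CGI recovers the true dG on Gaussian synthetic data", {
  ws <- gauss_ws(1.0, 1.0, 5000, seed = 107)
  est <- crooks_gaussian_intersection(ws)
  se <- bootstrap_uncertainty(ws, "cgi", n_boot = 1000, seed = 1)
  expect_true(est$converged)
  expect_lt(abs(est$dg - 1.0), 3 * se)
})

test_that("BAR is exact in the reversible limit and antisymmetric", {
  for (cc in c(-3, 0.7, 12)) {
    expect_equal(bar(ws_of(cc, -cc))$dg, cc, tolerance = 1e-7)
  }
  ws <- gauss_ws(1.0, 1.0, 500, seed = 109)
  swapped <- ws_of(ws$reverse$work, ws$forward$work)
  expect_equal(bar(ws)$dg, -bar(swapped)$dg, tolerance = 1e-6)
})

test_that("BAR agrees with a dense grid scan of the implicit equation", {
  ws <- gauss_ws(1.0, 1.0, 5000, seed = 113)
  est <- bar(ws)
  # independent oracle: brute-force scan of the Bennett equation written
  # out with plain logistic functions
  wf <- ws$forward$work
  wr <- ws$reverse$work
  M <- log(length(wf) / length(wr))
  g <- function(dg) {
    sum(1 / (1 + exp(BETA300 * (wf - dg) + M))) -
      sum(1 / (1 + exp(BETA300 * (wr + dg) - M)))
  }
  grid <- seq(est$dg - 0.05, est$dg + 0.05, by = 1e-4)
  gv <- vapply(grid, g, numeric(1))
  expect_lt(abs(grid[which.min(abs(gv))] - est$dg), 1e-4 + 1e-8)
  se <- bootstrap_uncertainty(ws, "bar", n_boot = 1000, seed = 2)
  expect_lt(abs(est$dg - 1.0), 3 * se)
  expect_true(est$converged)
})

test_that("BAR requires both directions and names the one-sided fallback", {
  ws <- work_set(c(1, 2), numeric(0))
  expect_error(bar(ws), "jarzynski", class = "neqfe_one_sided")
  # the documented fallback works on the forward set alone
  expect_equal(estimate_dg(work_set(c(0.5, 0.5), numeric(0)),
                           "jarzynski_f")$dg, 0.5)
})

test_that("all estimators exclude failed transitions and report the count", {
  meta_bad <- data.frame(completed = c(TRUE, TRUE, FALSE))
  ws <- work_set(c(1, 1, 50), c(-1, -1, -50),
                 forward_meta = meta_bad, reverse_meta = meta_bad)
  for (es in c("bar", "cgi", "jarzynski_f", "jarzynski_r")) {
    est <- estimate_dg(ws, es)
    expect_equal(est$n_excluded, 2L)
    expect_lt(abs(est$dg - 1), 1e-6) # the outlier pair is excluded
  }
})

test_that("estimates scale affinely with a common work/temperature factor", {
  ws <- gauss_ws(1.0, 1.0, 1000, seed = 127)
  fac <- 2.5
  scaled <- work_set(fac * ws$forward$work, fac * ws$reverse$work,
                     temperature = fac * 300)
  for (es in c("bar", "cgi", "jarzynski_f", "jarzynski_r")) {
    base <- estimate_dg(ws, es)$dg
    expect_equal(estimate_dg(scaled, es)$dg, fac * base, tolerance = 1e-6)
  }
})

test_that("bootstrap uncertainty is deterministic, zero for constants, and
           shrinks like 1/sqrt(n)", {
  wsc <- ws_of(rep(1, 10), rep(-1, 10))
  expect_equal(bootstrap_uncertainty(wsc, "bar", n_boot = 50, seed = 3), 0)
  ws <- gauss_ws(0, 1, 400, seed = 131)
  u1 <- bootstrap_uncertainty(ws, "cgi", n_boot = 500, seed = 5)
  expect_identical(u1, bootstrap_uncertainty(ws, "cgi", n_boot = 500, seed = 5))
  expect_error(bootstrap_uncertainty(ws, "cgi", n_boot = 1), "n_boot")
  # doubling n shrinks the SE by about sqrt(2), averaged over repetitions
  ratios <- vapply(1:50, function(i) {
    a <- gauss_ws(0, 1, 300, seed = 1000 + i)
    b <- gauss_ws(0, 1, 600, seed = 2000 + i)
    bootstrap_uncertainty(a, "cgi", n_boot = 200, seed = i) /
      bootstrap_uncertainty(b, "cgi", n_boot = 200, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - sqrt(2)) / sqrt(2), 0.2)
})

test_that("estimator consistency: BAR, CGI and the Jarzynski mean all recover
           the truth on mildly dissipative Gaussian data", {
  hits <- vapply(1:20, function(i) {
    ws <- gauss_ws(0.5, 1.5, 5000, seed = 3000 + i)
    okb <- abs(bar(ws)$dg - 0.5) <
      3 * bootstrap_uncertainty(ws, "bar", n_boot = 100, seed = i)
    okc <- abs(crooks_gaussian_intersection(ws)$dg - 0.5) <
      3 * bootstrap_uncertainty(ws, "cgi", n_boot = 100, seed = i)
    jf <- estimate_dg(ws, "jarzynski_f")$dg
    jr <- estimate_dg(ws, "jarzynski_r")$dg
    sej <- sqrt(bootstrap_uncertainty(ws, "jarzynski_f", n_boot = 100,
                                      seed = i)^2 +
                bootstrap_uncertainty(ws, "jarzynski_r", n_boot = 100,
                                      seed = i)^2) / 2
    okj <- abs((jf + jr) / 2 - 0.5) < 3 * sej
    okb && okc && okj
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
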