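test_that("generalized harmonic numbers match closed forms and the oracle", {
  for (b in c(0.5, 1, 1.3, 2.7)) expect_equal(gharmonic(1, b), 1)
  expect_equal(gharmonic(4, 1), 25 / 12)
  expect_equal(gharmonic(3, 2), 1 + 1 / 4 + 1 / 9)
  # brute-force summation oracle vs asymptotic branch on the overlap range
  for (b in c(1.1, 1.5, 2.5)) {
    for (x in c(1e4, 1e5, 1e6)) {
      direct <- sum(seq_len(x)^(-b))
      expect_equal(gharmonic(x, b, method = "asymptotic"), direct,
                   tolerance = 1e-10)
    }
  }
  # beta <= 1 asymptotic branch against a longer direct sum
  expect_equal(gharmonic(5e6, 0.9, method = "asymptotic"),
               sum(seq_len(5e6)^(-0.9)), tolerance = 1e-10)
  expect_equal(gharmonic(5e6, 1, method = "asymptotic"),
               sum(1 / seq_len(5e6)), tolerance = 1e-10)
  expect_error(gharmonic(0, 1), ">= 1")
  expect_error(gharmonic(5, 0), "beta")
})

test_that("gharmonic is monotone in x and decreasing in beta", {
  xs <- c(1, 2, 5, 10, 100, 1e4)
  for (b in c(0.8, 1.2, 2)) {
    h <- gharmonic(xs, b)
    expect_true(all(diff(h) > 0))
  }
  for (x in c(2, 10, 1000)) {
    h_by_beta <- vapply(c(0.5, 1, 1.5, 2.5), function(b) gharmonic(x, b),
                        numeric(1))
    expect_true(all(diff(h_by_beta) < 0))
  }
})

test_that("zeta_limit evaluates closed limits and flags open repertoires", {
  expect_equal(zeta_limit(1, 2), pi^2 / 6, tolerance = 1e-12)
  expect_identical(zeta_limit(10, 0.87454), Inf)
  expect_identical(zeta_limit(10, 1), Inf)
  expect_true(is_open(0.87454))
  expect_true(is_open(1))
  expect_false(is_open(1.00001))
  # alpha * H(x, beta) approaches the limit from below, at the tail rate
  lim <- zeta_limit(1, 1.2)
  h <- gharmonic(1e7, 1.2, method = "asymptotic")
  expect_lt(h, lim)
  expect_lt(lim - h, 1e7^(-0.2) / 0.2 * 1.001)
})

test_that("capture_quantile returns the exact crossing integer", {
  # tiny case solvable by hand: beta = 2, zeta = pi^2/6 ~ 1.6449
  # H(1)=1, H(2)=1.25, H(3)=1.3611...; q = 0.75 -> target 1.2337 -> x = 2
  expect_equal(capture_quantile(2, q = 0.75), 2)
  expect_equal(capture_quantile(2, q = 0.5), 1)   # first fish suffices
  expect_error(capture_quantile(0.9), "open repertoire")
  expect_error(capture_quantile(1), "open repertoire")

  # bracketing invariant across a beta grid, both branches
  for (b in c(1.1, 1.15, 1.3, 1.6, 2)) {
    xq <- capture_quantile(b, 0.9)
    target <- 0.9 * zeta_limit(1, b)
    expect_gte(gharmonic(xq, b), target)
    if (xq > 1) expect_lt(gharmonic(xq - 1, b), target)
  }
  # x_q is nonincreasing in beta at fixed q
  grid <- seq(1.1, 2, by = 0.1)
  xqs <- vapply(grid, capture_quantile, numeric(1), q = 0.9)
  expect_true(all(diff(xqs) <= 0))
})

test_that("fit recovers exact model parameters from noiseless curves", {
  for (par in list(c(100, 1.3), c(436.8, 1.2), c(53.9, 1.41), c(250, 1.63))) {
    cur <- simulate_model_curve(par[1], par[2], n = 20, noise_sd = 0)
    fit <- fit_saturation(cur)
    expect_lt(abs(fit$alpha - par[1]) / par[1], 1e-6)
    expect_lt(abs(fit$beta - par[2]) / par[2], 1e-6)
    expect_true(fit$converged)
    expect_equal(fit$limit, zeta_limit(par[1], par[2]), tolerance = 1e-6)
  }
})

test_that("fit handles degenerate and boundary curves sensibly", {
  # saturated-at-first-fish: constant curve -> steep beta, alpha ~ c, closed
  const <- data.frame(x = 1:10, G = rep(42, 10))
  fit <- fit_saturation(const)
  expect_true(fit$closed)
  expect_gt(fit$beta, 3)
  expect_equal(fit$alpha, 42, tolerance = 0.01)
  expect_equal(fit$limit, 42, tolerance = 0.5)

  expect_error(fit_saturation(data.frame(x = 1:2, G = c(1, 2))),
               "at least 3")
  expect_error(fit_saturation(data.frame(x = 1:5, G = rep(0, 5))),
               "degenerate")
})

test_that("unbounded curves classify as open with undefined quantiles", {
  # linear growth: increments do not decay, so beta is driven to ~0 (open)
  lin <- fit_saturation(data.frame(x = 1:15, G = 10 * (1:15)))
  expect_false(lin$closed)
  open_cur <- simulate_model_curve(100, 0.9, 25, 0)
  ofit <- fit_saturation(open_cur)
  expect_false(ofit$closed)
  expect_identical(ofit$limit, Inf)
  qd <- fit_quantiles(ofit, 0.9)
  expect_true(is.na(qd$x_q))
})

test_that("fit_quantiles reports crossings for closed fits", {
  cur <- simulate_model_curve(178.274, 1.43356, 8, 0)
  fit <- fit_saturation(cur)
  qd <- fit_quantiles(fit, c(0.5, 0.9))
  expect_equal(nrow(qd), 2)
  expect_true(all(qd$x_q >= 1))
  expect_true(all(diff(qd$x_q) > 0))
})

test_that("audit_fit_table flags internally inconsistent printed rows", {
  tab <- data.frame(
    alpha = c(178.274, 479.892, 436.761),
    beta = c(1.43356, 1.26093, 1.2152),
    limit = c(519.548, 2152.12, 2288.41),    # middle row transposed digits
    quantile = c(118, 3907, 2060))           # last row grossly inconsistent
  audited <- audit_fit_table(tab, q = 0.9, rel_tol = 1e-3)
  expect_true(audited$limit_consistent[1])
  expect_false(audited$limit_consistent[2])
  expect_true(audited$limit_consistent[3])
  expect_identical(audited$quantile_status,
                   c("consistent", "boundary", "inconsistent"))
})
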