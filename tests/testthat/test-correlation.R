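test_that("kendall_tau matches the exhaustive pair-enumeration oracle", {
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))$tau, 4 / 6,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    x <- sample(rnorm(n)) # continuous
    y <- rnorm(n)
    expect_equal(kendall_tau(x, y)$tau, tau_brute(x, y), tolerance = 1e-12)
    # with ties
    xt <- sample(1:4, n, replace = TRUE)
    yt <- sample(1:4, n, replace = TRUE)
    expect_equal(kendall_tau(xt, yt)$tau, tau_brute(xt, yt), tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:3, 1:4), class = "mobiscale_input_error")
})

test_that("tau is +/-1 on monotone series and invariant to monotone maps", {
  x <- rnorm(50)
  expect_equal(kendall_tau(x, exp(x))$tau, 1)
  expect_equal(kendall_tau(x, -x^3)$tau, -1)
  y <- rnorm(50)
  expect_equal(kendall_tau(x, y)$tau, kendall_tau(exp(x), atan(y))$tau)
})

test_that("analytic and permutation null CIs agree", {
  expect_equal(tau_ci(1000), 1.96 * sqrt(2 * 2005 / (9 * 1000 * 999)),
               tolerance = 1e-3)
  expect_lt(abs(tau_ci(1000) - 0.041393), 5e-6) # closed-form evaluation
  expect_lt(tau_ci(1e6), 0.002) # shrinks with n
  set.seed(6)
  x <- rnorm(300); y <- rnorm(300)
  perm <- tau_ci_permutation(x, y, n_perm = 500, seed = 1)
  expect_equal(perm, tau_ci(300), tolerance = 0.25)
})

test_that("lagged pairs stay within file boundaries", {
  s <- dplyr::bind_rows(
    make_series(1:5, file_id = "f1"),
    make_series(1:4, file_id = "f2")
  )
  expect_equal(lagged_tau(s, 1)$n_pairs, (5 - 1) + (4 - 1))
  expect_equal(lagged_tau(s, 3)$n_pairs, (5 - 3) + (4 - 3))
  expect_error(lagged_tau(s, 10), class = "mobiscale_input_error")
})

test_that("AR(1) log-displacement series decay across lags", {
  s <- generate_series("log-ar1", n = 5000, seed = 12, phi = 0.7)
  prof <- tau_lag_profile(s, max_lag = 20)
  t1 <- prof$tau[prof$lag == 1]
  t5 <- prof$tau[prof$lag == 5]
  t20 <- prof$tau[prof$lag == 20]
  expect_gt(t1, t5)
  expect_gt(t5, t20)
  expect_gt(t20, 0)
  # tau1 matches the Gaussian-copula closed form 2/pi * asin(phi)
  expect_equal(t1, 2 / pi * asin(0.7), tolerance = 0.03)
})

test_that("iid series sit inside the null band", {
  s <- generate_series("iid-lognormal", n = 3000, seed = 13)
  t1 <- lagged_tau(s, 1)
  expect_lt(abs(t1$tau), t1$ci_halfwidth)
})

test_that("decay-exponent fit recovers a constructed power-law decay", {
  prof <- structure(
    tibble::tibble(lag = 1:20, tau = (1:20)^(-0.4),
                   n_pairs = 1000, ci_halfwidth = tau_ci(1000),
                   pearson_log = (1:20)^(-0.6)),
    class = c("lag_decay", class(tibble::tibble()))
  )
  expect_equal(fit_tau_decay(prof)$decay_exponent, -0.4, tolerance = 1e-9)
  pf <- fit_tau_decay(prof, "pearson_log")
  expect_equal(pf$decay_exponent, -0.6, tolerance = 1e-9)
  expect_equal(pf$hurst_implied, 1 - 0.3, tolerance = 1e-9)
  short <- prof[1:3, ]
  expect_error(fit_tau_decay(short), class = "mobiscale_fit_error")
})

test_that("log-displacement Pearson recovers an AR(1) coefficient", {
  s <- generate_series("log-ar1", n = 5000, seed = 14, phi = 0.8)
  expect_equal(log_pearson(s)$r_delta, 0.8, tolerance = 0.03)
  ind <- generate_series("iid-lognormal", n = 5000, seed = 15)
  expect_lt(abs(log_pearson(ind)$r_delta), 2 / sqrt(5000) * 2)
  expect_error(log_pearson(make_series(rep(7, 50))),
               class = "mobiscale_degenerate_error")
})

test_that("scatter pattern concentrates on the diagonal for persistent series", {
  s <- generate_series("log-ar1", n = 4000, seed = 16, phi = 0.9, sdlog = 1.5)
  sc <- scatter_correlation_pattern(s)
  shuffled <- s
  set.seed(17)
  shuffled$displacement <- sample(shuffled$displacement)
  sc0 <- scatter_correlation_pattern(shuffled)
  expect_gt(sc$diagonal_mass, sc0$diagonal_mass)
  expect_equal(sum(sc$grid$count), sc$n_pairs)
})
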