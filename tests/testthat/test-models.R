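test_that("all simulators are seed-deterministic", {
  sims <- list(
    function(s) simulate_levy(n_steps = 300, seed = s),
    function(s) simulate_ctrw(n_steps = 300, seed = s),
    function(s) simulate_epr(n_steps = 300, seed = s),
    function(s) simulate_slaw(n_steps = 300, n_waypoints = 200, seed = s),
    function(s) simulate_hts(n_steps = 300, seed = s)
  )
  for (f in sims) {
    expect_identical(f(7), f(7))
    expect_false(isTRUE(all.equal(f(7)$displacement, f(8)$displacement)))
  }
})

test_that("Levy move lengths recover the configured tail exponent", {
  s <- simulate_levy(n_steps = 5000, alpha = 2.0, x_min = 1, seed = 31)
  f <- fit_powerlaw_ks(s$displacement, x_min = 1, n_bootstrap = 0)
  expect_equal(f$alpha, 2.0, tolerance = 0.1)
})

test_that("Levy and CTRW displacements carry no serial correlation", {
  pooled <- dplyr::bind_rows(lapply(1:8, function(s)
    simulate_levy(n_steps = 2000, seed = s)))
  for (dn in c(1, 5)) {
    t <- lagged_tau(pooled, dn)
    expect_lt(abs(t$tau), tau_ci(t$n_pairs, level = 0.99))
  }
  pooled_c <- dplyr::bind_rows(lapply(1:8, function(s)
    simulate_ctrw(n_steps = 2000, seed = s)))
  t1 <- lagged_tau(pooled_c, 1)
  expect_lt(abs(t1$tau), tau_ci(t1$n_pairs, level = 0.99))
})

test_that("CTRW waits and jumps are mutually independent", {
  pooled <- dplyr::bind_rows(lapply(1:8, function(s)
    simulate_ctrw(n_steps = 2000, seed = s)))
  t <- run_staytime_independence(pooled)
  expect_lt(abs(t$tau), tau_ci(t$n_pairs, level = 0.99))
  # wait-tail recovery
  f <- fit_powerlaw_ks(pooled$preceding_staytime, x_min = 60, n_bootstrap = 0)
  expect_equal(f$alpha, 2.0, tolerance = 0.1)
})

test_that("EPR shows positive lag-1 correlation that dies beyond lag 1", {
  pooled <- dplyr::bind_rows(lapply(1:10, function(s)
    simulate_epr(n_steps = 2000, seed = s)))
  t1 <- lagged_tau(pooled, 1)
  expect_gt(t1$tau, 3 * t1$ci_halfwidth)
  for (dn in c(2, 5)) {
    expect_lt(abs(lagged_tau(pooled, dn)$tau), 0.05)
  }
  # the visited-location count grows sublinearly
  s <- simulate_epr(n_steps = 4000, seed = 32)
  n_new <- sum(!duplicated(signif(s$displacement, 12))) # proxy: distinct moves
  expect_lt(n_new, 4000)
})

test_that("SLAW correlation strengthens as the landscape H drops", {
  mean_tau1 <- function(h) {
    mean(vapply(1:6, function(s)
      lagged_tau(simulate_slaw(hurst = h, seed = s), 1)$tau, numeric(1)))
  }
  t_low <- mean_tau1(0.6)
  t_mid <- mean_tau1(0.75)
  t_high <- mean_tau1(0.9)
  expect_gt(t_low, t_mid)
  expect_gt(t_mid, t_high)
  expect_gt(t_low, 0.1)
})

test_that("HTS walker produces heavy-tailed, positively correlated moves", {
  s <- simulate_hts(seed = 33)
  t1 <- lagged_tau(s, 1)
  expect_gt(t1$tau, 5 * t1$ci_halfwidth)
  # link lengths span the hierarchy, from short bottom-layer links to the
  # long top-layer ones
  expect_gt(max(s$displacement) / min(s$displacement), 50)
  # gradual changes: consecutive pairs concentrate on the diagonal
  # relative to a shuffled control
  sc <- scatter_correlation_pattern(s)
  shuf <- s
  set.seed(34)
  shuf$displacement <- sample(shuf$displacement)
  expect_gt(sc$diagonal_mass, scatter_correlation_pattern(shuf)$diagonal_mass)
  # the lag profile decays but stays positive at moderate lags
  prof <- tau_lag_profile(s, max_lag = 10)
  expect_gt(prof$tau[1], prof$tau[10])
  expect_gt(prof$tau[5], 0)
})
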