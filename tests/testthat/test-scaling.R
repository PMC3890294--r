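test_that("log-binned densities integrate to one", {
  set.seed(1)
  x <- rlnorm(10000, 3, 1.5)
  b <- log_bin(x)
  expect_true(all(b$density >= 0))
  expect_equal(sum(b$density * (b$high - b$low)), 1, tolerance = 1e-6)
  expect_equal(sum(b$count), length(x))
  # samples confined to one bin: a single spike of density 1/width
  y <- runif(100, 1.0, 1.05)
  b1 <- log_bin(y)
  nz <- b1[b1$count > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$density, 1 / (nz$high - nz$low))
  expect_error(log_bin(c(1, -2)), class = "mobiscale_domain_error")
})

test_that("binned Pareto samples show the right log-log slope", {
  set.seed(2)
  b <- log_bin(rpareto(10000, 2.5, 1))
  fit <- loglog_pearson(b)
  expect_equal(fit$slope, -2.5, tolerance = 0.15)
  expect_lt(fit$R, -0.97)
})

test_that("two-regime fit recovers a constructed piecewise power law", {
  bd <- make_piecewise_binned(-1.5, -2.5, break_at = 1e3)
  f <- fit_two_regime(bd)
  expect_equal(f$alpha_low, -1.5, tolerance = 0.05)
  expect_equal(f$alpha_high, -2.5, tolerance = 0.05)
  expect_lt(abs(log10(f$break_point) - 3), 0.15) # within a bin of the break
  expect_lte(f$sse, f$sse_single)
  expect_equal(tidy(f)$estimate[1:2], c(f$alpha_low, f$alpha_high))
})

test_that("a single power law fits with two agreeing slopes", {
  bd <- make_piecewise_binned(-2, -2, break_at = 1e3)
  f <- fit_two_regime(bd)
  expect_equal(f$alpha_low, f$alpha_high, tolerance = 0.05)
  expect_error(fit_two_regime(make_piecewise_binned(lo_dec = 1, hi_dec = 1.4)),
               class = "mobiscale_fit_error")
})

test_that("power-law MLE recovers the exponent and respects scaling", {
  set.seed(3)
  x <- rpareto(5000, 2.0, 10)
  f <- fit_powerlaw_ks(x, n_bootstrap = 0)
  expect_equal(f$alpha, 2.0, tolerance = 0.05)
  # alpha is invariant when samples and lower bound share a scale factor
  f1 <- fit_powerlaw_ks(x, x_min = 10, n_bootstrap = 0)
  f2 <- fit_powerlaw_ks(x * 1000, x_min = 10000, n_bootstrap = 0)
  expect_equal(f1$alpha, f2$alpha)
  # insufficient tail errors
  expect_error(fit_powerlaw_ks(x[1:30], n_bootstrap = 0),
               class = "mobiscale_fit_error")
})

test_that("bootstrap p is seed-reproducible and rejects exponential data", {
  set.seed(4)
  x <- rpareto(2000, 2.0, 10)
  pa <- fit_powerlaw_ks(x, x_min = 10, n_bootstrap = 100, seed = 42)$p
  pb <- fit_powerlaw_ks(x, x_min = 10, n_bootstrap = 100, seed = 42)$p
  expect_identical(pa, pb)
  expect_gt(pa, 0.1)
  e <- 10 + rexp(2000, 1 / 30)
  pe <- fit_powerlaw_ks(e, x_min = 10, n_bootstrap = 100, seed = 42)$p
  expect_lt(pe, 0.05)
})

test_that("log-log Pearson R distinguishes power laws from flat densities", {
  bd <- make_piecewise_binned(-2, -2)
  expect_equal(loglog_pearson(bd)$R, -1)
  flat <- make_piecewise_binned(0, 0)
  expect_lt(abs(loglog_pearson(flat)$slope), 1e-10)
  expect_error(loglog_pearson(make_piecewise_binned(lo_dec = 1, hi_dec = 1.1)),
               class = "mobiscale_fit_error")
})
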