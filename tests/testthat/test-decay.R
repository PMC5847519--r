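test_that("signal models evaluate the closed forms", {
  expect_equal(biexp_signal(0, A = 100, f = 0.6, t2s = 5, t2l = 30), 100)
  expect_equal(biexp_signal(17, A = 0, f = 0.5, t2s = 5, t2l = 30, ric = 5), 5)
  expect_equal(biexp_signal(10, A = 100, f = 0.6, t2s = 5, t2l = 30, ric = 4),
               sqrt((100 * (0.6 * exp(-2) + 0.4 * exp(-1 / 3)))^2 + 16))
  expect_equal(biexp_signal(10, 100, 0.6, 5, 30, 4), 36.99823, tolerance = 1e-6)
  expect_error(biexp_signal(-1, 100, 0.6, 5, 30), "non-negative")

  expect_equal(monoexp_signal(12, m0 = 150, t2star = 12), 150 / exp(1))
  expect_equal(monoexp_signal(0, 150, 12), 150)
  expect_equal(monoexp_signal(1e6, 150, 12, ric = 3), 3)
  expect_error(monoexp_signal(-0.1, 150, 12), "non-negative")
})

test_that("biexp_signal is strictly decreasing and converges to the floor", {
  te <- seq(0, 200, by = 0.5)
  s <- biexp_signal(te, 100, 0.6, 5, 30, ric = 0)
  expect_true(all(diff(s) < 0))
  s_floor <- biexp_signal(c(300, 500, 800), 100, 0.6, 5, 30, ric = 7)
  expect_true(all(abs(s_floor - 7) < 1e-3))
  expect_true(all(diff(s_floor) < 0))
})

test_that("r_squared follows its definition", {
  y <- c(1, 5, 2, 8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "unequal")
})

test_that("noiseless biexponential curves are recovered exactly", {
  cv <- noiseless_curve(A = 100, f = 0.6, t2s = 5, t2l = 30)
  fit <- fit_biexp(cv)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$params$A, 100, tolerance = 1e-4)
  expect_equal(fit$params$f, 0.6, tolerance = 1e-4)
  expect_equal(fit$params$t2s, 5, tolerance = 1e-4)
  expect_equal(fit$params$t2l, 30, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("canonical labelling puts the short component first", {
  # random admissible parameter sets; the fit must always report t2s <= t2l
  set.seed(77)
  for (i in 1:5) {
    t2s <- runif(1, 2, 6); t2l <- runif(1, 25, 50); f <- runif(1, 0.3, 0.8)
    cv <- noiseless_curve(A = 80, f = f, t2s = t2s, t2l = t2l)
    fit <- fit_biexp(cv)
    expect_lte(fit$params$t2s, fit$params$t2l)
    expect_equal(fit$params$t2s, t2s, tolerance = 1e-3)
    expect_equal(fit$params$f, f, tolerance = 1e-3)
  }
})

test_that("a monoexponential curve collapses the biexponential fit", {
  cv <- noiseless_tube(m0 = 100, t2star = 20)
  fit <- suppressWarnings(fit_biexp(cv))
  expect_true(fit$degenerate)
  # and the fitted curve agrees with the monoexponential fit (same model class)
  mono <- fit_monoexp(cv)
  expect_equal(fit$fitted, mono$fitted, tolerance = 1e-5)
  expect_equal(mono$params$m0, 100, tolerance = 1e-6)
  expect_equal(mono$params$t2star, 20, tolerance = 1e-6)
})

test_that("fit preconditions are enforced", {
  short <- noiseless_curve()[1:5, ]
  expect_error(fit_biexp(short), ">= 6 distinct")
  late_only <- noiseless_curve(schedule = acq_schedule(c(5, 10, 20, 30, 40, 50, 60)))
  expect_warning(fit_biexp(late_only), "span")
  zero <- data.frame(te_ms = c(1, 2, 4, 8, 16, 32), signal = rep(0, 6))
  expect_error(fit_biexp(zero), "all-zero")
  expect_error(fit_monoexp(zero[1:3, ]), ">= 4 distinct")
  expect_error(fit_monoexp(zero), "all-zero")
  neg <- data.frame(te_ms = c(1, 2, 4, 8), signal = c(3, 2, -1, 1))
  expect_error(fit_monoexp(neg), "non-negative")
})

test_that("tube M0 is recovered with <1% bias at snr 100", {
  set.seed(12)
  sch <- make_default_schedule()
  m0_hat <- replicate(100, {
    mu <- monoexp_signal(sch$te_ms, 150, 12)
    cv <- data.frame(te_ms = sch$te_ms, signal = rician_sample(mu, 1.5))
    fit_monoexp(cv)$params$m0
  })
  expect_lt(abs(mean(m0_hat) / 150 - 1), 0.01)
})

test_that("recovery error decreases with snr", {
  set.seed(13)
  sch <- make_default_schedule()
  rmse <- sapply(c(10, 25, 50, 100), function(snr) {
    err <- replicate(40, {
      mu <- biexp_signal(sch$te_ms, 100, 0.46, 4.99, 31.51)
      cv <- data.frame(te_ms = sch$te_ms, signal = rician_sample(mu, 100 / snr))
      fit <- fit_biexp(cv)
      (fit$params$t2s / 4.99 - 1)^2
    })
    sqrt(mean(err))
  })
  # monotone within Monte-Carlo slack; the extremes must order strictly
  expect_lt(rmse[4], rmse[1])
  expect_true(all(diff(rmse) < 0.2 * rmse[-4] + 1e-12))
})

test_that("magnetization fractions partition the amplitude", {
  cv <- noiseless_curve(A = 100, f = 0.6, t2s = 5, t2l = 30)
  fit <- fit_biexp(cv)
  m0 <- magnetization_fractions(fit)
  expect_equal(m0$m0_sf, 60, tolerance = 1e-3)
  expect_equal(m0$m0_lf, 40, tolerance = 1e-3)
  expect_equal(m0$m0_sf + m0$m0_lf, fit$params$A)  # exact by construction

  # worked cohort-mean share: f = 0.577 of A = 100
  fit2 <- fit_biexp(noiseless_curve(A = 100, f = 0.577, t2s = 4, t2l = 35))
  m02 <- magnetization_fractions(fit2)
  expect_equal(m02$m0_sf, 57.7, tolerance = 1e-2)
  expect_equal(m02$m0_lf, 42.3, tolerance = 1e-2)

  mono <- fit_monoexp(noiseless_tube())
  expect_error(magnetization_fractions(mono), "biexponential")
})

test_that("fits serialize to JSON with diagnostics", {
  fit <- fit_biexp(noiseless_curve())
  rec <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(rec$model, "biexp")
  expect_equal(rec$params$A, 100, tolerance = 1e-4)
  expect_true(rec$converged)
  expect_equal(rec$options$degenerate_ratio, 1.5)
})
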