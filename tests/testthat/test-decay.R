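test_that("noise-free generation inverts exactly under the decay fit", {
  for (k in c(0.006, 0.025)) {
    s <- sim_decay_series(k, c0 = 50, noise = noise_free(), seed = 1,
                          matrix = "serum")
    f <- fit_first_order_decay(s)
    expect_equal(f$k, k, tolerance = 1e-6)
    expect_equal(f$c0_hat, 50, tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("linear-scale fit agrees with log-linear least squares when noise-free", {
  s <- sim_decay_series(0.025, 10, noise = noise_free(), seed = 2,
                        matrix = "serum")
  f_lin <- fit_first_order_decay(s, scale = "linear")
  f_log <- fit_first_order_decay(s, scale = "log")
  expect_equal(f_lin$k, f_log$k, tolerance = 1e-8)
  expect_equal(f_lin$c0_hat, f_log$c0_hat, tolerance = 1e-6)
})

test_that("noisy-series fit matches the exhaustive grid-search oracle", {
  s <- sim_decay_series(0.025, 50, noise = assay_noise(cv = 0.05), seed = 77,
                        matrix = "serum")
  f <- fit_first_order_decay(s)
  k_oracle <- decay_grid_oracle(s, k_range = c(0.015, 0.035), k_step = 1e-5)
  expect_lt(abs(f$k - k_oracle), 2e-5)
})

test_that("fitted k is unbiased across 200 noisy replicates", {
  k_true <- 0.025
  k_hat <- vapply(1:200, function(seed) {
    s <- sim_decay_series(k_true, 50, noise = assay_noise(cv = 0.05),
                          seed = seed, matrix = "serum")
    fit_first_order_decay(s)$k
  }, numeric(1))
  mc_se <- sd(k_hat) / sqrt(length(k_hat))
  expect_lt(abs(mean(k_hat) - k_true), 3 * mc_se)
})

test_that("decay fit rejects degenerate series", {
  bad <- data.frame(time_h = c(0, 1, 2), analyte = "meropenem",
                    conc_mg_L = c(0, 0, 0))
  expect_error(fit_first_order_decay(bad), "zero")
  two <- data.frame(time_h = c(0, 1), analyte = "meropenem",
                    conc_mg_L = c(10, 9))
  expect_error(fit_first_order_decay(two), "3 distinct")
  nf <- data.frame(time_h = c(0, 1, 2), analyte = "meropenem",
                   conc_mg_L = c(10, NA, 8))
  expect_error(fit_first_order_decay(nf), "non-finite")
})

test_that("recovery matches the printed stability results", {
  expect_equal(recovery_at(0.006, 24), 86.6, tolerance = 0.05 / 86.6)  # saline, 22 C
  expect_equal(recovery_at(0.025, 24), 54.9, tolerance = 0.05 / 54.9)  # serum, 37 C
  expect_equal(recovery_at(0.31, 0), 100)
  expect_error(recovery_at(0.025, -1), "non-negative")
})

test_that("recovery is decreasing and satisfies the semigroup identity", {
  k <- 0.025
  t <- seq(0, 24, by = 0.5)
  r <- recovery_at(k, t)
  expect_true(all(diff(r) < 0))
  for (tt in c(1, 6.2, 24)) {
    expect_equal(recovery_at(k, tt), recovery_at(k, tt / 2)^2 / 100)
  }
})

test_that("stability window reproduces the pharmacopoeial crossing times", {
  expect_equal(stability_window(0.006, 0.90), 17.56, tolerance = 0.2 / 17.56)
  expect_equal(stability_window(0.025, 0.90), -log(0.9) / 0.025)  # 4.21 h
  expect_equal(stability_window(0.31, 1.0), 0)
  expect_identical(stability_window(0, 0.9), Inf)
})

test_that("stability window round-trips through recovery", {
  for (k in c(0.006, 0.025, 0.31)) {
    for (theta in c(0.5, 0.9, 0.99)) {
      expect_equal(recovery_at(k, stability_window(k, theta)), 100 * theta,
                   tolerance = 1e-9)
    }
  }
})

test_that("half-life matches printed and derived values", {
  expect_equal(half_life(0.025), 27.7, tolerance = 0.05 / 27.7)
  expect_equal(half_life(log(2)), 1.0)
  expect_equal(half_life(0.006), log(2) / 0.006)  # 115.5 h
  expect_error(half_life(0), "k")
})

test_that("theoretical metabolite curve follows equimolar conversion", {
  expect_equal(theoretical_metabolite_curve(20000, 0.006, 0), 0)
  # degraded parent after 24 h converted at the ORM/parent molar-mass ratio
  expect_equal(theoretical_metabolite_curve(20000, 0.006, 24),
               (20000 - 20000 * exp(-0.144)) * 401.16 / 383.46,
               tolerance = 1e-12)
  expect_equal(round(theoretical_metabolite_curve(20000, 0.006, 24)), 2806)
  expect_equal(theoretical_metabolite_curve(20000, 0.006, 1e7),
               20000 * 401.16 / 383.46)
})

test_that("mass-balance deficit reflects the generator's metabolite yield", {
  for (yield in c(1, 0.8, 0)) {
    s <- sim_decay_series(0.025, 50, noise = noise_free(), seed = 1,
                          metabolite_yield = yield, matrix = "serum")
    f <- fit_first_order_decay(s)
    mb <- mass_balance_deficit(s, f)
    expect_false(mb$defined[mb$time_h == 0])
    expect_equal(mb$deficit[mb$defined], rep(1 - yield, sum(mb$defined)),
                 tolerance = 1e-6)
  }
})

test_that("stability report rounds half-up and issues inclusive verdicts", {
  s <- sim_decay_series(0.006, 20000, noise = noise_free(), seed = 1)
  rep <- stability_report(fit_first_order_decay(s))
  expect_equal(rep$rounded$recovery_24h_percent, 86.6)
  expect_equal(rep$rounded$stability_window_h, 17.6)
  # verdict is inclusive at exactly the threshold
  expect_true(all(rep$verdict$stable[rep$verdict$time_h <= 17.5]))
  expect_false(any(rep$verdict$stable[rep$verdict$time_h >= 20]))
  r2 <- stability_report(fit_first_order_decay(s), times = c(0, 17.5, 17.7))
  expect_equal(r2$verdict$stable, c(TRUE, TRUE, FALSE))  # crossing near 17.56 h
})
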