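test_that("individual clearance assembles the partitioned components", {
  fx <- fixed_params(v = 26.4, k_serum = 0.025)  # cl_decay = 0.66
  expect_equal(individual_clearance(fx, 3.6, gfr = 139, eta = 0), 12.60)
  fx0 <- fixed_params(v = 1, k_serum = 0)
  expect_equal(individual_clearance(fx0, 0, gfr = 100, eta = 0), 6.0)
  expect_equal(individual_clearance(fx, 3.6, gfr = 139, eta = log(2)),
               2 * individual_clearance(fx, 3.6, gfr = 139, eta = 0))
  # alternative placement: random effect on the non-GFR component only
  expect_equal(individual_clearance(fx, 3.6, 139, log(2), iiv = "nongfr"),
               139 * 0.06 + 7.2 + 0.66)
  expect_error(individual_clearance(fx, 3.6, gfr = 139, eta = NaN), "eta")
})

test_that("steady-state concentration is rate over clearance", {
  expect_equal(predict_css(250, 11.4), 250 / 11.4)  # ~21.93 mg/L
  expect_equal(predict_css(0, 5), 0)
  expect_equal(predict_css(250, 2 * 11.4), predict_css(250, 11.4) / 2)
  expect_error(predict_css(250, 0), "cl")
  # mass balance: Css * CL = infusion rate
  for (r in c(125, 250)) for (cl in c(5.2, 11.4, 25.3)) {
    expect_equal(predict_css(r, cl) * cl, r, tolerance = 1e-12)
  }
})

test_that("omega = 0 likelihood equals the closed-form fixed-effects -2LL", {
  co <- toy_cohort(n_patients = 4, seed = 5)
  fx <- fixed_params()
  theta <- 3.6; sigma <- 0.135
  d <- co[co$analyte == "meropenem", ]
  css <- d$rate_mg_h / (d$gfr_ml_min * fx$gfr_factor + theta + fx$cl_decay)
  closed <- -2 * sum(dnorm(d$dv_mg_L, css, sigma * css, log = TRUE))
  expect_equal(poppk_neg2ll(theta, 0, sigma, co, fx), closed, tolerance = 1e-10)
})

test_that("Laplace and quadrature match brute-force integration", {
  for (seed in c(101, 202)) {
    co <- toy_cohort(n_patients = 3, seed = seed)
    for (th in c(2.5, 3.6)) {
      oracle <- neg2ll_trapezoid(th, 0.148, 0.135, co)
      lap <- poppk_neg2ll(th, 0.148, 0.135, co, method = "laplace")
      quad <- poppk_neg2ll(th, 0.148, 0.135, co, method = "quadrature")
      expect_lt(abs(lap - oracle), 0.05)
      expect_lt(abs(quad - oracle), 0.05)
      expect_lt(abs(lap - quad), 0.05)
    }
  }
})

test_that("quadrature is converged by 21 nodes", {
  co <- toy_cohort(n_patients = 5, seed = 17)
  v21 <- poppk_neg2ll(3.6, 0.148, 0.135, co, method = "quadrature", nodes = 21)
  v41 <- poppk_neg2ll(3.6, 0.148, 0.135, co, method = "quadrature", nodes = 41)
  expect_lt(abs(v21 - v41), 1e-4)
})

test_that("-2LL is invariant to patient order and additive under duplication", {
  co <- toy_cohort(n_patients = 6, seed = 23)
  v <- poppk_neg2ll(3.6, 0.148, 0.135, co)
  shuffled <- co[rev(seq_len(nrow(co))), ]
  expect_equal(poppk_neg2ll(3.6, 0.148, 0.135, shuffled), v, tolerance = 1e-9)
  doubled <- rbind(co, transform(co, id = id + 100))
  expect_equal(poppk_neg2ll(3.6, 0.148, 0.135, doubled), 2 * v,
               tolerance = 1e-9)
})

test_that("noise-free data are recovered exactly and fits are deterministic", {
  co <- sim_cohort(cohort_spec(n_patients = 10, seed = 3),
                   theta_cl_nongfr = 3.6, omega_cl = 0, sigma_prop = 0)
  # with no inter-individual or residual noise the likelihood concentrates on
  # the generating theta: profile the degenerate (omega = 0) objective in the
  # small-sigma limit (at finite sigma the proportional-error mode is shifted
  # by O(sigma^2))
  prof <- function(theta) poppk_neg2ll(theta, 0, 1e-6, co)
  theta_hat <- optimize(prof, c(0.5, 20), tol = 1e-10)$minimum
  expect_equal(theta_hat, 3.6, tolerance = 1e-6)

  co2 <- toy_cohort(n_patients = 8, seed = 31)
  f1 <- fit_poppk(co2)
  f2 <- fit_poppk(co2)
  expect_identical(f1$theta_cl_nongfr, f2$theta_cl_nongfr)
  expect_identical(f1$minus2ll, f2$minus2ll)
})

test_that("parameters are recovered and Wald intervals calibrated over replicates", {
  n_rep <- 50
  theta_true <- 3.6
  est <- matrix(NA_real_, n_rep, 2)  # theta, se_theta
  for (r in seq_len(n_rep)) {
    co <- sim_cohort(cohort_spec(n_patients = 100, seed = 1000 + r))
    fit <- fit_poppk(co, n_starts = 1)
    est[r, ] <- c(fit$theta_cl_nongfr, fit$se[1])
  }
  bias <- mean(est[, 1]) / theta_true - 1
  expect_lt(abs(bias), 0.03)
  covered <- abs(est[, 1] - theta_true) <= 1.96 * est[, 2]
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("clearance partition reproduces the reported totals and fractions", {
  p <- partition_clearance(cl_gfr = 7.1, cl_nongfr = 3.6, cl_decay = 0.66)
  expect_equal(round(p$cl_total, 1), 11.4)
  expect_equal(unname(round(p$fraction_percent)), c(62, 32, 6))
  expect_equal(sum(p$fraction_percent), 100)
  p1 <- partition_clearance(cl_gfr = 0, cl_nongfr = 5, cl_decay = 0)
  expect_equal(unname(p1$fraction_percent), c(0, 100, 0))
  expect_error(partition_clearance(0, 0, 0), "total")
})

test_that("cl_decay bridge multiplies rate and volume", {
  expect_equal(cl_decay_from_invitro(0.025, 26.2), 0.655)
  expect_equal(cl_decay_from_invitro(0, 26.2), 0)
  expect_equal(cl_decay_from_invitro(0.006, 26.2), 0.1572)
  expect_equal(fixed_params()$cl_decay, 0.655)
})

test_that("goodness-of-fit table diagnoses the fit", {
  co <- sim_cohort(cohort_spec(n_patients = 60, samples_per_patient = 4,
                               seed = 8))
  fit <- fit_poppk(co)
  gof <- gof_tables(fit, co)
  expect_equal(nrow(gof), 240)
  expect_true(all(is.finite(gof$iwres)))
  # observed vs individual-predicted scatter around the identity line
  slope <- coef(lm(observed ~ ipred, data = gof))[2]
  expect_gt(slope, 0.9); expect_lt(slope, 1.1)

  # a patient observed exactly at the typical prediction has EBE ~ 0
  fx <- fixed_params()
  d0 <- data.frame(id = rep(1:3, each = 2), time_h = 50,
                   analyte = "meropenem",
                   rate_mg_h = 250, gfr_ml_min = c(50, 139, 250)[rep(1:3, each = 2)])
  d0$dv_mg_L <- d0$rate_mg_h / (d0$gfr_ml_min * fx$gfr_factor + 3.6 + fx$cl_decay)
  # posterior mode shrinks to zero up to the O(sigma^2) proportional-error
  # mode shift
  inner <- meropk:::neg2ll_core(3.6, 0.148, 0.05,
                                meropk:::prep_patients(d0), fx)
  expect_lt(max(abs(inner$eta)), 0.01)
  inner2 <- meropk:::neg2ll_core(3.6, 0.148, 1e-4,
                                 meropk:::prep_patients(d0), fx)
  expect_lt(max(abs(inner2$eta)), 1e-6)
})

test_that("ill-posed inputs are rejected with clear messages", {
  co <- toy_cohort(n_patients = 3, seed = 2)
  expect_error(fit_poppk(co[co$id == 1, ]), "2 patients")
  expect_error(poppk_neg2ll(3.6, 0.1, 0, co), "sigma")
  bad <- co; bad$gfr_ml_min <- -bad$gfr_ml_min
  expect_error(poppk_neg2ll(3.6, 0.1, 0.1, bad), "GFR")
})
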