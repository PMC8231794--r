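# Shared fixture builders and independent oracles. Everything here is built
# in code at test time; the oracles deliberately avoid the package's own
# computation paths.

noise_free <- function(replicates = 2) assay_noise(cv = 0, replicates = replicates)

# small steady-state cohort for likelihood fixtures
toy_cohort <- function(n_patients = 3, seed = 101, omega_cv = 14.9,
                       sigma_cv = 13.5, samples = 4) {
  sim_cohort(
    cohort_spec(n_patients = n_patients, samples_per_patient = samples,
                seed = seed),
    fixed_params(),
    theta_cl_nongfr = 3.6,
    omega_cl = cv_to_omega(omega_cv),
    sigma_prop = sigma_cv / 100
  )
}

# brute-force marginal -2LL: per-patient trapezoid integration of the joint
# density over eta in [-6 omega, 6 omega] (201 points); independent of the
# package's Laplace/quadrature code.
neg2ll_trapezoid <- function(theta, omega, sigma, cohort,
                             fixed = fixed_params(), n_grid = 201) {
  d <- cohort[cohort$analyte == "meropenem", ]
  ids <- unique(d$id)
  eta_grid <- seq(-6 * omega, 6 * omega, length.out = n_grid)
  h <- diff(eta_grid[1:2])
  total <- 0
  for (i in ids) {
    di <- d[d$id == i, ]
    cl_typ <- di$gfr_ml_min[1] * fixed$gfr_factor + theta + fixed$cl_decay
    integrand <- vapply(eta_grid, function(e) {
      css <- di$rate_mg_h[1] / (cl_typ * exp(e))
      prod(stats::dnorm(di$dv_mg_L, css, sigma * css)) *
        stats::dnorm(e, 0, omega)
    }, numeric(1))
    m <- h * (sum(integrand) - 0.5 * (integrand[1] + integrand[n_grid]))
    total <- total + log(m)
  }
  -2 * total
}

# profile grid-search oracle for the first-order decay fit: for each k on a
# fine grid the optimal c0 is the closed-form linear LS solution, so the SSE
# profile over k can be scanned exhaustively.
decay_grid_oracle <- function(series, k_range, k_step = 1e-5) {
  d <- series[series$analyte == "meropenem", ]
  t <- d$time_h; y <- d$conc_mg_L
  ks <- seq(k_range[1], k_range[2], by = k_step)
  sse <- vapply(ks, function(k) {
    e <- exp(-k * t)
    c0 <- sum(y * e) / sum(e * e)
    sum((y - c0 * e)^2)
  }, numeric(1))
  ks[which.min(sse)]
}
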