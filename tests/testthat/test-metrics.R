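test_that("metabolic ratio follows its defining formula on both bases", {
  # cohort median concentrations give a ratio consistent with the median 0.28
  expect_equal(orm_ratio(7.73, 19.74), 7.73 / (7.73 + 19.74))
  expect_equal(round(orm_ratio(7.73, 19.74), 2), 0.28)
  expect_equal(orm_ratio(0, 10), 0)
  expect_equal(orm_ratio(10, 0), 1)
  molar <- orm_ratio(7.73, 19.74, basis = "molar")
  expect_equal(molar,
               (7.73 / 401.16) / (7.73 / 401.16 + 19.74 / 383.46))
  expect_warning(r <- orm_ratio(0, 0), "undefined")
  expect_true(is.na(r))
})

test_that("metabolic ratio is scale invariant and order preserving across bases", {
  orm <- c(2.71, 7.73, 23.37)
  mero <- c(31.25, 19.74, 7.25)
  for (s in c(0.1, 1, 17)) {
    expect_equal(orm_ratio(s * orm, s * mero), orm_ratio(orm, mero))
    expect_equal(orm_ratio(s * orm, s * mero, basis = "molar"),
                 orm_ratio(orm, mero, basis = "molar"))
  }
  expect_identical(order(orm_ratio(orm, mero)),
                   order(orm_ratio(orm, mero, basis = "molar")))
})

test_that("creatinine clearance is the urine-collection quotient", {
  expect_equal(creatinine_clearance(5, 1440, 1440, 5), 1.0)
  expect_equal(creatinine_clearance(100, 1500, 1440, 1), 100 * 1500 / 1440)
  # homogeneity: degree 1 in urine terms, -1 in time and plasma creatinine
  base <- creatinine_clearance(80, 1200, 1440, 1.1)
  expect_equal(creatinine_clearance(80, 2400, 1440, 1.1), 2 * base)
  expect_equal(creatinine_clearance(160, 1200, 1440, 1.1), 2 * base)
  expect_equal(creatinine_clearance(80, 1200, 2880, 1.1), base / 2)
  expect_equal(creatinine_clearance(80, 1200, 1440, 2.2), base / 2)
  expect_error(creatinine_clearance(80, 1200, 0, 1.1), "collection_time")
})

test_that("GFR unit bridge converts mL/min to L/h", {
  expect_equal(gfr_to_clearance(139), 8.34)
  expect_equal(gfr_to_clearance(0), 0)
  expect_equal(gfr_to_clearance(1000 / 60), 1.0)
  expect_equal(gfr_to_clearance(100), fixed_params()$gfr_factor * 100)
})

test_that("ratio tables pair samples and summarise per patient", {
  co <- sim_cohort(cohort_spec(n_patients = 6, seed = 12))
  rt <- ratio_table(co)
  expect_equal(nrow(rt$samples), 24)
  expect_equal(nrow(rt$patients), 6)
  expect_true(all(rt$samples$ratio_mass >= 0 & rt$samples$ratio_mass <= 1))
  # per-patient median really is the median of that patient's samples
  p1 <- rt$samples$ratio_mass[rt$samples$id == 1]
  expect_equal(rt$patients$median_ratio[rt$patients$id == 1], median(p1))
  expect_true(rt$summary$per_sample_range[1] <= rt$summary$per_sample_median)
})

test_that("ratio-GFR association detects structure and respects the null", {
  # perfectly linear relation -> r^2 = 1, smallest attainable p
  gfr <- seq(30, 300, length.out = 20)
  ratio <- 0.5 - 0.001 * gfr
  a <- ratio_gfr_association(ratio, gfr, n_perm = 1000, seed = 1)
  expect_equal(a$r_squared, 1)
  expect_lt(a$p_value, 0.01)
  # sign flip of GFR leaves r^2 unchanged
  b <- ratio_gfr_association(ratio, -gfr + 400, n_perm = 1000, seed = 1)
  expect_equal(b$r_squared, a$r_squared)

  # independent inputs: r^2 near 0, p not extreme
  set.seed(99)
  r0 <- runif(100, 0.2, 0.5)
  g0 <- runif(100, 28, 307)
  c0 <- ratio_gfr_association(r0, g0, n_perm = 1000, seed = 2)
  expect_lt(c0$r_squared, 0.1)
  expect_gt(c0$p_value, 0.01)

  expect_error(ratio_gfr_association(rep(0.3, 10), gfr[1:10]), "constant")
  expect_error(ratio_gfr_association(c(0.1, 0.2), c(10, 20)), ">= 3")
})

test_that("association p-values are reproducible under a seed", {
  co <- sim_cohort(cohort_spec(n_patients = 10, seed = 6))
  rt <- ratio_table(co)
  a <- ratio_gfr_association(rt$samples$ratio_mass, rt$samples$gfr_ml_min,
                             n_perm = 500, seed = 42)
  b <- ratio_gfr_association(rt$samples$ratio_mass, rt$samples$gfr_ml_min,
                             n_perm = 500, seed = 42)
  expect_identical(a, b)
})
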