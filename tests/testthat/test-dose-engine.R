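test_that("counts-to-dose-rate follows the LED chain and its symmetries", {
  # 100 MBq in 1 kg: 100e6 Bq * 2.3694e-14 J * 3600 s/h = 8.52984e-3 Gy/h
  dr <- counts_to_doserate(counts = 100 * 10 * 60, duration_s = 60, cf = 10,
                           volume_ml = 1000, density_g_ml = 1)
  expect_equal(dr, 100e6 * 2.3694e-14 * 3600, tolerance = 1e-12)

  base <- counts_to_doserate(5e4, 2700, 10, 25, 1.05)
  expect_equal(counts_to_doserate(1e5, 2700, 10, 25, 1.05), 2 * base,
               tolerance = 1e-14)                     # linear in counts
  expect_equal(counts_to_doserate(5e4, 2700, 10, 50, 1.05), base / 2,
               tolerance = 1e-14)                     # inverse-linear in mass
  # density 1 makes mass numerically equal to volume in grams
  expect_identical(counts_to_doserate(5e4, 2700, 10, 25, 1),
                   counts_to_doserate(5e4, 2700, 10, 25))
  expect_equal(counts_to_doserate(0, 2700, 10, 25), 0)
  expect_error(counts_to_doserate(5e4, 2700, 10, 0), class = "lutadose_value_error")
  expect_error(counts_to_doserate(5e4, 2700, 10, 25, 0), class = "lutadose_value_error")
})

test_that("monoexponential fit recovers noise-free kinetics on the 4/24/72/192 h schedule", {
  t <- c(4, 24, 72, 192)
  fit <- fit_monoexponential(t, 1.0 * exp(-0.05 * t))
  expect_equal(fit$d0, 1.0, tolerance = 1e-10)
  expect_equal(fit$lambda_eff, 0.05, tolerance = 1e-10)
  expect_false(fit$below_physical)
  expect_equal(integrate_monoexp(fit), 1.0 / 0.05, tolerance = 1e-10)

  # property sweep over generated kinetics
  set.seed(101)
  for (i in 1:50) {
    d0 <- runif(1, 1e-3, 5); l <- runif(1, 0.005, 0.2)
    f <- fit_monoexponential(t, d0 * exp(-l * t))
    expect_equal(f$d0, d0, tolerance = 1e-8)
    expect_equal(f$lambda_eff, l, tolerance = 1e-8)
  }
})

test_that("monoexponential fit enforces its preconditions and the physical floor", {
  expect_error(fit_monoexponential(c(4, 24), c(1, 0.5)),
               class = "lutadose_insufficient_data")
  expect_error(fit_monoexponential(c(4, 24, 72), c(1, 0.5, 0)),
               class = "lutadose_value_error")
  expect_error(fit_monoexponential(c(4, 4, 72), c(1, 0.5, 0.2)),
               class = "lutadose_value_error")
  # rising curve: no clearing
  expect_error(fit_monoexponential(c(4, 24, 72), c(1, 2, 4)),
               class = "lutadose_nonclearing")
  # slower than physical decay: flagged by default, rejected in strict mode
  lam <- lu177_constants$lambda_phys_per_h / 2
  t <- c(4, 24, 72, 192)
  f <- fit_monoexponential(t, exp(-lam * t))
  expect_true(f$below_physical)
  expect_error(fit_monoexponential(t, exp(-lam * t), strict = TRUE),
               class = "lutadose_nonclearing")
})

test_that("fit is the least-squares optimum and tolerates Poisson-level noise", {
  # 1,000 noisy replicates: median relative error of lambda_eff < 5%
  set.seed(77)
  t <- c(4, 24, 72, 192)
  cf <- 10; dur <- 2700; vol <- 5
  a0 <- 1.0; lam <- log(2) / 80
  mu <- a0 * vol * exp(-lam * t) * cf * dur  # ~1e5 counts at 4 h
  rel_err <- replicate(1000, {
    counts <- rpois(length(t), mu)
    dr <- counts_to_doserate(counts, dur, cf, vol)
    abs(fit_monoexponential(t, dr)$lambda_eff - lam) / lam
  })
  expect_lt(median(rel_err), 0.05)

  # grid-search oracle agrees with the closed-form log-linear solution
  set.seed(78)
  for (i in 1:5) {
    counts <- rpois(length(t), mu)
    dr <- counts_to_doserate(counts, dur, cf, vol)
    fit <- fit_monoexponential(t, dr)
    grid <- grid_monoexp(t, dr, seq(0.5, 2, by = 1e-4) * fit$lambda_eff)
    expect_equal(fit$lambda_eff, grid$lambda, tolerance = 2e-4)
    expect_equal(fit$d0, grid$d0, tolerance = 1e-3)
  }
})

test_that("monoexponential integral matches quadrature and closed forms", {
  expect_equal(integrate_monoexp(list(d0 = 2, lambda_eff = 0.01)), 200)
  # physical-decay-only bound
  lam_phys <- lu177_constants$lambda_phys_per_h
  expect_equal(integrate_monoexp(list(d0 = 1, lambda_eff = lam_phys)),
               1 / lam_phys)
  set.seed(42)
  for (i in 1:40) {
    d0 <- runif(1, 1e-4, 10); l <- runif(1, lam_phys, 0.3)
    ad <- integrate_monoexp(list(d0 = d0, lambda_eff = l))
    expect_equal(ad, quad_ad(d0, l), tolerance = 1e-6)
  }
  expect_error(integrate_monoexp(list(d0 = 1, lambda_eff = 0)),
               class = "lutadose_value_error")
})

test_that("single-time-point scaling reproduces the printed identity and ratios", {
  expect_identical(scale_single_timepoint(25.64, 1e5, 1e5, 12, 12), 25.64)
  expect_equal(scale_single_timepoint(25.64, 0.8e5, 1e5, 12, 12), 20.512)
  base <- scale_single_timepoint(30, 9e4, 1e5, 10, 10)
  expect_equal(scale_single_timepoint(30, 9e4, 1e5, 10, 5), 2 * base)
  expect_equal(scale_single_timepoint(30, 0, 1e5, 10, 10), 0)
  expect_error(scale_single_timepoint(30, 9e4, 0, 10, 10),
               class = "lutadose_value_error")
  expect_error(scale_single_timepoint(30, 9e4, 1e5, 10, 0),
               class = "lutadose_value_error")
})

test_that("cycle doses are linear in counts and cumulative doses are exact sums", {
  coh <- generate_cohort(cohort_config(n_patients = 4, seed = 21))
  cd1 <- compute_cycle_doses(coh$timepoints, cf = 10, rc_curve = NULL)
  tp2 <- coh$timepoints
  tp2$counts <- tp2$counts * 3
  cd3 <- compute_cycle_doses(tp2, cf = 10, rc_curve = NULL)
  expect_equal(cd3$ad_gy, 3 * cd1$ad_gy, tolerance = 1e-12)

  ds <- compute_course_dosimetry(cd1)
  sums <- tapply(cd1$ad_gy,
                 interaction(cd1$patient_id, cd1$structure_id, drop = TRUE),
                 sum)
  key <- interaction(ds$structures$patient_id, ds$structures$structure_id,
                     drop = TRUE)
  expect_identical(as.vector(ds$structures$cum_ad_gy - sums[as.character(key)]),
                   rep(0, nrow(ds$structures)))
  p <- ds$patients
  expect_true(all(p$min_total_ad <= p$mean_total_ad + 1e-12 &
                    p$mean_total_ad <= p$max_total_ad + 1e-12))
})

test_that("course aggregation reproduces hand-computed cycle sums and indices", {
  cd <- data.frame(
    patient_id = "P1", cycle = 1:4, structure_id = "L1",
    structure_class = "lesion", ad_gy = c(31.99, 25.64, 23.30, 18.74))
  ds <- compute_course_dosimetry(cd)
  expect_equal(ds$structures$cum_ad_gy, 99.67)
  expect_equal(ds$patients$mean_total_ad, 99.67)
  expect_equal(ds$patients$min_total_ad, ds$patients$max_total_ad)

  cd2 <- data.frame(
    patient_id = "P1", cycle = 1L, structure_id = c("L1", "L2"),
    structure_class = "lesion", ad_gy = c(8.73, 287.89))
  p <- compute_course_dosimetry(cd2)$patients
  expect_equal(p$min_total_ad, 8.73)
  expect_equal(p$max_total_ad, 287.89)
  expect_equal(p$mean_total_ad, 148.31)
})

test_that("single-time-point cycles require a usable reference cycle", {
  coh <- generate_cohort(cohort_config(n_patients = 2, seed = 3))
  tp <- coh$timepoints
  tp <- tp[!(tp$cycle == 2), ]  # remove the reference cycle entirely
  expect_error(compute_cycle_doses(tp, cf = 10),
               class = "lutadose_insufficient_data")
  expect_error(compute_cycle_doses(tp[0, ], cf = 10), NA)
  expect_error(
    compute_cycle_doses(coh$timepoints[, -7], cf = 10),
    "duration_s", class = "lutadose_schema_error")
})
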