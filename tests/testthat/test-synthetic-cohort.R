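test_that("a fixed seed reproduces the cohort exactly", {
  a <- generate_cohort(cohort_config(n_patients = 6, seed = 12))
  b <- generate_cohort(cohort_config(n_patients = 6, seed = 12))
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n_patients = 6, seed = 13))
  expect_false(identical(a$timepoints$counts, c2$timepoints$counts))
})

test_that("noise-free mode yields exact closed-form counts", {
  coh <- generate_cohort(noise_free_config(n_patients = 4, seed = 2))
  tp <- coh$timepoints
  tr <- coh$truth$kinetics
  m <- match(paste(tp$patient_id, tp$cycle, tp$structure_id),
             paste(tr$patient_id, tr$cycle, tr$structure_id))
  expected <- tr$a0_mbq_ml[m] * tp$volume_ml *
    exp(-tr$lambda_eff_per_h[m] * tp$t_h) * 10 * 2700
  expect_equal(tp$counts, expected, tolerance = 1e-12)
})

test_that("counting noise is Poisson around the noise-free mean", {
  nf <- generate_cohort(cohort_config(
    seed = 31, counting = list(cf = 10, duration_s = 2700, noise_free = TRUE)))
  po <- generate_cohort(cohort_config(seed = 31))
  expect_identical(nf$truth$kinetics, po$truth$kinetics)
  z <- (po$timepoints$counts - nf$timepoints$counts) / sqrt(nf$timepoints$counts)
  n <- length(z)
  expect_lt(abs(mean(z)), 4 / sqrt(n))        # Poisson mean = mu
  expect_lt(abs(var(z) - 1), 0.1)             # Poisson variance = mu
})

test_that("effective half-life draws match the configured prior mean", {
  set.seed(40)
  hl <- lutadose:::r_half_life(10000, mean_h = 80, cv = 0.25)
  se <- sd(hl) / sqrt(length(hl))
  expect_lt(abs(mean(hl) - 80), 3 * se)
  expect_true(all(hl < lu177_constants$half_life_h))
  expect_true(all(hl > 0))
})

test_that("true absorbed doses equal the integral of the generating kinetics", {
  coh <- generate_cohort(cohort_config(n_patients = 3, seed = 8))
  tr <- coh$truth$kinetics
  d0_per_conc <- lutadose:::led_doserate_per_conc(
    lu177_constants$led_j_per_decay, 1)
  for (i in sample(nrow(tr), 20)) {
    d0 <- tr$a0_mbq_ml[i] * d0_per_conc
    expect_equal(tr$ad_gy[i], quad_ad(d0, tr$lambda_eff_per_h[i]),
                 tolerance = 1e-8)
  }
})

test_that("stronger per-cycle uptake decline lowers cycle-4 doses", {
  slow <- generate_cohort(noise_free_config(seed = 6, cycle_dose_decay = 0.9))
  fast <- generate_cohort(noise_free_config(seed = 6, cycle_dose_decay = 0.7))
  s4 <- slow$truth$kinetics
  f4 <- fast$truth$kinetics
  les4 <- s4$structure_class == "lesion" & s4$cycle == 4
  expect_identical(s4$structure_id[les4], f4$structure_id[les4])
  expect_true(all(f4$ad_gy[les4] < s4$ad_gy[les4]))
  # cycle-1 doses are untouched by the decay factor
  les1 <- s4$structure_class == "lesion" & s4$cycle == 1
  expect_equal(s4$ad_gy[les1], f4$ad_gy[les1])
})

test_that("the generated design follows the acquisition schedule", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 1))
  tp <- coh$timepoints
  key <- interaction(tp$patient_id, tp$structure_id, tp$cycle, drop = TRUE)
  npts <- tapply(tp$t_h, key, length)
  cyc <- tapply(tp$cycle, key, unique)
  expect_true(all(npts[cyc <= 2] == 4))
  expect_true(all(npts[cyc >= 3] == 1))
  expect_true(all(tp$t_h[tp$cycle >= 3] == 24))
  # lesion volume responds to dose: observed volumes stay nonnegative
  expect_true(all(coh$lesions$v_m3_ml >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(site_distribution = c(liver = 0.5, bone = 0.2)),
               class = "lutadose_config_error")
  expect_error(cohort_config(n_cycles_distribution = c(`2` = -0.1, `4` = 1.1)),
               class = "lutadose_config_error")
  expect_error(cohort_config(response_noise_sd = -1),
               class = "lutadose_config_error")
  expect_error(cohort_config(cycle_dose_decay = 0),
               class = "lutadose_config_error")
  expect_error(cohort_config(kinetics_priors = list(
    lesion = list(a0 = c(mean = 3, cv = 0.5), half_life = c(mean = 200, cv = 0.2)))),
    class = "lutadose_config_error")
})
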