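plateau_curve <- function(ad, floor, cap, rate)
  floor + (cap - floor) * exp(-rate * ad)

test_that("plateaued dose-response fit recovers noiseless parameters", {
  set.seed(19)
  ad <- runif(60, 5, 280)
  pid <- rep(sprintf("P%d", 1:15), each = 4)
  dv <- plateau_curve(ad, floor = -45, cap = 30, rate = 0.02)
  fit <- fit_dose_response(ad, dv, pid, n_boot = 0)
  expect_equal(unname(fit$coefficients["floor"]), -45, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["cap"]), 30, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["rate"]), 0.02, tolerance = 1e-6)
  expect_lt(fit$spearman_rho, 0)
  expect_lt(fit$spearman_p, 1e-6)
  # fitted curve is monotone nonincreasing in dose
  grid <- predict(fit, seq(0, 300, by = 1))
  expect_true(all(diff(grid) <= 0))
})

test_that("dose-response fit degrades gracefully and validates input", {
  expect_error(fit_dose_response(1:5, 1:5, rep("P1", 5)),
               class = "lutadose_insufficient_data")
  expect_error(fit_dose_response(rep(50, 12), rnorm(12), rep("P1", 12)),
               class = "lutadose_value_error")
  # flat truth: plateau collapses towards a constant model
  set.seed(20)
  ad <- runif(40, 10, 200)
  dv <- rnorm(40, -10, 1e-6)
  fit <- fit_dose_response(ad, dv, rep(sprintf("P%d", 1:10), 4), n_boot = 0)
  expect_equal(unname(predict(fit, c(0, 150, 300))), rep(-10, 3),
               tolerance = 0.05)
  # linear alternative reports intercept/slope
  lin <- fit_dose_response(ad, -10 - 0.1 * ad, rep(sprintf("P%d", 1:10), 4),
                           model = "linear", n_boot = 0)
  expect_equal(unname(lin$coefficients["slope"]), -0.1, tolerance = 1e-8)
})

test_that("cluster bootstrap intervals cover generating parameters", {
  set.seed(22)
  pid <- rep(sprintf("P%02d", 1:35), times = sample(2:6, 35, replace = TRUE))
  ad <- exp(rnorm(length(pid), log(90), 0.6))
  dv <- plateau_curve(ad, -45, 30, 0.02) + rnorm(length(ad), 0, 5)
  fit <- fit_dose_response(ad, dv, pid, n_boot = 300, seed = 4)
  expect_true(fit$ci["2.5%", "floor"] <= -45 && -45 <= fit$ci["97.5%", "floor"])
  expect_true(fit$ci["2.5%", "rate"] <= 0.02 && 0.02 <= fit$ci["97.5%", "rate"])
  expect_equal(fit$n_patients, 35)
  # bootstrap respects its seed
  fit2 <- fit_dose_response(ad, dv, pid, n_boot = 300, seed = 4)
  expect_identical(fit$boot, fit2$boot)
})

test_that("TCP logistic regression recovers a known slope and flags separation", {
  set.seed(23)
  ad <- exp(rnorm(500, log(90), 0.7))
  y <- rbinom(500, 1, plogis(-2 + 0.03 * ad))
  tcp <- fit_tcp(ad, y)
  expect_false(tcp$separation)
  expect_lt(abs(tcp$slope - 0.03) / 0.03, 0.25)
  expect_equal(tcp$d50_gy, -tcp$intercept / tcp$slope)
  expect_gt(tcp$d90_gy, tcp$d50_gy)
  # agreement with glm on the same data
  ref <- glm(y ~ ad, family = binomial)
  expect_equal(tcp$slope, unname(coef(ref)[2]), tolerance = 1e-6)

  # one-class outcome: separation flag + finite penalized estimates
  all1 <- fit_tcp(ad, rep(TRUE, 500))
  expect_true(all1$separation && all1$penalized)
  expect_true(all(is.finite(c(all1$intercept, all1$slope))))
  expect_error(fit_tcp(ad[1:5], y[1:5]), class = "lutadose_insufficient_data")
})

test_that("Firth penalty matches ML closely on well-separated-free data", {
  set.seed(24)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(0.5 + x))
  ml <- glm(y ~ x, family = binomial)
  fl <- lutadose:::firth_logistic(cbind(1, x), y)
  expect_equal(unname(coef(ml)), unname(fl$beta), tolerance = 0.05)
})

test_that("Spearman layer equals brute-force rank-Pearson and is rank-invariant", {
  set.seed(25)
  x <- runif(35); y <- -2 * x + rnorm(35, 0, 0.3)  # tie-free
  st <- lutadose:::spearman_test(x, y)
  expect_equal(st$rho, spearman_brute(x, y), tolerance = 1e-12)
  # strictly increasing transforms leave rho unchanged
  st2 <- lutadose:::spearman_test(exp(3 * x), y^3)
  expect_equal(st2$rho, st$rho, tolerance = 1e-12)
  # perfectly monotone decreasing: rho = -1
  expect_equal(lutadose:::spearman_test(1:10, -(1:10)^2)$rho, -1)
  # exact path for small tie-free samples
  st_small <- lutadose:::spearman_test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
  expect_equal(st_small$method, "exact")
  expect_equal(st_small$p,
               cor.test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7),
                        method = "spearman", exact = TRUE)$p.value)
  expect_error(lutadose:::spearman_test(rep(1, 10), rnorm(10)),
               class = "lutadose_value_error")
})

test_that("toxicity correlation table reports one row per organ-lab pair", {
  coh <- generate_cohort(cohort_config(seed = 26))
  labs <- coh$labs  # carries the generating organ cumulative doses
  tox <- correlate_toxicity(labs)
  expect_setequal(tox$correlations$lab, unique(labs$lab))
  bm <- tox$correlations[tox$correlations$organ == "bone_marrow", ]
  expect_true(all(bm$rho[bm$lab %in% c("platelets", "lymphocytes")] < 0))
  expect_true(all(tox$correlations$n == 35))
  expect_true(all(abs(tox$correlations$rho) <= 1))
  expect_true(all(c("cum_ad_gy", "pct_change_trend") %in% names(tox$trends)))
})

test_that("paired lab test matches the closed-form t statistic", {
  set.seed(27)
  base <- rnorm(30, 10, 1)
  up <- base + 1 + rnorm(30, 0, 0.05)
  res <- paired_lab_test(base, up)
  d <- up - base
  t_oracle <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 29), tolerance = 1e-12)
  expect_lt(res$p, 0.001)
  # identical visits: degenerate null with p = 1
  same <- paired_lab_test(base, base)
  expect_equal(same$p, 1)
  expect_equal(same$mean_diff, 0)
  expect_error(paired_lab_test(1, 1), class = "lutadose_insufficient_data")
  expect_error(paired_lab_test(base, base + 1), class = "lutadose_value_error")
})

test_that("identical groups give a hazard ratio of exactly 1", {
  t0 <- c(3, 5, 8, 13, 21, 34)
  times <- c(t0, t0); events <- rep(1, 12)
  cov <- rep(c(0, 1), each = 6)
  cmp <- survival_by_median(cov, times, events, "sym")
  expect_equal(cmp$hr, 1, tolerance = 1e-8)
  expect_equal(unname(cmp$medians["low"]), unname(cmp$medians["high"]))
})

test_that("Cox hazard ratio inverts when groups are relabeled", {
  set.seed(28)
  cov <- runif(80)
  times <- rexp(80, 0.05 * exp(-1.2 * (cov >= median(cov))))
  events <- as.integer(times < 30); times <- pmin(times, 30)
  a <- survival_by_median(cov, times, events)
  b <- survival_by_median(-cov, times, events)  # swaps high/low membership
  expect_equal(log(a$hr), -log(b$hr), tolerance = 1e-6)
})

test_that("KM estimator equals the empirical survivor function without censoring", {
  set.seed(29)
  times <- sort(rexp(40, 0.1)) + 0.01
  cov <- rep(c(0, 1), 20)
  cmp <- survival_by_median(cov, times, rep(1, 40))
  for (g in c("low", "high")) {
    km <- cmp$km[cmp$km$group == g, ]
    tg <- times[(cov >= cmp$cutoff) == (g == "high")]
    emp <- vapply(km$time, function(u) mean(tg > u), 0)
    expect_equal(km$surv, emp, tolerance = 1e-12)
  }
})

test_that("no events leaves KM flat and medians not reached", {
  cmp <- survival_by_median(c(1, 2, 3, 4, 5, 6), rep(10, 6), rep(0, 6))
  expect_true(all(is.na(cmp$medians)))
  expect_false(cmp$hr_estimable)
  expect_true(all(cmp$km$surv == 1) || nrow(cmp$km) == 0)
})

test_that("median dichotomization puts median-valued patients in the high group", {
  cov <- c(1, 2, 3, 3, 9, 10)
  cmp <- survival_by_median(cov, 1:6, rep(1, 6))
  expect_equal(cmp$cutoff, 3)
  grp <- cmp$groups
  n_high <- sum(grp$Freq[grp$group == "high"])
  expect_equal(n_high, 4)  # both 3s are >= the median
})
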