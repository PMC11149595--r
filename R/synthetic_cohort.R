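#' Configuration for a synthetic PRRT dosimetry cohort
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults emulate a
#' 35-patient GEP-NET cohort treated with 4 cycles of 7.4 GBq
#' \[177Lu\]Lu-DOTATATE: 1--9 lesions per patient (mostly liver and lymph
#' node), lognormal lesion volumes, monoexponential washout with effective
#' half-lives bounded by the 159.5 h physical half-life of 177Lu, Poisson
#' counting noise, volume-dependent partial-volume loss, a per-cycle decline
#' of lesion uptake, a plateaued dose--volume response, linear dose-dependent
#' hematologic decline and proportional-hazards survival.
#'
#' @param n_patients number of patients.
#' @param lesions_per_patient_range integer range (min, max), sampled
#'   uniformly.
#' @param site_distribution named nonnegative weights over
#'   `liver, lymph_node, mesentery, pancreas, peritoneum, bone`; must sum
#'   to 1 (within 1e-8).
#' @param volume_lognormal_params `c(meanlog, sdlog)` of lesion baseline
#'   volume in mL.
#' @param kinetics_priors named list per structure class; each element is
#'   `list(a0 = c(mean, cv), half_life = c(mean, cv))` giving the lognormal
#'   prior of the initial activity concentration (MBq/mL, back-extrapolated
#'   to injection) and of the effective half-life (h).
#' @param organ_volumes named list per organ of `c(mean_ml, cv)`.
#' @param injected_activity_mbq injected activity per cycle (MBq).
#' @param n_cycles_distribution named weights over 2, 3 and 4 cycles.
#' @param cycle_dose_decay multiplicative decline of lesion uptake per cycle
#'   (1 = no decline); healthy-organ uptake is held stable.
#' @param response_model_params `list(floor, cap, rate, noise_sd)` of the
#'   plateaued response \eqn{\Delta V\% = floor + (cap-floor) e^{-rate \cdot
#'   AD} + \epsilon}; floor/cap in percent, rate in 1/Gy.
#' @param tox_model_params data.frame with columns `lab`, `organ`,
#'   `slope_pct_per_gy`, `noise_sd_pct`, `baseline_mean`, `baseline_sd`:
#'   percent lab change at month 3 is linear in the organ's cumulative
#'   absorbed dose.
#' @param survival_model_params list per endpoint (`pfs`, `os`) of
#'   `list(median_months, beta_per_gy, ad_ref_gy)`: exponential baseline
#'   with the stated median at the reference mean lesion dose and log-hazard
#'   linear in the patient's true mean total lesion dose.
#' @param censoring_months `c(min, max)` administrative censoring window.
#' @param counting `list(cf, duration_s, noise_free)`: calibration factor
#'   (counts/s/MBq), acquisition duration (s), and whether Poisson draws are
#'   replaced by their means.
#' @param pve a [recovery_curve()] applied to expected lesion counts
#'   (volume-dependent partial-volume loss), or `NULL` for none.
#' @param density_g_ml tissue density used throughout.
#' @param schedule_full_h acquisition times (h) of fully sampled cycles 1--2.
#' @param stp_time_h single acquisition time of cycles 3--4.
#' @param patient_effect_cv optional lognormal patient-level random effect
#'   on uptake (coefficient of variation; 0 disables it).
#' @param response_noise_sd,tox_noise_scale convenience overrides applied on
#'   top of the model parameter lists (`NULL` = keep).
#' @param seed integer root seed; all randomness flows from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_patients = 35L,
    lesions_per_patient_range = c(1L, 9L),
    site_distribution = c(liver = 0.60, lymph_node = 0.23, mesentery = 0.04,
                          pancreas = 0.04, peritoneum = 0.02, bone = 0.07),
    volume_lognormal_params = c(meanlog = log(10), sdlog = 1.0),
    kinetics_priors = list(
      lesion      = list(a0 = c(mean = 3.0,   cv = 0.55), half_life = c(mean = 80, cv = 0.25)),
      liver       = list(a0 = c(mean = 0.135, cv = 0.35), half_life = c(mean = 67, cv = 0.15)),
      kidneys     = list(a0 = c(mean = 0.40,  cv = 0.30), half_life = c(mean = 55, cv = 0.15)),
      spleen      = list(a0 = c(mean = 0.45,  cv = 0.30), half_life = c(mean = 65, cv = 0.15)),
      bone_marrow = list(a0 = c(mean = 0.042, cv = 0.40), half_life = c(mean = 60, cv = 0.15))),
    organ_volumes = list(liver = c(1400, 0.15), kidneys = c(300, 0.15),
                         spleen = c(220, 0.25), bone_marrow = c(45, 0.15)),
    injected_activity_mbq = 7400,
    n_cycles_distribution = c(`2` = 0.06, `3` = 0.08, `4` = 0.86),
    cycle_dose_decay = 0.85,
    response_model_params = list(floor = -45, cap = 30, rate = 0.02,
                                 noise_sd = 15),
    tox_model_params = data.frame(
      lab = c("hemoglobin", "leukocytes", "lymphocytes", "neutrophils",
              "platelets", "gfr"),
      organ = c(rep("bone_marrow", 5), "kidneys"),
      slope_pct_per_gy = c(-5, -25, -30, -22, -28, 0),
      noise_sd_pct = c(5, 10, 10, 10, 10, 8),
      baseline_mean = c(13.4, 6.5, 1.5, 4.0, 218, 72),
      baseline_sd = c(1.3, 2.2, 0.5, 1.5, 68, 15),
      stringsAsFactors = FALSE),
    survival_model_params = list(
      pfs = list(median_months = 30, beta_per_gy = -0.012, ad_ref_gy = 91),
      os  = list(median_months = 57, beta_per_gy = -0.012, ad_ref_gy = 91)),
    censoring_months = c(36, 72),
    counting = list(cf = 10, duration_s = 2700, noise_free = FALSE),
    pve = default_recovery_curve(),
    density_g_ml = 1.0,
    schedule_full_h = c(4, 24, 72, 192),
    stp_time_h = 24,
    patient_effect_cv = 0,
    response_noise_sd = NULL,
    tox_noise_scale = NULL,
    seed = 0L) {

  if (!is.null(response_noise_sd))
    response_model_params$noise_sd <- response_noise_sd
  if (!is.null(tox_noise_scale))
    tox_model_params$noise_sd_pct <- tox_model_params$noise_sd_pct * tox_noise_scale

  cfg <- list(
    n_patients = as.integer(n_patients),
    lesions_per_patient_range = as.integer(lesions_per_patient_range),
    site_distribution = site_distribution,
    volume_lognormal_params = volume_lognormal_params,
    kinetics_priors = kinetics_priors,
    organ_volumes = organ_volumes,
    injected_activity_mbq = injected_activity_mbq,
    n_cycles_distribution = n_cycles_distribution,
    cycle_dose_decay = cycle_dose_decay,
    response_model_params = response_model_params,
    tox_model_params = tox_model_params,
    survival_model_params = survival_model_params,
    censoring_months = censoring_months,
    counting = counting,
    pve = pve,
    density_g_ml = density_g_ml,
    schedule_full_h = schedule_full_h,
    stp_time_h = stp_time_h,
    patient_effect_cv = patient_effect_cv,
    led_constant = lu177_constants$led_j_per_decay,
    physical_half_life_h = lu177_constants$half_life_h,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  check_weights <- function(w, name) {
    if (any(!is.finite(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-8)
      stop_lutadose(sprintf("`%s` must be nonnegative weights summing to 1",
                            name), "lutadose_config_error")
  }
  check_weights(cfg$site_distribution, "site_distribution")
  check_weights(cfg$n_cycles_distribution, "n_cycles_distribution")
  if (cfg$n_patients < 1L)
    stop_lutadose("n_patients must be >= 1", "lutadose_config_error")
  r <- cfg$lesions_per_patient_range
  if (length(r) != 2L || r[1L] < 0L || r[2L] < r[1L])
    stop_lutadose("invalid lesions_per_patient_range", "lutadose_config_error")
  if (cfg$volume_lognormal_params[[2L]] < 0)
    stop_lutadose("volume sdlog must be >= 0", "lutadose_config_error")
  for (cl in names(cfg$kinetics_priors)) {
    kp <- cfg$kinetics_priors[[cl]]
    if (kp$a0[["mean"]] <= 0 || kp$a0[["cv"]] < 0 ||
        kp$half_life[["mean"]] <= 0 || kp$half_life[["cv"]] < 0)
      stop_lutadose(sprintf("invalid kinetics prior for class '%s'", cl),
                    "lutadose_config_error")
    if (kp$half_life[["mean"]] > cfg$physical_half_life_h)
      stop_lutadose(sprintf(
        "mean effective half-life for '%s' exceeds the physical half-life of 177Lu",
        cl), "lutadose_config_error")
  }
  if (cfg$cycle_dose_decay <= 0)
    stop_lutadose("cycle_dose_decay must be > 0", "lutadose_config_error")
  if (cfg$response_model_params$noise_sd < 0 ||
      any(cfg$tox_model_params$noise_sd_pct < 0))
    stop_lutadose("noise SDs must be >= 0", "lutadose_config_error")
  if (cfg$counting$cf <= 0 || cfg$counting$duration_s <= 0)
    stop_lutadose("counting parameters must be > 0", "lutadose_config_error")
  invisible(cfg)
}

# lognormal draw parameterized by mean and coefficient of variation
r_lognormal_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# effective half-life: lognormal prior with the stated mean, rejection-
# resampled below the physical half-life of 177Lu
r_half_life <- function(n, mean_h, cv, max_h = lu177_constants$half_life_h) {
  x <- r_lognormal_mean_cv(n, mean_h, cv)
  bad <- which(x >= max_h)
  guard <- 0L
  while (length(bad) && guard < 1000L) {
    x[bad] <- r_lognormal_mean_cv(length(bad), mean_h, cv)
    bad <- bad[x[bad] >= max_h]
    guard <- guard + 1L
  }
  if (length(bad)) x[bad] <- max_h * 0.999
  x
}

# dose rate (Gy/h) of 1 MBq/mL at the given density under LED
led_doserate_per_conc <- function(led_constant, density_g_ml) {
  1e6 * led_constant * 3600 * 1000 / density_g_ml
}

#' Generate a synthetic PRRT cohort with known ground truth
#'
#' Simulates every table the dosimetry and outcome pipeline consumes,
#' together with the generating truth, under one root seed. Observed counts
#' at time t are Poisson with mean
#' \eqn{A_0 V e^{-\lambda_{\mathrm{eff}} t} \cdot cf \cdot duration \cdot
#' RC(V)} (RC applied to lesions); cycles 1--2 are imaged at the full
#' schedule and cycles 3--4 once at 24 h. Lesion uptake declines
#' multiplicatively over cycles; the effective half-life of a structure is
#' shared across its cycles. Volume response follows the plateaued model,
#' lab changes are linear in the organ cumulative dose, and survival is
#' exponential with log-hazard linear in the true mean total lesion dose.
#'
#' @param config a [cohort_config()].
#' @return A list of class `synthetic_cohort`:
#' \describe{
#'   \item{timepoints}{VOI time-point table (one row per acquisition per
#'     structure) with the columns [compute_cycle_doses()] expects.}
#'   \item{lesions}{per lesion: `patient_id`, `lesion_id`, `site`,
#'     `v_bl_ml`, `v_m3_ml`.}
#'   \item{labs}{per patient and lab: baseline and month-3 values and the
#'     observed percent change.}
#'   \item{survival}{per patient and endpoint (`pfs`, `os`): `time_months`,
#'     `event`.}
#'   \item{truth}{list of `kinetics` (per structure-cycle true `a0`,
#'     `lambda_eff`, `ad_gy`), `lesions` (true total dose and true
#'     \eqn{\Delta V\%}), `patients` (true mean/min/max total lesion dose
#'     and per-endpoint log-hazard). Never consumed by the pipeline.}
#'   \item{config}{the generating configuration.}
#' }
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 3, seed = 7))
#' head(coh$timepoints)
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  cfg <- config
  pad <- max(2L, nchar(as.character(cfg$n_patients)))
  pid <- sprintf(paste0("P%0", pad, "d"), seq_len(cfg$n_patients))

  n_cycles <- as.integer(sample(names(cfg$n_cycles_distribution),
                                cfg$n_patients, replace = TRUE,
                                prob = cfg$n_cycles_distribution))
  pat_eff <- r_lognormal_mean_cv(cfg$n_patients, 1, cfg$patient_effect_cv)

  d0_per_conc <- led_doserate_per_conc(cfg$led_constant, cfg$density_g_ml)
  cf <- cfg$counting$cf
  dur <- cfg$counting$duration_s
  noise_free <- isTRUE(cfg$counting$noise_free)
  organs <- names(cfg$organ_volumes)
  n_org <- length(organs)

  # one structure table for the whole cohort: organs first, then lesions
  nles <- sample(seq(cfg$lesions_per_patient_range[1L],
                     cfg$lesions_per_patient_range[2L]),
                 cfg$n_patients, replace = TRUE)
  organ_vol <- vapply(organs, function(o)
    r_lognormal_mean_cv(cfg$n_patients, cfg$organ_volumes[[o]][1L],
                        cfg$organ_volumes[[o]][2L]), numeric(cfg$n_patients))
  organ_vol <- matrix(organ_vol, nrow = cfg$n_patients)
  les_pat <- rep(seq_len(cfg$n_patients), nles)
  sites <- sample(names(cfg$site_distribution), sum(nles), replace = TRUE,
                  prob = cfg$site_distribution)
  lvol <- stats::rlnorm(sum(nles), cfg$volume_lognormal_params[[1L]],
                        cfg$volume_lognormal_params[[2L]])
  les_idx <- unlist(lapply(nles, seq_len), use.names = FALSE)

  structs <- data.frame(
    patient = c(rep(seq_len(cfg$n_patients), each = n_org), les_pat),
    structure_id = c(rep(organs, cfg$n_patients),
                     sprintf("%s_L%02d", pid[les_pat], les_idx)),
    structure_class = c(rep(organs, cfg$n_patients), rep("lesion", sum(nles))),
    site = c(rep(NA_character_, n_org * cfg$n_patients), sites),
    volume_ml = c(as.vector(t(organ_vol)), lvol),
    stringsAsFactors = FALSE)

  # kinetics drawn per structure, grouped by class to keep draws vectorized
  structs$a0_base <- NA_real_
  structs$lambda <- NA_real_
  for (cl in unique(structs$structure_class)) {
    kp <- cfg$kinetics_priors[[cl]]
    sel <- which(structs$structure_class == cl)
    structs$a0_base[sel] <-
      r_lognormal_mean_cv(length(sel), kp$a0[["mean"]], kp$a0[["cv"]]) *
      pat_eff[structs$patient[sel]]
    structs$lambda[sel] <- log(2) /
      r_half_life(length(sel), kp$half_life[["mean"]], kp$half_life[["cv"]],
                  cfg$physical_half_life_h)
  }
  structs$rc <- 1
  if (!is.null(cfg$pve)) {
    isles <- structs$structure_class == "lesion"
    structs$rc[isles] <- rc_at(cfg$pve, structs$volume_ml[isles])
  }

  # expand structures over cycles, then over acquisition times
  s_cyc <- structs[rep(seq_len(nrow(structs)), n_cycles[structs$patient]), ]
  s_cyc$cycle <- unlist(lapply(n_cycles[structs$patient], seq_len),
                        use.names = FALSE)
  decay <- ifelse(s_cyc$structure_class == "lesion", cfg$cycle_dose_decay, 1)
  s_cyc$a0 <- s_cyc$a0_base * decay^(s_cyc$cycle - 1L)

  kinetics <- data.frame(
    patient_id = pid[s_cyc$patient], cycle = s_cyc$cycle,
    structure_id = s_cyc$structure_id, structure_class = s_cyc$structure_class,
    a0_mbq_ml = s_cyc$a0, lambda_eff_per_h = s_cyc$lambda,
    ad_gy = s_cyc$a0 * d0_per_conc / s_cyc$lambda,
    stringsAsFactors = FALSE)

  ntimes <- ifelse(s_cyc$cycle <= 2L, length(cfg$schedule_full_h), 1L)
  row_tp <- rep(seq_len(nrow(s_cyc)), ntimes)
  t_h <- unlist(lapply(seq_len(nrow(s_cyc)), function(r)
    if (s_cyc$cycle[r] <= 2L) cfg$schedule_full_h else cfg$stp_time_h),
    use.names = FALSE)
  mu <- s_cyc$a0[row_tp] * s_cyc$volume_ml[row_tp] *
    exp(-s_cyc$lambda[row_tp] * t_h) * cf * dur * s_cyc$rc[row_tp]
  timepoints <- data.frame(
    patient_id = pid[s_cyc$patient[row_tp]], cycle = s_cyc$cycle[row_tp],
    structure_id = s_cyc$structure_id[row_tp],
    structure_class = s_cyc$structure_class[row_tp],
    t_h = t_h, counts = mu, duration_s = dur,
    volume_ml = s_cyc$volume_ml[row_tp], density_g_ml = cfg$density_g_ml,
    stringsAsFactors = FALSE)
  # counting noise applied after all kinetics draws, so noise-free and
  # Poisson runs of the same seed share identical ground truth
  if (!noise_free)
    timepoints$counts <- stats::rpois(nrow(timepoints), timepoints$counts)

  lesions <- data.frame(
    patient_id = pid[les_pat],
    lesion_id = sprintf("%s_L%02d", pid[les_pat], les_idx),
    site = sites, v_bl_ml = lvol, stringsAsFactors = FALSE)
  rownames(timepoints) <- rownames(kinetics) <- rownames(lesions) <- NULL

  # true total lesion doses and plateaued volume response
  les_tot <- stats::aggregate(ad_gy ~ structure_id,
                              data = kinetics[kinetics$structure_class == "lesion", ],
                              FUN = sum)
  lesions$total_ad_true_gy <- les_tot$ad_gy[match(lesions$lesion_id,
                                                  les_tot$structure_id)]
  rp <- cfg$response_model_params
  dv_true <- rp$floor + (rp$cap - rp$floor) * exp(-rp$rate * lesions$total_ad_true_gy)
  dv_obs <- pmax(dv_true + stats::rnorm(nrow(lesions), 0, rp$noise_sd), -100)
  lesions$v_m3_ml <- lesions$v_bl_ml * (1 + dv_obs / 100)

  truth_lesions <- data.frame(
    patient_id = lesions$patient_id, lesion_id = lesions$lesion_id,
    total_ad_gy = lesions$total_ad_true_gy, delta_v_pct_true = dv_true,
    stringsAsFactors = FALSE)
  lesions$total_ad_true_gy <- NULL

  # organ cumulative doses drive the toxicity layer
  org_kin <- kinetics[kinetics$structure_class != "lesion", ]
  org_cum <- stats::aggregate(ad_gy ~ patient_id + structure_class,
                              data = org_kin, FUN = sum)
  labs <- do.call(rbind, lapply(seq_len(nrow(cfg$tox_model_params)), function(k) {
    tm <- cfg$tox_model_params[k, ]
    cum <- org_cum[org_cum$structure_class == tm$organ, ]
    cum <- cum[match(pid, cum$patient_id), ]
    base <- pmax(stats::rnorm(cfg$n_patients, tm$baseline_mean, tm$baseline_sd),
                 tm$baseline_mean * 0.2)
    pct <- tm$slope_pct_per_gy * cum$ad_gy +
      stats::rnorm(cfg$n_patients, 0, tm$noise_sd_pct)
    pct <- pmax(pct, -100)
    data.frame(patient_id = pid, lab = tm$lab, organ = tm$organ,
               organ_cum_ad_gy = cum$ad_gy, baseline = base,
               month3 = base * (1 + pct / 100), pct_change = pct,
               stringsAsFactors = FALSE)
  }))
  rownames(labs) <- NULL

  # survival: exponential hazard, log-linear in true mean total lesion dose
  pat_truth <- do.call(rbind, lapply(split(truth_lesions, truth_lesions$patient_id),
    function(p) data.frame(patient_id = p$patient_id[1L],
                           mean_total_ad_true = mean(p$total_ad_gy),
                           min_total_ad_true = min(p$total_ad_gy),
                           max_total_ad_true = max(p$total_ad_gy),
                           stringsAsFactors = FALSE)))
  pat_truth <- pat_truth[match(pid, pat_truth$patient_id), ]
  rownames(pat_truth) <- NULL

  surv <- list()
  for (ep in names(cfg$survival_model_params)) {
    sm <- cfg$survival_model_params[[ep]]
    h0 <- log(2) / sm$median_months
    lp <- sm$beta_per_gy * (pat_truth$mean_total_ad_true - sm$ad_ref_gy)
    t_event <- stats::rexp(cfg$n_patients, h0 * exp(lp))
    t_cens <- stats::runif(cfg$n_patients, cfg$censoring_months[1L],
                           cfg$censoring_months[2L])
    surv[[ep]] <- data.frame(
      patient_id = pid, endpoint = ep,
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE)
    pat_truth[[paste0("log_hazard_", ep)]] <- lp
  }
  survival_tab <- do.call(rbind, surv); rownames(survival_tab) <- NULL

  structure(list(
    timepoints = timepoints, lesions = lesions, labs = labs,
    survival = survival_tab,
    truth = list(kinetics = kinetics, lesions = truth_lesions,
                 patients = pat_truth),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic PRRT cohort: %d patients, %d lesions, %d VOI time points (seed %d)\n",
    x$config$n_patients, nrow(x$lesions), nrow(x$timepoints), x$config$seed))
  invisible(x)
}

#' Simulate sphere-phantom images for recovery-coefficient calibration
#'
#' Places uniform-activity spheres in a 3D voxel grid, blurs the grid with an
#' isotropic Gaussian point-spread function (separable convolution,
#' zero-padded, kernel truncated at 4 sigma) and measures the in-mask
#' recovered fraction of each sphere, i.e. its recovery coefficient.
#'
#' @param sphere_volumes_ml sphere volumes in mL.
#' @param psf_sigma_mm Gaussian PSF sigma in mm (>= 0; 0 means no blur).
#' @param grid_dim integer grid dimensions (voxels), length 3.
#' @param voxel_mm isotropic voxel size in mm.
#' @param centers optional matrix (n x 3) of sphere centers in voxel
#'   coordinates; auto-placed on a non-overlapping lattice when `NULL`.
#' @return list with `rc` (data.frame `volume_ml`, `radius_mm`, `rc`),
#'   `image` (blurred 3D array), `labels` (integer 3D array, 0 background).
#' @export
#' @examples
#' ph <- generate_phantom_images(c(2, 20), psf_sigma_mm = 0,
#'                               grid_dim = c(32, 32, 32), voxel_mm = 3)
#' ph$rc
generate_phantom_images <- function(sphere_volumes_ml, psf_sigma_mm,
                                    grid_dim = c(64L, 64L, 64L),
                                    voxel_mm = 2.5, centers = NULL) {
  if (any(sphere_volumes_ml <= 0))
    stop_lutadose("sphere volumes must be > 0", "lutadose_value_error")
  if (psf_sigma_mm < 0)
    stop_lutadose("psf_sigma_mm must be >= 0", "lutadose_value_error")
  n <- length(sphere_volumes_ml)
  radii_mm <- (3 * sphere_volumes_ml * 1000 / (4 * pi))^(1 / 3)
  radii_vox <- radii_mm / voxel_mm

  if (is.null(centers)) {
    # spheres in a row along axis 1, separated by the blur tail plus margin
    tail_vox <- 4 * psf_sigma_mm / voxel_mm
    gap <- tail_vox + 2
    cx <- numeric(n)
    cx[1L] <- radii_vox[1L] + tail_vox + 1
    if (n > 1L) for (k in 2:n)
      cx[k] <- cx[k - 1L] + radii_vox[k - 1L] + radii_vox[k] + gap
    if (cx[n] + radii_vox[n] + tail_vox + 1 > grid_dim[1L])
      stop_lutadose("grid too small to place all spheres without overlap",
                    "lutadose_value_error")
    centers <- cbind(cx, grid_dim[2L] / 2, grid_dim[3L] / 2)
  }
  centers <- matrix(centers, ncol = 3L)
  for (k in seq_len(n)) {
    if (any(centers[k, ] - radii_vox[k] < 0) ||
        any(centers[k, ] + radii_vox[k] > grid_dim))
      stop_lutadose("sphere does not fit inside the grid",
                    "lutadose_value_error")
  }
  if (n > 1L) {
    d <- as.matrix(stats::dist(centers))
    rsum <- outer(radii_vox, radii_vox, `+`)
    diag(d) <- Inf
    if (any(d <= rsum))
      stop_lutadose("spheres overlap", "lutadose_value_error")
  }

  labels <- array(0L, dim = grid_dim)
  x <- seq_len(grid_dim[1L]); y <- seq_len(grid_dim[2L]); z <- seq_len(grid_dim[3L])
  for (k in seq_len(n)) {
    dx2 <- (x - centers[k, 1L])^2
    dy2 <- (y - centers[k, 2L])^2
    dz2 <- (z - centers[k, 3L])^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radii_vox[k]^2
    labels[inside] <- k
  }
  ideal <- array(as.numeric(labels > 0L), dim = grid_dim)
  blurred <- gaussian_blur_3d(ideal, psf_sigma_mm / voxel_mm)

  rc <- vapply(seq_len(n), function(k) {
    m <- labels == k
    sum(blurred[m]) / sum(ideal[m])
  }, 0)
  list(rc = data.frame(volume_ml = sphere_volumes_ml, radius_mm = radii_mm,
                       rc = rc),
       image = blurred, labels = labels)
}

#' Write phantom grids to NIfTI files
#'
#' Saves the blurred count grid and the sphere label mask of a
#' [generate_phantom_images()] result as NIfTI volumes (requires the
#' suggested RNifti package).
#'
#' @param phantom result of [generate_phantom_images()].
#' @param path_prefix output path prefix; writes `<prefix>_counts.nii.gz`
#'   and `<prefix>_labels.nii.gz`.
#' @param voxel_mm isotropic voxel size recorded in the header.
#' @return invisibly, the two file paths.
#' @export
save_phantom_nifti <- function(phantom, path_prefix, voxel_mm = 2.5) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_lutadose("NIfTI export requires the RNifti package",
                  "lutadose_value_error")
  paths <- paste0(path_prefix, c("_counts.nii.gz", "_labels.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$image,
                                     pixdim = rep(voxel_mm, 3)), paths[1L])
  RNifti::writeNifti(RNifti::asNifti(phantom$labels,
                                     pixdim = rep(voxel_mm, 3)), paths[2L])
  invisible(paths)
}

# separable 3D Gaussian convolution, sigma in voxels, zero-padded edges
gaussian_blur_3d <- function(arr, sigma_vox) {
  if (sigma_vox == 0) return(arr)
  h <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-h, h), sd = sigma_vox)
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), nrow = d[axis])
    K <- matrix(0, d[axis], d[axis])
    for (o in seq(-h, h)) {
      i <- seq_len(d[axis])
      j <- i + o
      ok <- j >= 1 & j <= d[axis]
      K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + k[o + h + 1L]
    }
    out <- K %*% m
    aperm(array(out, dim = d[perm]), order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}
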