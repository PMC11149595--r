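#' Convert VOI counts to an absorbed dose rate (local energy deposition)
#'
#' Quantifies the activity in a VOI from detected counts and converts it to a
#' dose rate under the local energy deposition (LED) approximation with
#' density correction: all electron emission energy of each decay is assumed
#' absorbed within the VOI, photons are neglected.
#'
#' The chain is
#' \deqn{A = \mathrm{counts} / (\mathrm{duration} \cdot \mathrm{cf})
#'   \ \mathrm{MBq}, \qquad
#'   \dot D = A \cdot 10^{6} \cdot E_{\mathrm{LED}} \cdot 3600 / m
#'   \ \mathrm{Gy/h},}
#' with \eqn{E_{\mathrm{LED}}} the locally deposited energy per decay in J
#' and \eqn{m = V \rho / 1000} the VOI mass in kg. The result is linear in
#' counts and inverse-linear in mass.
#'
#' @param counts detected counts in the VOI (>= 0).
#' @param duration_s acquisition duration in seconds.
#' @param cf calibration factor in counts per second per MBq.
#' @param volume_ml VOI volume in mL.
#' @param density_g_ml tissue density in g/mL (default 1).
#' @param led_constant locally deposited energy per decay in J; default
#'   `lu177_constants$led_j_per_decay`.
#' @return dose rate in Gy/h (vectorized over the inputs).
#' @export
#' @examples
#' # 100 MBq in 1 kg of tissue
#' counts_to_doserate(counts = 100 * 10 * 60, duration_s = 60, cf = 10,
#'                    volume_ml = 1000, density_g_ml = 1)
counts_to_doserate <- function(counts, duration_s, cf, volume_ml,
                               density_g_ml = 1,
                               led_constant = lu177_constants$led_j_per_decay) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_lutadose("counts must be finite and >= 0", "lutadose_value_error")
  if (any(duration_s <= 0) || any(cf <= 0))
    stop_lutadose("duration and calibration factor must be > 0",
                  "lutadose_value_error")
  if (any(volume_ml <= 0) || any(density_g_ml <= 0))
    stop_lutadose("volume and density must be > 0", "lutadose_value_error")
  check_scalar_pos(led_constant, "led_constant")
  activity_mbq <- counts / (duration_s * cf)
  mass_kg <- volume_ml * density_g_ml / 1000
  activity_mbq * 1e6 * led_constant * 3600 / mass_kg
}

#' Fit a monoexponential washout model to dose-rate measurements
#'
#' Fits \eqn{\dot D(t) = \dot D_0 e^{-\lambda_{\mathrm{eff}} t}} to at least
#' three (time, dose rate) points by unweighted least squares on the log dose
#' rate, which is closed form for the 3--4 points of a fully sampled cycle.
#' The effective decay constant combines physical decay and biological
#' clearance, so a fit below the physical decay constant of 177Lu implies
#' negative biological clearance; such fits are flagged (default) or rejected
#' (`strict = TRUE`), since counting noise can legitimately produce them.
#'
#' @param t_h acquisition times in hours post-injection (distinct, > 0).
#' @param doserate_gy_h dose rates in Gy/h (strictly positive).
#' @param strict reject fits with `lambda_eff` below the physical decay
#'   constant instead of flagging them.
#' @return An object of class `monoexp_fit`: list with `d0` (Gy/h),
#'   `lambda_eff` (1/h), `n`, `rss_log` (residual sum of squares on the log
#'   scale) and `below_physical` flag.
#' @export
#' @examples
#' t <- c(4, 24, 72, 192)
#' fit <- fit_monoexponential(t, 1.0 * exp(-0.05 * t))
#' c(fit$d0, fit$lambda_eff)
fit_monoexponential <- function(t_h, doserate_gy_h, strict = FALSE) {
  if (length(t_h) != length(doserate_gy_h))
    stop_lutadose("time and dose-rate vectors must have equal length",
                  "lutadose_value_error")
  if (length(t_h) < 3L)
    stop_lutadose(
      "monoexponential fit needs >= 3 time points; use single-time-point scaling",
      "lutadose_insufficient_data")
  if (any(!is.finite(t_h)) || any(t_h <= 0) || anyDuplicated(t_h))
    stop_lutadose("times must be positive, finite and distinct",
                  "lutadose_value_error")
  if (any(!is.finite(doserate_gy_h)) || any(doserate_gy_h <= 0))
    stop_lutadose("dose rates must be strictly positive for a log-linear fit",
                  "lutadose_value_error")
  y <- log(doserate_gy_h)
  co <- stats::lm.fit(cbind(1, t_h), y)
  d0 <- exp(co$coefficients[[1L]])
  lambda <- -co$coefficients[[2L]]
  if (!is.finite(lambda) || lambda <= 0)
    stop_lutadose("fitted kinetics do not clear (lambda_eff <= 0)",
                  "lutadose_nonclearing")
  below <- lambda < lu177_constants$lambda_phys_per_h
  if (below && strict)
    stop_lutadose(
      "lambda_eff below the physical decay constant of 177Lu (strict mode)",
      "lutadose_nonclearing")
  structure(list(d0 = d0, lambda_eff = lambda, n = length(t_h),
                 rss_log = sum(co$residuals^2), below_physical = below),
            class = "monoexp_fit")
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf(
    "Monoexponential fit: d0 = %.4g Gy/h, lambda_eff = %.4g /h (T1/2 = %.1f h), n = %d\n",
    x$d0, x$lambda_eff, log(2) / x$lambda_eff, x$n))
  if (x$below_physical)
    cat("  note: lambda_eff below physical decay constant of 177Lu\n")
  invisible(x)
}

#' Integrate a fitted monoexponential dose-rate curve to an absorbed dose
#'
#' The absorbed dose is the area under the fitted dose-rate curve from
#' injection (t = 0) to infinity:
#' \eqn{AD = \int_0^\infty \dot D_0 e^{-\lambda t}\,dt = \dot D_0/\lambda}.
#' Hours cancel, leaving Gy.
#'
#' @param fit a `monoexp_fit`, or a list with elements `d0` and `lambda_eff`.
#' @return absorbed dose in Gy.
#' @export
integrate_monoexp <- function(fit) {
  d0 <- fit$d0; lambda <- fit$lambda_eff
  check_scalar_pos(d0, "d0", allow_zero = TRUE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop_lutadose("lambda_eff must be > 0 to integrate", "lutadose_value_error")
  d0 / lambda
}

#' Single-time-point absorbed-dose scaling for later cycles
#'
#' Later cycles imaged only once at 24 h are scaled from a fully sampled
#' reference cycle (cycle 2):
#' \deqn{AD_{c3/4} = AD_{c2} \times
#'   \frac{\mathrm{counts}_{24h,c3/4}}{\mathrm{counts}_{24h,c2}} \times
#'   \frac{V_{24h,c2}}{V_{24h,c3/4}}.}
#' The count ratio carries the activity-concentration change and the volume
#' ratio restores the per-mass normalization. This assumes the new cycle
#' shares the reference cycle's effective washout.
#'
#' @param ad_cycle2 reference-cycle absorbed dose in Gy.
#' @param counts24_new 24 h counts of the cycle being estimated (>= 0).
#' @param counts24_c2 24 h counts of the reference cycle (> 0).
#' @param v24_c2 reference-cycle VOI volume in mL (> 0).
#' @param v24_new new-cycle VOI volume in mL (> 0).
#' @return absorbed dose in Gy.
#' @export
#' @examples
#' scale_single_timepoint(25.64, counts24_new = 8e4, counts24_c2 = 1e5,
#'                        v24_c2 = 12, v24_new = 12)
scale_single_timepoint <- function(ad_cycle2, counts24_new, counts24_c2,
                                   v24_c2, v24_new) {
  check_scalar_pos(ad_cycle2, "ad_cycle2", allow_zero = TRUE)
  check_scalar_pos(counts24_new, "counts24_new", allow_zero = TRUE)
  check_scalar_pos(counts24_c2, "counts24_c2")
  check_scalar_pos(v24_c2, "v24_c2")
  check_scalar_pos(v24_new, "v24_new")
  ad_cycle2 * (counts24_new / counts24_c2) * (v24_c2 / v24_new)
}

#' Compute per-cycle absorbed doses for a cohort of VOI time points
#'
#' Runs the full dose engine on a tidy time-point table. For each
#' (patient, cycle, structure): counts are converted to dose rates
#' ([counts_to_doserate()]); cycles with >= 3 time points are fitted with a
#' monoexponential and integrated analytically; cycles with a single 24 h
#' point are scaled from the reference cycle with
#' [scale_single_timepoint()]. Lesion doses are then corrected for
#' partial-volume losses with `rc_curve`; healthy organs are assumed large
#' enough not to need it.
#'
#' By default (`volume_mode = "baseline"`) each structure uses one constant
#' volume across cycles (its first recorded volume), matching delineation on
#' a single reference CT; `volume_mode = "per_cycle"` uses each cycle's own
#' recorded volume instead.
#'
#' @param timepoints data.frame with columns `patient_id`, `cycle`,
#'   `structure_id`, `structure_class` (`"lesion"`, `"liver"`, `"kidneys"`,
#'   `"spleen"`, `"bone_marrow"`), `t_h`, `counts`, `duration_s`,
#'   `volume_ml`, `density_g_ml`.
#' @param cf calibration factor, counts/s/MBq.
#' @param rc_curve [recovery_curve()] for lesion partial-volume correction,
#'   or `NULL` to skip.
#' @param led_constant locally deposited energy per decay in J.
#' @param volume_mode `"baseline"` or `"per_cycle"`.
#' @param reference_cycle cycle used as the single-time-point reference
#'   (default 2).
#' @param stp_time_h nominal acquisition time of single-time-point cycles
#'   (default 24 h); the reference count is taken at the reference cycle's
#'   time point closest to this.
#' @return data.frame with one row per (patient, cycle, structure):
#'   `patient_id`, `cycle`, `structure_id`, `structure_class`, `ad_gy`,
#'   `method` (`"multi_timepoint"` or `"single_timepoint_scaled"`),
#'   `pve_corrected`, `lambda_eff`, `d0`, `below_physical`.
#' @export
compute_cycle_doses <- function(timepoints, cf,
                                rc_curve = default_recovery_curve(),
                                led_constant = lu177_constants$led_j_per_decay,
                                volume_mode = c("baseline", "per_cycle"),
                                reference_cycle = 2L,
                                stp_time_h = 24) {
  volume_mode <- match.arg(volume_mode)
  req <- c("patient_id", "cycle", "structure_id", "structure_class",
           "t_h", "counts", "duration_s", "volume_ml", "density_g_ml")
  miss <- setdiff(req, names(timepoints))
  if (length(miss))
    stop_lutadose(paste("time-point table missing column(s):",
                        paste(miss, collapse = ", ")),
                  "lutadose_schema_error")
  check_scalar_pos(cf, "cf")

  empty <- data.frame(
    patient_id = character(), cycle = integer(), structure_id = character(),
    structure_class = character(), ad_gy = numeric(), method = character(),
    pve_corrected = logical(), lambda_eff = numeric(), d0 = numeric(),
    below_physical = logical(), stringsAsFactors = FALSE)
  if (!nrow(timepoints)) return(empty)

  tp <- timepoints[order(timepoints$patient_id, timepoints$structure_id,
                         timepoints$cycle, timepoints$t_h), req]
  struct_key <- interaction(tp$patient_id, tp$structure_id, drop = TRUE)

  out <- list()
  for (sk in levels(struct_key)) {
    s <- tp[struct_key == sk, ]
    if (volume_mode == "baseline") s$volume_ml <- s$volume_ml[1L]
    s$doserate <- counts_to_doserate(s$counts, s$duration_s, cf, s$volume_ml,
                                     s$density_g_ml, led_constant)
    cycles <- sort(unique(s$cycle))

    # multi-time-point cycles first: the reference cycle must exist before
    # any single-time-point cycle can be scaled
    fits <- list(); ads <- list()
    for (cy in cycles) {
      sc <- s[s$cycle == cy, ]
      if (nrow(sc) >= 3L) {
        fit <- fit_monoexponential(sc$t_h, sc$doserate)
        fits[[as.character(cy)]] <- fit
        ads[[as.character(cy)]] <- data.frame(
          patient_id = sc$patient_id[1L], cycle = cy,
          structure_id = sc$structure_id[1L],
          structure_class = sc$structure_class[1L],
          ad_gy = integrate_monoexp(fit), method = "multi_timepoint",
          pve_corrected = FALSE, lambda_eff = fit$lambda_eff, d0 = fit$d0,
          below_physical = fit$below_physical,
          volume_ml = sc$volume_ml[1L], stringsAsFactors = FALSE)
      }
    }
    ref <- s[s$cycle == reference_cycle, ]
    ref_row <- if (nrow(ref)) ref[which.min(abs(ref$t_h - stp_time_h)), ] else NULL
    for (cy in cycles) {
      sc <- s[s$cycle == cy, ]
      if (nrow(sc) >= 3L) next
      if (is.null(ref_row) ||
          is.null(ads[[as.character(reference_cycle)]]))
        stop_lutadose(sprintf(
          "structure %s of patient %s: cycle %s has < 3 time points and no fitted reference cycle %d",
          sc$structure_id[1L], sc$patient_id[1L], cy, reference_cycle),
          "lutadose_insufficient_data")
      sc24 <- sc[which.min(abs(sc$t_h - stp_time_h)), ]
      ad <- scale_single_timepoint(
        ad_cycle2 = ads[[as.character(reference_cycle)]]$ad_gy,
        counts24_new = sc24$counts, counts24_c2 = ref_row$counts,
        v24_c2 = ref_row$volume_ml, v24_new = sc24$volume_ml)
      ads[[as.character(cy)]] <- data.frame(
        patient_id = sc$patient_id[1L], cycle = cy,
        structure_id = sc$structure_id[1L],
        structure_class = sc$structure_class[1L],
        ad_gy = ad, method = "single_timepoint_scaled",
        pve_corrected = FALSE, lambda_eff = NA_real_, d0 = NA_real_,
        below_physical = NA, volume_ml = sc24$volume_ml,
        stringsAsFactors = FALSE)
    }
    out[[sk]] <- do.call(rbind, ads)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL

  if (!is.null(rc_curve)) {
    les <- res$structure_class == "lesion"
    res$ad_gy[les] <- apply_recovery_correction(res$ad_gy[les],
                                                res$volume_ml[les], rc_curve)
    res$pve_corrected[les] <- TRUE
  }
  res$volume_ml <- NULL
  res
}

#' Aggregate cycle doses into per-course patient dosimetry
#'
#' Cumulative absorbed dose (CumAD) per structure is the exact sum of its
#' per-cycle absorbed doses over the treatment course. Per patient, the
#' lesion dose indices are the mean, minimum and maximum of the lesion
#' cumulative doses.
#'
#' @param cycle_doses data.frame as returned by [compute_cycle_doses()]
#'   (columns `patient_id`, `cycle`, `structure_id`, `structure_class`,
#'   `ad_gy`).
#' @return A list of class `patient_dosimetry` with
#'   \describe{
#'     \item{structures}{data.frame of `patient_id`, `structure_id`,
#'       `structure_class`, `n_cycles`, `cum_ad_gy`.}
#'     \item{patients}{data.frame of `patient_id`, `n_lesions`,
#'       `mean_total_ad`, `min_total_ad`, `max_total_ad` (Gy; `NA` when a
#'       patient has no lesions).}
#'   }
#' @export
compute_course_dosimetry <- function(cycle_doses) {
  req <- c("patient_id", "cycle", "structure_id", "structure_class", "ad_gy")
  miss <- setdiff(req, names(cycle_doses))
  if (length(miss))
    stop_lutadose(paste("cycle-dose table missing column(s):",
                        paste(miss, collapse = ", ")),
                  "lutadose_schema_error")
  key <- interaction(cycle_doses$patient_id, cycle_doses$structure_id,
                     drop = TRUE)
  structures <- do.call(rbind, lapply(split(cycle_doses, key), function(s) {
    data.frame(patient_id = s$patient_id[1L],
               structure_id = s$structure_id[1L],
               structure_class = s$structure_class[1L],
               n_cycles = nrow(s),
               cum_ad_gy = sum(s$ad_gy),
               stringsAsFactors = FALSE)
  }))
  rownames(structures) <- NULL

  patients <- do.call(rbind, lapply(
    split(structures, structures$patient_id), function(p) {
      les <- p$cum_ad_gy[p$structure_class == "lesion"]
      data.frame(patient_id = p$patient_id[1L],
                 n_lesions = length(les),
                 mean_total_ad = if (length(les)) mean(les) else NA_real_,
                 min_total_ad = if (length(les)) min(les) else NA_real_,
                 max_total_ad = if (length(les)) max(les) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(patients) <- NULL
  structure(list(structures = structures, patients = patients),
            class = "patient_dosimetry")
}

#' @export
print.patient_dosimetry <- function(x, ...) {
  cat(sprintf("Patient dosimetry: %d structures, %d patients\n",
              nrow(x$structures), nrow(x$patients)))
  les <- x$patients$mean_total_ad[!is.na(x$patients$mean_total_ad)]
  if (length(les))
    cat(sprintf("  median mean-total-AD over lesions: %.2f Gy\n", stats::median(les)))
  invisible(x)
}
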