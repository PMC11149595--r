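#' Recovery-coefficient curve for partial-volume correction
#'
#' A recovery coefficient (RC) is the fraction of true activity recovered
#' inside a VOI of a given volume after imaging-system blur. The curve is a
#' set of (volume, rc) knots, interpolated linearly and clamped to the end
#' knot values outside the knot range, so the correction never overshoots.
#'
#' @param volume_ml numeric vector of knot volumes in mL, strictly increasing.
#' @param rc numeric vector of recovery coefficients at the knots, each in
#'   (0, 1], nondecreasing in volume.
#' @return An object of class `recovery_curve`.
#' @seealso [fit_recovery_curve()], [apply_recovery_correction()]
#' @export
#' @examples
#' rc <- recovery_curve(c(1, 2, 10, 100), c(0.3, 0.5, 0.85, 1.0))
#' rc_at(rc, c(0.5, 2, 30, 1e4))
recovery_curve <- function(volume_ml, rc) {
  if (length(volume_ml) != length(rc) || length(rc) < 1L)
    stop_lutadose("volume_ml and rc must be equal-length, non-empty vectors",
                  "lutadose_value_error")
  if (any(!is.finite(volume_ml)) || any(!is.finite(rc)))
    stop_lutadose("recovery curve knots must be finite", "lutadose_value_error")
  if (any(diff(volume_ml) <= 0))
    stop_lutadose("knot volumes must be strictly increasing",
                  "lutadose_value_error")
  if (any(rc <= 0) || any(rc > 1))
    stop_lutadose("recovery coefficients must lie in (0, 1]",
                  "lutadose_value_error")
  if (any(diff(rc) < 0))
    stop_lutadose("recovery coefficients must be nondecreasing in volume",
                  "lutadose_value_error")
  structure(list(volume_ml = as.numeric(volume_ml), rc = as.numeric(rc)),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat("Recovery-coefficient curve with", length(x$rc), "knots\n")
  print(data.frame(volume_ml = x$volume_ml, rc = x$rc), row.names = FALSE)
  invisible(x)
}

#' Evaluate a recovery curve at given volumes
#'
#' Linear interpolation between knots; volumes outside the knot range are
#' clamped to the first/last knot value.
#'
#' @param curve a [recovery_curve()].
#' @param volume_ml numeric vector of volumes in mL (> 0).
#' @return numeric vector of recovery coefficients.
#' @export
rc_at <- function(curve, volume_ml) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (any(!is.finite(volume_ml)) || any(volume_ml <= 0))
    stop_lutadose("volumes must be positive and finite", "lutadose_value_error")
  if (length(curve$rc) == 1L) return(rep(curve$rc, length(volume_ml)))
  stats::approx(curve$volume_ml, curve$rc, xout = volume_ml, rule = 2)$y
}

#' Default recovery curve
#'
#' A generic sphere-phantom recovery curve for 177Lu SPECT with medium-energy
#' collimation: it passes through RC = 0.5 at 2 mL (the volume floor used for
#' lesion selection) and saturates at 1 for large volumes.
#'
#' @return A [recovery_curve()].
#' @export
default_recovery_curve <- function() {
  recovery_curve(
    volume_ml = c(0.5, 1, 2, 5, 10, 20, 50, 100),
    rc        = c(0.20, 0.35, 0.50, 0.70, 0.80, 0.88, 0.95, 1.00)
  )
}

#' Correct an absorbed dose for partial-volume losses
#'
#' Divides the absorbed dose by the recovery coefficient at the VOI volume.
#' Because RC <= 1 the correction never decreases the dose.
#'
#' @param ad absorbed dose in Gy (scalar or vector).
#' @param volume_ml VOI volume(s) in mL, recycled against `ad`.
#' @param rc_curve a [recovery_curve()]; defaults to
#'   [default_recovery_curve()].
#' @return corrected absorbed dose(s) in Gy.
#' @export
#' @examples
#' apply_recovery_correction(10, 2)  # RC = 0.5 at 2 mL -> 20 Gy
apply_recovery_correction <- function(ad, volume_ml,
                                      rc_curve = default_recovery_curve()) {
  if (any(!is.finite(ad)) || any(ad < 0))
    stop_lutadose("absorbed doses must be finite and >= 0",
                  "lutadose_value_error")
  rc <- rc_at(rc_curve, volume_ml)
  if (any(rc <= 0))
    stop_lutadose("recovery coefficient evaluated <= 0", "lutadose_value_error")
  ad / rc
}

#' Fit a monotone recovery curve from phantom measurements
#'
#' Takes sphere-phantom measurements (volume, measured activity fraction) and
#' returns a nondecreasing recovery curve: measurements are ordered by volume,
#' made monotone by isotonic regression (pool adjacent violators) and clipped
#' to (0, 1].
#'
#' @param volume_ml sphere volumes in mL (>= 2 distinct values).
#' @param measured_fraction measured in-mask activity fractions.
#' @return A [recovery_curve()].
#' @export
fit_recovery_curve <- function(volume_ml, measured_fraction) {
  if (length(volume_ml) != length(measured_fraction))
    stop_lutadose("volume and fraction vectors must have equal length",
                  "lutadose_value_error")
  keep <- is.finite(volume_ml) & is.finite(measured_fraction)
  volume_ml <- volume_ml[keep]; measured_fraction <- measured_fraction[keep]
  if (length(unique(volume_ml)) < 2L)
    stop_lutadose("need at least 2 phantom spheres with distinct volumes",
                  "lutadose_value_error")
  o <- order(volume_ml)
  v <- volume_ml[o]; f <- measured_fraction[o]
  # average duplicated volumes before isotonic adjustment
  if (anyDuplicated(v)) {
    f <- as.numeric(tapply(f, v, mean))
    v <- sort(unique(v))
  }
  iso <- stats::isoreg(v, f)$yf
  iso <- pmin(pmax(iso, .Machine$double.eps), 1)
  recovery_curve(v, iso)
}
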