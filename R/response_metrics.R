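#' Apply lesion-selection rules to a candidate lesion table
#'
#' Target-lesion rules for dose--response analysis: bone lesions are excluded
#' (response is hard to assess on CT), lesions smaller than 2 mL are excluded
#' (below that volume the recovery coefficient drops under 0.5 and
#' partial-volume errors dominate), and at most 5 lesions per organ/site are
#' kept per patient. When more than 5 survive the volume floor, the kept set
#' always contains the site's largest and smallest lesion; the remaining 3
#' slots are filled by descending volume, ties broken by lesion id.
#'
#' Selection is idempotent: re-running it on its own output changes nothing.
#'
#' @param lesions data.frame with columns `patient_id`, `lesion_id`, `site`
#'   (one of `"liver"`, `"lymph_node"`, `"mesentery"`, `"pancreas"`,
#'   `"peritoneum"`, `"bone"`), `v_bl_ml` (baseline volume, mL). Other
#'   columns are carried through.
#' @param min_volume_ml volume floor in mL (default 2).
#' @param max_per_site maximum lesions kept per patient-site (default 5).
#' @return the input with logical `selected` and character
#'   `exclusion_reason` (`NA`, `"bone_site"`, `"small_volume"`,
#'   `"site_cap"`) columns replaced/added.
#' @export
select_lesions <- function(lesions, min_volume_ml = 2, max_per_site = 5L) {
  req <- c("patient_id", "lesion_id", "site", "v_bl_ml")
  miss <- setdiff(req, names(lesions))
  if (length(miss))
    stop_lutadose(paste("lesion table missing column(s):",
                        paste(miss, collapse = ", ")),
                  "lutadose_schema_error")
  n <- nrow(lesions)
  selected <- rep(TRUE, n)
  reason <- rep(NA_character_, n)

  bone <- lesions$site == "bone"
  selected[bone] <- FALSE; reason[bone] <- "bone_site"
  small <- !bone & lesions$v_bl_ml < min_volume_ml
  selected[small] <- FALSE; reason[small] <- "small_volume"

  key <- interaction(lesions$patient_id, lesions$site, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k & selected)
    if (length(idx) <= max_per_site) next
    v <- lesions$v_bl_ml[idx]
    id <- as.character(lesions$lesion_id[idx])
    ord <- order(-v, id)           # descending volume, lexicographic ties
    keep <- idx[ord[seq_len(max_per_site - 1L)]]
    i_min <- idx[order(v, id)[1L]] # mandatory smallest-volume lesion
    if (!(i_min %in% keep)) keep <- c(keep, i_min) else
      keep <- c(keep, idx[ord[max_per_site]])
    drop <- setdiff(idx, keep)
    selected[drop] <- FALSE; reason[drop] <- "site_cap"
  }
  lesions$selected <- selected
  lesions$exclusion_reason <- reason
  lesions
}

#' Percent change in lesion volume between baseline and month-3 CT
#'
#' \deqn{\Delta V\% = 100 \times (V_{M3} - V_{BL}) / V_{BL}.}
#' Negative values indicate shrinkage; a vanished lesion gives -100.
#'
#' @param v_bl baseline volume in mL (> 0).
#' @param v_m3 month-3 volume in mL (>= 0).
#' @return percent volume change (vectorized).
#' @export
#' @examples
#' compute_delta_v(10, 8)  # -20
compute_delta_v <- function(v_bl, v_m3) {
  if (any(!is.finite(v_bl)) || any(v_bl <= 0))
    stop_lutadose("baseline volumes must be > 0", "lutadose_value_error")
  ok <- is.na(v_m3) | (is.finite(v_m3) & v_m3 >= 0)
  if (!all(ok))
    stop_lutadose("month-3 volumes must be >= 0 (or NA if missing)",
                  "lutadose_value_error")
  100 * (v_m3 - v_bl) / v_bl
}

#' Classify lesion response from percent volume change
#'
#' A lesion is \emph{controlled} when its volume did not increase
#' (\eqn{\Delta V\% \le 0}) and \emph{stable} when it did not grow by more
#' than 20\% (\eqn{\Delta V\% \le +20}); both boundaries inclusive, so every
#' controlled lesion is also stable.
#'
#' @param delta_v_pct percent volume change(s), each >= -100.
#' @param stability_threshold growth threshold in percent (default +20).
#' @return data.frame with columns `delta_v_pct`, `controlled`, `stable`.
#' @export
classify_response <- function(delta_v_pct, stability_threshold = 20) {
  ok <- is.na(delta_v_pct) | (is.finite(delta_v_pct) & delta_v_pct >= -100)
  if (!all(ok))
    stop_lutadose("delta_v_pct must be >= -100", "lutadose_value_error")
  data.frame(delta_v_pct = delta_v_pct,
             controlled = delta_v_pct <= 0,
             stable = delta_v_pct <= stability_threshold)
}

#' Per-patient lesion dose indices
#'
#' For each patient, the mean, minimum and maximum of the total (cumulative)
#' absorbed doses over that patient's selected lesions. Patients with no
#' selected lesion are dropped with a warning.
#'
#' @param lesions data.frame with columns `patient_id`, `total_ad_gy` and
#'   optionally `selected` (if present, only selected rows are used).
#' @return data.frame with columns `patient_id`, `n_lesions`,
#'   `mean_total_ad`, `min_total_ad`, `max_total_ad`.
#' @export
patient_dose_indices <- function(lesions) {
  req <- c("patient_id", "total_ad_gy")
  miss <- setdiff(req, names(lesions))
  if (length(miss))
    stop_lutadose(paste("lesion table missing column(s):",
                        paste(miss, collapse = ", ")),
                  "lutadose_schema_error")
  all_ids <- unique(lesions$patient_id)
  if ("selected" %in% names(lesions)) lesions <- lesions[lesions$selected, ]
  lesions <- lesions[is.finite(lesions$total_ad_gy), ]
  out <- do.call(rbind, lapply(split(lesions, lesions$patient_id), function(p) {
    data.frame(patient_id = p$patient_id[1L],
               n_lesions = nrow(p),
               mean_total_ad = mean(p$total_ad_gy),
               min_total_ad = min(p$total_ad_gy),
               max_total_ad = max(p$total_ad_gy),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  dropped <- setdiff(all_ids, out$patient_id)
  if (length(dropped))
    warning("patients with no usable lesion dropped: ",
            paste(dropped, collapse = ", "))
  out
}
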