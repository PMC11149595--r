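#' Run the dosimetry and outcome pipeline end to end
#'
#' Orchestrates the four stages on one output directory:
#' \enumerate{
#'   \item \strong{simulate} -- generate a synthetic cohort
#'     ([generate_cohort()]) and write its observation and truth tables;
#'     skipped when `cohort_tables` is supplied.
#'   \item \strong{dose} -- per-cycle absorbed doses
#'     ([compute_cycle_doses()]) and per-course dosimetry
#'     ([compute_course_dosimetry()]).
#'   \item \strong{respond} -- lesion selection, percent volume change,
#'     response classification, patient dose indices.
#'   \item \strong{analyze} -- dose--response and TCP models, toxicity
#'     correlations, paired lab tests, median-dichotomized survival
#'     comparisons; written as one statistics JSON.
#' }
#' All tables are CSV; a JSON manifest records the configuration seeds, row
#' counts, warnings and an MD5 checksum per output file, so identical
#' configuration and seeds reproduce identical checksums.
#'
#' @param out_dir output directory (created if missing).
#' @param config a [cohort_config()]; its `counting$cf` and `pve` entries
#'   also parameterize the dose engine.
#' @param cohort_tables optional pre-built cohort (a `synthetic_cohort` or a
#'   list with `timepoints`, `lesions`, `labs`, `survival`) to analyze
#'   instead of simulating.
#' @param stats_seed seed for the bootstrap in the analysis stage.
#' @param n_boot cluster-bootstrap resamples for the dose--response model.
#' @param stages character subset of
#'   `c("simulate", "dose", "respond", "analyze")`; earlier stages must have
#'   run (their outputs are reused from memory within one call).
#' @param volume_mode passed to [compute_cycle_doses()].
#' @return the manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         cohort_tables = NULL, stats_seed = 1L,
                         n_boot = 200L,
                         stages = c("simulate", "dose", "respond", "analyze"),
                         volume_mode = "baseline") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  files <- character()
  counts <- list()

  put <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    counts[[name]] <<- nrow(df)
    path
  }

  # -- simulate ---------------------------------------------------------
  cohort <- if (!is.null(cohort_tables)) cohort_tables else
    generate_cohort(config)
  if ("simulate" %in% stages) {
    put(cohort$timepoints, "timepoints")
    put(cohort$lesions, "lesions")
    put(cohort$labs, "labs")
    put(cohort$survival, "survival")
    if (!is.null(cohort$truth)) {
      put(cohort$truth$kinetics, "truth_kinetics")
      put(cohort$truth$lesions, "truth_lesions")
      put(cohort$truth$patients, "truth_patients")
    }
  }
  viol <- validate_tables(list(timepoints = cohort$timepoints,
                               lesions = cohort$lesions,
                               survival = cohort$survival))
  if (!is.null(viol) && nrow(viol))
    stop_lutadose(paste("input validation failed:",
                        paste(utils::head(viol$problem, 3), collapse = "; ")),
                  "lutadose_schema_error")

  dosim <- NULL; cycle_doses <- NULL
  if (any(c("dose", "respond", "analyze") %in% stages)) {
    cycle_doses <- compute_cycle_doses(
      cohort$timepoints, cf = config$counting$cf, rc_curve = config$pve,
      led_constant = config$led_constant, volume_mode = volume_mode,
      stp_time_h = config$stp_time_h)
    dosim <- compute_course_dosimetry(cycle_doses)
    if (any(cycle_doses$below_physical, na.rm = TRUE))
      warnings_log <- c(warnings_log, sprintf(
        "%d structure-cycles fitted below the physical decay constant",
        sum(cycle_doses$below_physical, na.rm = TRUE)))
    if ("dose" %in% stages) {
      put(cycle_doses, "cycle_doses")
      put(dosim$structures, "structure_cum_ad")
      put(dosim$patients, "patient_dosimetry")
    }
  }

  lesion_resp <- NULL; indices <- NULL
  if (any(c("respond", "analyze") %in% stages)) {
    les <- select_lesions(cohort$lesions)
    les$total_ad_gy <- dosim$structures$cum_ad_gy[
      match(les$lesion_id, dosim$structures$structure_id)]
    les$delta_v_pct <- compute_delta_v(les$v_bl_ml, les$v_m3_ml)
    cls <- classify_response(les$delta_v_pct)
    les$controlled <- cls$controlled
    les$stable <- cls$stable
    lesion_resp <- les
    indices <- patient_dose_indices(les)
    if ("respond" %in% stages) {
      put(les, "lesion_response")
      put(indices, "patient_dose_indices")
    }
  }

  stats_out <- NULL
  if ("analyze" %in% stages) {
    sel <- lesion_resp[lesion_resp$selected & is.finite(lesion_resp$delta_v_pct), ]
    dr <- fit_dose_response(sel$total_ad_gy, sel$delta_v_pct, sel$patient_id,
                            n_boot = n_boot, seed = stats_seed)
    tcp <- fit_tcp(sel$total_ad_gy, sel$controlled)

    labs <- cohort$labs
    org <- stats::aggregate(cum_ad_gy ~ patient_id + structure_class,
                            data = dosim$structures[
                              dosim$structures$structure_class != "lesion", ],
                            FUN = sum)
    labs$organ_cum_ad_gy <- org$cum_ad_gy[
      match(interaction(labs$patient_id, labs$organ),
            interaction(org$patient_id, org$structure_class))]
    tox <- correlate_toxicity(labs)

    lab_tests <- lapply(split(labs, labs$lab), function(d)
      paired_lab_test(d$baseline, d$month3))

    surv_cmp <- list()
    for (ep in unique(cohort$survival$endpoint)) {
      sv <- cohort$survival[cohort$survival$endpoint == ep, ]
      for (idx in c("mean_total_ad", "min_total_ad")) {
        cov <- indices[[idx]][match(sv$patient_id, indices$patient_id)]
        keep <- is.finite(cov)
        cmp <- survival_by_median(cov[keep], sv$time_months[keep],
                                  sv$event[keep],
                                  endpoint = paste(ep, idx, sep = "_"))
        surv_cmp[[paste(ep, idx, sep = "_")]] <- cmp
      }
    }

    stats_out <- list(
      seed = stats_seed,
      dose_response = list(
        model = dr$model, coefficients = as.list(dr$coefficients),
        ci = apply(dr$ci, 2, as.list), se = as.list(dr$se),
        spearman_rho = dr$spearman_rho, spearman_p = dr$spearman_p,
        n = dr$n, n_boot = n_boot),
      tcp = list(intercept = tcp$intercept, slope = tcp$slope,
                 p_slope = tcp$p_slope, separation = tcp$separation,
                 d50_gy = tcp$d50_gy, d90_gy = tcp$d90_gy, n = tcp$n),
      toxicity = tox$correlations,
      lab_tests = lab_tests,
      survival = lapply(surv_cmp, function(s) list(
        endpoint = s$endpoint, cutoff = s$cutoff,
        median_low = unname(s$medians["low"]),
        median_high = unname(s$medians["high"]),
        hr = s$hr, hr_ci = s$hr_ci, p_wald = s$p_wald,
        logrank_p = s$logrank_p, hr_estimable = s$hr_estimable)))
    stats_path <- file.path(out_dir, "statistics.json")
    jsonlite::write_json(stats_out, stats_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    files <- c(files, stats_path)
    put(tox$trends, "toxicity_trends")
    km <- do.call(rbind, lapply(surv_cmp, function(s)
      cbind(endpoint = s$endpoint, s$km)))
    rownames(km) <- NULL
    put(km, "km_curves")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("lutadose")),
    cohort_seed = config$seed, stats_seed = stats_seed,
    stages = stages,
    row_counts = counts,
    warnings = warnings_log,
    checksums = as.list(tools::md5sum(sort(files))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Validate pipeline input tables against their schemas
#'
#' Checks column presence, basic types and the domain invariants of each
#' known table (`timepoints`, `lesions`, `labs`, `survival`), including
#' uniqueness of the (patient, cycle, structure, time) key.
#'
#' @param tables named list of data.frames, or of CSV file paths; names
#'   identify the schema.
#' @return data.frame of violations (`table`, `row`, `column`, `problem`);
#'   zero rows when everything is well formed.
#' @export
validate_tables <- function(tables) {
  viol <- list()
  note <- function(tab, row, col, problem)
    viol[[length(viol) + 1L]] <<- data.frame(
      table = tab, row = row, column = col, problem = problem,
      stringsAsFactors = FALSE)

  schemas <- list(
    timepoints = list(
      cols = c("patient_id", "cycle", "structure_id", "structure_class",
               "t_h", "counts", "duration_s", "volume_ml", "density_g_ml"),
      checks = function(d, tab) {
        bad <- which(!is.finite(d$t_h) | d$t_h <= 0)
        for (r in bad) note(tab, r, "t_h", "t_h must be > 0")
        bad <- which(!is.finite(d$counts) | d$counts < 0)
        for (r in bad) note(tab, r, "counts", "counts must be >= 0")
        bad <- which(!is.finite(d$volume_ml) | d$volume_ml <= 0)
        for (r in bad) note(tab, r, "volume_ml", "volume_ml must be > 0")
        bad <- which(!is.finite(d$density_g_ml) | d$density_g_ml <= 0)
        for (r in bad) note(tab, r, "density_g_ml", "density_g_ml must be > 0")
        key <- interaction(d$patient_id, d$cycle, d$structure_id, d$t_h)
        dup <- which(duplicated(key))
        for (r in dup) note(tab, r, "(patient_id,cycle,structure_id,t_h)",
                            "duplicated acquisition key")
      }),
    lesions = list(
      cols = c("patient_id", "lesion_id", "site", "v_bl_ml"),
      checks = function(d, tab) {
        bad <- which(!is.finite(d$v_bl_ml) | d$v_bl_ml <= 0)
        for (r in bad) note(tab, r, "v_bl_ml", "v_bl_ml must be > 0")
        if ("v_m3_ml" %in% names(d)) {
          bad <- which(!is.na(d$v_m3_ml) & d$v_m3_ml < 0)
          for (r in bad) note(tab, r, "v_m3_ml", "v_m3_ml must be >= 0")
        }
        dup <- which(duplicated(d$lesion_id))
        for (r in dup) note(tab, r, "lesion_id", "duplicated lesion_id")
      }),
    labs = list(
      cols = c("patient_id", "lab", "baseline", "month3"),
      checks = function(d, tab) {
        bad <- which(is.finite(d$baseline) & d$baseline <= 0)
        for (r in bad) note(tab, r, "baseline", "baseline must be > 0")
      }),
    survival = list(
      cols = c("patient_id", "endpoint", "time_months", "event"),
      checks = function(d, tab) {
        bad <- which(!is.finite(d$time_months) | d$time_months <= 0)
        for (r in bad) note(tab, r, "time_months", "time_months must be > 0")
        bad <- which(!d$event %in% c(0L, 1L))
        for (r in bad) note(tab, r, "event", "event must be 0 or 1")
      }))

  for (nm in names(tables)) {
    if (!nm %in% names(schemas)) next
    d <- tables[[nm]]
    if (is.character(d)) {
      if (!file.exists(d)) {
        note(nm, NA_integer_, NA_character_, paste("file not found:", d))
        next
      }
      d <- utils::read.csv(d, stringsAsFactors = FALSE)
    }
    sc <- schemas[[nm]]
    miss <- setdiff(sc$cols, names(d))
    if (length(miss)) {
      for (m in miss) note(nm, NA_integer_, m, "missing required column")
      next
    }
    sc$checks(d, nm)
  }
  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(table = character(), row = integer(), column = character(),
               problem = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
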