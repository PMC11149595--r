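#' Fit a plateaued exponential dose--response model
#'
#' Models percent lesion volume change as
#' \eqn{\Delta V\% = floor + (cap - floor) e^{-rate \cdot AD} + \epsilon}:
#' at zero dose the expected change is `cap`, large doses approach the
#' `floor` plateau, and for `rate >= 0` the curve is monotone nonincreasing.
#' The model is fitted by least squares with the linear parameters profiled
#' out (for fixed rate, floor and cap are a linear regression), so only the
#' rate requires a 1-D search. Uncertainty comes from a patient-level
#' cluster bootstrap, which respects within-patient correlation of lesions.
#' The sign and p-value of the monotone dose--response association are
#' reported via Spearman rank correlation.
#'
#' @param total_ad_gy lesion total absorbed doses (Gy).
#' @param delta_v_pct lesion percent volume changes.
#' @param patient_id patient identifier per lesion (cluster variable).
#' @param model `"plateau"` (default) or `"linear"` (straight-line
#'   sensitivity alternative).
#' @param n_boot number of cluster-bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @param rate_interval search interval for the rate (1/Gy).
#' @return object of class `dose_response_fit`: `coefficients`
#'   (floor, cap, rate or intercept, slope), `boot` (matrix of bootstrap
#'   estimates), `ci` (95\% CIs: estimate +/- t(clusters - 1) quantile times
#'   the bootstrap SE), `ci_percentile` (raw percentile intervals), `se`,
#'   `spearman_rho`, `spearman_p`, `n`, `n_patients`, `model`, and
#'   `predict(ad)` via [predict.dose_response_fit()].
#' @export
fit_dose_response <- function(total_ad_gy, delta_v_pct, patient_id,
                              model = c("plateau", "linear"),
                              n_boot = 1000L, seed = 1L,
                              rate_interval = c(1e-5, 1)) {
  model <- match.arg(model)
  keep <- is.finite(total_ad_gy) & is.finite(delta_v_pct)
  ad <- total_ad_gy[keep]; dv <- delta_v_pct[keep]; pid <- patient_id[keep]
  if (length(ad) < 10L)
    stop_lutadose("need >= 10 lesions with dose and response",
                  "lutadose_insufficient_data")
  if (diff(range(ad)) == 0)
    stop_lutadose("degenerate dose spread: all total ADs equal",
                  "lutadose_value_error")

  fit_once <- if (model == "plateau") {
    function(a, y) fit_plateau_ls(a, y, rate_interval)
  } else {
    function(a, y) {
      co <- stats::lm.fit(cbind(1, a), y)$coefficients
      c(intercept = co[[1L]], slope = co[[2L]])
    }
  }
  est <- fit_once(ad, dv)

  clusters <- split(seq_along(ad), pid)
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  if (n_boot > 0L) {
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      idx <- unlist(clusters[sample(length(clusters), replace = TRUE)],
                    use.names = FALSE)
      if (diff(range(ad[idx])) == 0) next
      boot[b, ] <- tryCatch(fit_once(ad[idx], dv[idx]),
                            error = function(e) rep(NA_real_, length(est)))
    }
  }
  ok <- stats::complete.cases(boot)
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  # with few clusters, normal-theory intervals on t quantiles (G - 1 df)
  # calibrate better than raw percentiles, especially for the extrapolated
  # zero-dose parameter
  tq <- stats::qt(0.975, df = max(1L, length(clusters) - 1L))
  ci <- rbind(`2.5%` = est - tq * se, `97.5%` = est + tq * se)
  ci_percentile <- if (any(ok))
    apply(boot[ok, , drop = FALSE], 2, stats::quantile,
          probs = c(0.025, 0.975)) else matrix(NA_real_, 2, length(est))
  sp <- stats::cor.test(ad, dv, method = "spearman", exact = FALSE)

  structure(list(coefficients = est, boot = boot, ci = ci,
                 ci_percentile = ci_percentile, se = se,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 n = length(ad), n_patients = length(clusters),
                 n_boot_ok = sum(ok), model = model,
                 rate_interval = rate_interval),
            class = "dose_response_fit")
}

# variable-projection least squares for y = floor + (cap-floor) exp(-rate*ad):
# for fixed rate the model is linear in (floor, cap), so only the rate needs
# a 1-D search
fit_plateau_ls <- function(ad, y, rate_interval) {
  one <- rep(1, length(ad))
  sse_at <- function(r) {
    f <- stats::.lm.fit(cbind(one, exp(-r * ad)), y)
    sum(f$residuals^2)
  }
  opt <- stats::optimize(sse_at, interval = rate_interval, tol = 1e-10)
  r <- opt$minimum
  # a constant model (rate irrelevant) can beat an interior optimum
  if (stats::var(y) * (length(y) - 1) < opt$objective) r <- rate_interval[1L]
  co <- stats::.lm.fit(cbind(one, exp(-r * ad)), y)$coefficients
  c(floor = co[[1L]], cap = co[[1L]] + co[[2L]], rate = r)
}

#' Predict from a fitted dose--response model
#'
#' @param object a `dose_response_fit`.
#' @param ad absorbed doses (Gy) at which to evaluate the fitted curve.
#' @param ... unused.
#' @return expected percent volume change at `ad`.
#' @export
predict.dose_response_fit <- function(object, ad, ...) {
  co <- object$coefficients
  if (object$model == "plateau")
    co[["floor"]] + (co[["cap"]] - co[["floor"]]) * exp(-co[["rate"]] * ad)
  else co[["intercept"]] + co[["slope"]] * ad
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s model), %d lesions / %d patients\n",
              x$model, x$n, x$n_patients))
  print(round(rbind(estimate = x$coefficients, x$ci), 4))
  cat(sprintf("Spearman rho = %.3f (p = %.3g)\n", x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Tumor control probability by binary logistic regression
#'
#' Fits P(controlled) as a logistic function of the lesion total absorbed
#' dose by maximum likelihood. When the data are (quasi-)separated -- e.g.
#' every lesion controlled -- the ML estimate diverges; the fit is then
#' redone with Firth's bias-reducing penalty and flagged. When the slope is
#' positive, the doses achieving 50\% and 90\% control probability are
#' reported.
#'
#' @param total_ad_gy lesion total absorbed doses (Gy).
#' @param controlled logical (or 0/1) control indicator per lesion.
#' @param min_n minimum number of lesions (default 10).
#' @return object of class `tcp_model`: `intercept`, `slope` (per Gy),
#'   `se`, `p_slope`, `fitted`, `separation` flag, `penalized` flag,
#'   `d50_gy`, `d90_gy`, `n`.
#' @export
fit_tcp <- function(total_ad_gy, controlled, min_n = 10L) {
  keep <- is.finite(total_ad_gy) & !is.na(controlled)
  ad <- total_ad_gy[keep]; y <- as.integer(controlled[keep])
  if (length(ad) < min_n)
    stop_lutadose("need >= 10 lesions for the TCP model",
                  "lutadose_insufficient_data")
  one_class <- length(unique(y)) < 2L
  X <- cbind(1, ad)

  fit <- NULL; separation <- one_class
  if (!one_class) {
    w <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(cond) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(cond)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!w$converged || any(abs(w$coefficients) > 1e3 * c(1, 1 / max(abs(ad)))))
      separation <- TRUE
    fit <- w
  }
  penalized <- separation
  if (penalized) {
    fl <- firth_logistic(X, y)
    beta <- fl$beta; se <- fl$se; fitted <- fl$fitted
  } else {
    beta <- fit$coefficients
    # Wald SEs from the observed information
    p <- fit$fitted.values
    info <- crossprod(X * sqrt(p * (1 - p)))
    se <- sqrt(diag(solve(info)))
    fitted <- p
  }
  z <- beta[2L] / se[2L]
  slope <- unname(beta[2L])
  d50 <- d90 <- NA_real_
  if (is.finite(slope) && slope > 0) {
    d50 <- unname(-beta[1L] / slope)
    d90 <- unname((stats::qlogis(0.9) - beta[1L]) / slope)
  }
  structure(list(intercept = unname(beta[1L]), slope = slope,
                 se = unname(se), p_slope = 2 * stats::pnorm(-abs(z)),
                 fitted = fitted, separation = separation,
                 penalized = penalized, d50_gy = d50, d90_gy = d90,
                 n = length(ad)),
            class = "tcp_model")
}

#' @export
print.tcp_model <- function(x, ...) {
  cat(sprintf(
    "TCP logistic model (n = %d): intercept = %.3f, slope = %.4f /Gy (p = %.3g)\n",
    x$n, x$intercept, x$slope, x$p_slope))
  if (x$separation) cat("  separation detected; Firth-penalized fit\n")
  if (is.finite(x$d50_gy))
    cat(sprintf("  D50 = %.1f Gy, D90 = %.1f Gy\n", x$d50_gy, x$d90_gy))
  invisible(x)
}

# Firth-penalized logistic regression (bias-reduced ML); returns finite
# estimates under complete separation
firth_logistic <- function(X, y, maxit = 200L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X * sqrt(W))
    inv <- solve(XtWX)
    # leverages of the weighted hat matrix
    h <- rowSums((X %*% inv) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  XtWX <- crossprod(X * sqrt(p * (1 - p)))
  list(beta = beta, se = sqrt(diag(solve(XtWX))), fitted = p, iter = it)
}

#' Spearman correlation of organ dose with lab change, per organ-lab pair
#'
#' For each organ--lab pair, computes the Spearman rank correlation between
#' the organ cumulative absorbed dose and the percent lab change from
#' baseline, with an exact permutation p-value for n <= 9 (tie-free) and the
#' large-sample normal approximation \eqn{z = \rho\sqrt{n-1}} otherwise. A
#' locally weighted (lowess) trend is exported for plotting.
#'
#' @param labs data.frame with columns `organ`, `lab`, `organ_cum_ad_gy`
#'   and `pct_change` (one row per patient per lab).
#' @param lowess_f lowess smoother span.
#' @return list with `correlations` (data.frame `organ`, `lab`, `rho`, `p`,
#'   `n`) and `trends` (data.frame of lowess coordinates per pair).
#' @export
correlate_toxicity <- function(labs, lowess_f = 2 / 3) {
  req <- c("organ", "lab", "organ_cum_ad_gy", "pct_change")
  miss <- setdiff(req, names(labs))
  if (length(miss))
    stop_lutadose(paste("lab table missing column(s):",
                        paste(miss, collapse = ", ")),
                  "lutadose_schema_error")
  key <- interaction(labs$organ, labs$lab, drop = TRUE)
  cors <- list(); trends <- list()
  for (k in levels(key)) {
    d <- labs[key == k, ]
    d <- d[is.finite(d$organ_cum_ad_gy) & is.finite(d$pct_change), ]
    if (nrow(d) < 3L) next
    st <- spearman_test(d$organ_cum_ad_gy, d$pct_change)
    cors[[k]] <- data.frame(organ = d$organ[1L], lab = d$lab[1L],
                            rho = st$rho, p = st$p, n = nrow(d),
                            method = st$method, stringsAsFactors = FALSE)
    lo <- stats::lowess(d$organ_cum_ad_gy, d$pct_change, f = lowess_f)
    trends[[k]] <- data.frame(organ = d$organ[1L], lab = d$lab[1L],
                              cum_ad_gy = lo$x, pct_change_trend = lo$y,
                              stringsAsFactors = FALSE)
  }
  bind <- function(l) {
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l); rownames(out) <- NULL; out
  }
  list(correlations = bind(cors), trends = bind(trends))
}

# Spearman rho with exact p for small tie-free samples, normal approximation
# otherwise; errors on constant input
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3L)
    stop_lutadose("need >= 3 paired observations", "lutadose_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_lutadose("Spearman correlation undefined for a constant column",
                  "lutadose_value_error")
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) || anyDuplicated(y)
  if (n <= 9L && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    z <- rho * sqrt(n - 1)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Paired Student t test of a lab parameter between two visits
#'
#' Two-sided paired t test on the per-patient differences, reported with the
#' group means and SDs. If baseline and follow-up are identical the test is
#' degenerate and returned with p = 1 and a zero mean difference; a nonzero
#' constant difference has no variance to test against and errors.
#'
#' @param baseline,followup paired numeric vectors (same length, n >= 2);
#'   pairs with a missing value are dropped.
#' @return list: `n`, `mean_baseline`, `sd_baseline`, `mean_followup`,
#'   `sd_followup`, `mean_diff`, `t`, `df`, `p`.
#' @export
paired_lab_test <- function(baseline, followup) {
  if (length(baseline) != length(followup))
    stop_lutadose("baseline and follow-up must be paired (equal length)",
                  "lutadose_value_error")
  keep <- is.finite(baseline) & is.finite(followup)
  baseline <- baseline[keep]; followup <- followup[keep]
  n <- length(baseline)
  if (n < 2L)
    stop_lutadose("paired t test needs >= 2 complete pairs",
                  "lutadose_insufficient_data")
  d <- followup - baseline
  out <- list(n = n,
              mean_baseline = mean(baseline), sd_baseline = stats::sd(baseline),
              mean_followup = mean(followup), sd_followup = stats::sd(followup),
              mean_diff = mean(d))
  if (all(d == 0)) return(c(out, list(t = 0, df = n - 1, p = 1)))
  tt <- tryCatch(stats::t.test(followup, baseline, paired = TRUE),
                 error = function(e)
                   stop_lutadose(
                     "differences have (numerically) zero variance; p undefined",
                     "lutadose_value_error"))
  c(out, list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value))
}

#' Median-dichotomized survival comparison
#'
#' Splits patients at the cohort median of a dose covariate (values equal to
#' the median go to the high group), then compares the groups with
#' Kaplan--Meier curves (Greenwood pointwise CIs, medians with not-reached
#' handling), a Cox proportional-hazards model (high vs low, Efron ties,
#' Wald CI and p) and the log-rank test.
#'
#' @param covariate per-patient dose index (Gy).
#' @param time_months follow-up time.
#' @param event event indicator (1 = progression/death, 0 = censored).
#' @param endpoint label carried through to the output (e.g. `"pfs"`).
#' @return object of class `survival_comparison`: `endpoint`, `cutoff`,
#'   `groups` (n and events per group), `km` (step coordinates with CIs),
#'   `medians` (per group, `NA` = not reached), `hr`, `hr_ci`, `p_wald`,
#'   `logrank_p`, `hr_estimable`.
#' @export
survival_by_median <- function(covariate, time_months, event,
                               endpoint = "endpoint") {
  keep <- is.finite(covariate) & is.finite(time_months) & !is.na(event)
  covariate <- covariate[keep]; time_months <- time_months[keep]
  event <- as.integer(event[keep])
  if (any(time_months <= 0))
    stop_lutadose("survival times must be > 0", "lutadose_value_error")
  cutoff <- stats::median(covariate)
  group <- factor(ifelse(covariate >= cutoff, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < 2L))
    stop_lutadose("need >= 2 patients per group after dichotomization",
                  "lutadose_insufficient_data")
  df <- data.frame(time = time_months, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sfs <- summary(sf)
  km <- data.frame(group = sub("^group=", "", as.character(sfs$strata)),
                   time = sfs$time, surv = sfs$surv,
                   lower = sfs$lower, upper = sfs$upper,
                   n_risk = sfs$n.risk, n_event = sfs$n.event,
                   stringsAsFactors = FALSE)
  tab <- summary(sf)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  medians <- stats::setNames(tab[, "median"],
                             sub("^group=", "", rownames(tab)))

  hr <- NA_real_; hr_ci <- c(NA_real_, NA_real_); p_wald <- NA_real_
  estimable <- sum(event[group == "high"]) > 0 && sum(event[group == "low"]) > 0
  if (estimable) {
    cx <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ group, data = df,
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(cx)) {
      cx <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ group, data = df,
                        ties = "efron"))
    }
    s <- summary(cx)
    hr <- unname(s$coefficients[1L, "exp(coef)"])
    p_wald <- unname(s$coefficients[1L, "Pr(>|z|)"])
    hr_ci <- unname(s$conf.int[1L, c("lower .95", "upper .95")])
    estimable <- is.finite(hr) && is.finite(s$coefficients[1L, "se(coef)"])
  }
  logrank_p <- if (sum(event) > 0) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    1 - stats::pchisq(sd_$chisq, df = 1)
  } else NA_real_

  structure(list(endpoint = endpoint, cutoff = cutoff,
                 groups = as.data.frame(table(group = group,
                                              event = factor(event, 0:1))),
                 km = km, medians = medians, hr = hr, hr_ci = hr_ci,
                 p_wald = p_wald, logrank_p = logrank_p,
                 hr_estimable = estimable, n = length(covariate)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("Survival comparison (%s), median cut at %.2f Gy, n = %d\n",
              x$endpoint, x$cutoff, x$n))
  med <- ifelse(is.na(x$medians), "not reached",
                sprintf("%.1f mo", x$medians))
  cat(sprintf("  median survival: low = %s, high = %s\n", med["low"], med["high"]))
  if (x$hr_estimable)
    cat(sprintf("  HR (high vs low) = %.2f (95%% CI %.2f-%.2f), p = %.3g; log-rank p = %.3g\n",
                x$hr, x$hr_ci[1L], x$hr_ci[2L], x$p_wald, x$logrank_p))
  else cat("  hazard ratio not estimable\n")
  invisible(x)
}
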