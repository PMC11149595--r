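---
title: "VOI dosimetry and outcome modelling for 177Lu-DOTATATE: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VOI dosimetry and outcome modelling for 177Lu-DOTATATE: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutadose)
```

`lutadose` implements a volume-of-interest (VOI) dosimetry chain for
peptide receptor radionuclide therapy (PRRT) with [177Lu]Lu-DOTATATE, and
the statistical analyses that relate the resulting absorbed doses to tumor
response, hematologic toxicity and survival. This vignette documents the
models, their assumptions, the tunable parameters, and the numerical and
design choices behind them.

## The dosimetry model

### From counts to dose rate

Each VOI measurement is a count total acquired over a known duration on a
quantitatively calibrated SPECT system. The activity in the VOI is

$$A\ [\mathrm{MBq}] = \frac{\mathrm{counts}}{\mathrm{duration}\ [\mathrm{s}]
  \cdot cf\ [\mathrm{cps/MBq}]},$$

and the dose rate follows from the *local energy deposition* (LED)
approximation with density correction: every electron emitted in the VOI
(beta particles, conversion and Auger electrons) deposits its energy
locally, and photons are neglected,

$$\dot D\ [\mathrm{Gy/h}] = \frac{A \cdot 10^{6} \cdot E_{\mathrm{LED}}
  \cdot 3600}{V \rho / 1000},$$

with $V$ the VOI volume in mL and $\rho$ the tissue density in g/mL. The
default $E_{\mathrm{LED}} = 2.3694\times10^{-14}$ J/decay corresponds to a
mean locally deposited electron energy of about 147.9 keV per 177Lu decay;
it is a configurable parameter of `counts_to_doserate()`, never a
hard-coded constant, so users can substitute their preferred decay-data
compilation. LED is accurate for structures large compared with the
electron range (~2 mm in soft tissue) and ignores cross-irradiation
between structures; for the multi-centimetre VOIs this pipeline targets
that is the standard field assumption.

### Time integration

For fully sampled cycles (four acquisitions at 4, 24, 72 and 192 h
post-injection) the dose-rate time course is fitted with a monoexponential
$\dot D(t) = \dot D_0 e^{-\lambda_{\mathrm{eff}} t}$ and integrated
analytically from injection to infinity:

$$AD = \int_0^\infty \dot D_0 e^{-\lambda_{\mathrm{eff}} t}\,dt
     = \frac{\dot D_0}{\lambda_{\mathrm{eff}}}.$$

The fit minimises least squares on the log dose rate, which is closed form
for 3–4 points and exact on noise-free monoexponential data. Two choices
deserve comment:

* **Integration domain.** Integrating from $t = 0$ back-extrapolates the
  fitted curve to injection time. With only four points starting at 4 h
  there is no information about an uptake phase, so the monoexponential is
  taken to hold from injection onward; this is the convention the
  single-time-point scaling below also assumes.
* **Physical floor on $\lambda_{\mathrm{eff}}$.** The effective decay
  constant combines physical decay
  ($\lambda_{\mathrm{phys}} = \ln 2 / 159.5\ \mathrm{h}$) and biological
  clearance, so values below $\lambda_{\mathrm{phys}}$ imply negative
  clearance. Counting noise can legitimately produce such fits, so they
  are *flagged* (`below_physical`) rather than rejected by default;
  `strict = TRUE` rejects them. Fits with $\lambda_{\mathrm{eff}} \le 0$
  (non-clearing kinetics) always error.

### Single-time-point scaling for later cycles

Cycles imaged once at 24 h are scaled from the fully sampled reference
cycle (cycle 2):

$$AD_{c3/4} = AD_{c2} \times
  \frac{\mathrm{counts}_{24h,\,c3/4}}{\mathrm{counts}_{24h,\,c2}} \times
  \frac{V_{24h,\,c2}}{V_{24h,\,c3/4}}.$$

This is exact when the new cycle shares the reference cycle's effective
washout; the count ratio then carries the change in uptake and the volume
ratio restores the per-mass normalisation. Under that assumption the
scaled dose reproduces a full multi-time-point calculation exactly, which
the test suite verifies on noise-free synthetic cycles.

### Partial-volume correction

Imaging blur displaces counts across VOI boundaries; the recovered
fraction (recovery coefficient, RC) falls with VOI volume. Doses are
corrected by division, $AD_{\mathrm{corr}} = AD / RC(V)$, using a monotone
knot curve (`recovery_curve()`), linearly interpolated and clamped at the
end knots so the correction never overshoots. The default curve passes
through RC = 0.5 at 2 mL — the volume floor used for lesion selection —
and saturates at 1 for large volumes. Correction is applied to lesions
only; healthy-organ VOIs are large enough that RC ≈ 1. Curves can be
calibrated from sphere phantoms: `generate_phantom_images()` simulates
uniform spheres under an isotropic Gaussian point-spread function and
`fit_recovery_curve()` smooths the measured fractions with isotonic
regression (pool adjacent violators) and clips them to (0, 1]. Dividing
the dose by RC is equivalent to scaling the counts, by linearity of the
whole chain.

### Volumes across cycles

By default each structure keeps its baseline volume for all cycles
(`volume_mode = "baseline"`), reflecting delineation on a single reference
CT; low-dose CT of later cycles rarely supports accurate re-contouring.
`volume_mode = "per_cycle"` uses each cycle's recorded volume instead.
With constant volumes the single-time-point volume ratio is 1 and the RC
is identical across cycles, which keeps the two dose paths mutually
consistent.

### Cumulative dose and indices

`compute_course_dosimetry()` sums the per-cycle doses per structure
(CumAD, an exact sum by construction) and summarises each patient's
lesions by the mean, minimum and maximum total dose. It accepts a
whole-cohort table and aggregates per patient internally — the natural
granularity, since its output (per-patient indices) is itself a
cohort-level table.

## Lesion selection and response

Target-lesion rules for the response analysis: bone lesions are excluded
(CT response assessment is unreliable in bone), lesions under 2 mL are
excluded (RC < 0.5 makes partial-volume errors dominate), and at most 5
lesions per organ/site per patient are kept, always including the site's
largest and smallest lesion. Where more than five qualify, the three free
slots are filled by descending volume with ties broken by lesion id — a
deterministic completion of the max/min rule. The volume floor is applied
at baseline only; a lesion that shrinks below 2 mL by month 3 remains
evaluable (that shrinkage *is* the response).

Response is the percent volume change between baseline CT and the CT
three months after the last cycle,
$\Delta V\% = 100\,(V_{M3} - V_{BL})/V_{BL}$. A lesion is *controlled*
when $\Delta V\% \le 0$ and *stable* when $\Delta V\% \le +20$; both
boundaries inclusive, so controlled implies stable. Lesions without a
month-3 volume keep a missing response and are excluded from
dose–response fitting but still contribute to the patient dose indices.

## Outcome statistics

### Plateaued dose–response

The relation between lesion total dose and volume change is fitted as

$$\Delta V\% = \mathrm{floor} + (\mathrm{cap} - \mathrm{floor})
  \, e^{-\mathrm{rate} \cdot AD} + \varepsilon,$$

monotone nonincreasing with a saturation plateau: beyond some dose, more
radiation no longer improves shrinkage. The fit uses variable projection —
for fixed rate the model is linear in (floor, cap), so a 1-D golden-section
search over the rate (interval $[10^{-5}, 1]$ Gy$^{-1}$, tolerance
$10^{-10}$) with a closed-form inner regression gives the least-squares
optimum; a constant model is returned when it fits at least as well as any
interior rate. This is exact on noiseless data and fast enough to sit
inside a bootstrap.

Uncertainty comes from a patient-level cluster bootstrap (default 1,000
seeded resamples), which respects within-patient correlation of lesions.
The primary 95% interval is estimate $\pm\, t_{G-1, 0.975}$ × bootstrap
SE with $G$ the number of patients: with a few dozen clusters this
normal-theory form calibrates noticeably better than raw percentile
intervals for the extrapolated zero-dose parameter (cap), whose
information comes from the sparse low-dose tail. Percentile intervals are
kept in `ci_percentile`. The sign and p-value of the monotone association
are reported by Spearman rank correlation. A straight-line alternative
(`model = "linear"`) is available for sensitivity analysis.

### Tumor control probability

`fit_tcp()` fits P(controlled) as a logistic function of total dose by
maximum likelihood and reports the doses at 50% and 90% control
probability when the slope is positive. Separation (e.g. every lesion
controlled) makes the ML estimate diverge; it is detected from the glm
warning, non-convergence or runaway coefficients, and the model is then
refitted with Firth's bias-reducing penalty (IRLS with the hat-matrix
score correction), which always yields finite estimates, and flagged.

### Toxicity and labs

Organ dose–toxicity association uses Spearman rank correlation between
the organ CumAD and the percent lab change from baseline, per organ–lab
pair, with an exact permutation p-value for tie-free $n \le 9$ and the
large-sample normal approximation $z = \rho\sqrt{n-1}$ otherwise, plus a
lowess trend exported for plotting. Visit-to-visit lab changes use the
paired two-sided Student t test. One degenerate case is resolved
explicitly: identical baseline and follow-up vectors return $t = 0$,
$p = 1$ (no evidence of change), while a nonzero constant difference —
zero variance with a nonzero mean — errors, since the t statistic is
undefined there.

### Survival

Dose indices are dichotomized at the cohort median — values equal to the
median go to the high group, a deterministic rule — and the groups are
compared with Kaplan–Meier curves (Greenwood pointwise intervals, medians
reported as not reached when the curve never crosses 0.5), a Cox
proportional-hazards model (high vs low, Efron tie handling, Wald CI and
p) and the log-rank test. When one group has no events the hazard ratio
is flagged non-estimable and the KM output is still returned. No
multiple-testing adjustment is applied across endpoints or indices.

## The synthetic cohort generator

`generate_cohort()` produces every table the pipeline consumes, plus the
generating truth, from one root seed. Its defaults emulate a 35-patient
GEP-NET cohort treated with up to four cycles of 7.4 GBq: 1–9 lesions per
patient, sites weighted toward liver and lymph nodes, lognormal baseline
volumes (median 10 mL), lesion effective half-lives with prior mean 80 h
(organs 55–67 h), all bounded by the 159.5 h physical half-life via
rejection resampling, and initial activity concentrations set so that
organ and lesion doses land in the clinically reported ranges (lesions
~25–30 Gy in early cycles, kidneys ~2.7 Gy/cycle, bone marrow ~0.3
Gy/cycle). Lesion uptake declines by a factor 0.85 per cycle; organ
uptake is stable. Counts are Poisson around
$A_0 V e^{-\lambda t} \cdot cf \cdot \mathrm{duration} \cdot RC(V)$ with
$cf = 10$ cps/MBq and 2,700 s acquisitions, giving $\ge 10^4$ counts per
VOI in the relevant regime; `noise_free = TRUE` replaces draws by their
means for exact-arithmetic tests, and the noise is applied after all
kinetics draws so noise-free and noisy runs of one seed share identical
ground truth. Volume response follows the plateaued model (floor −45%,
cap +30%, rate 0.02/Gy, Gaussian noise SD 15%), lab changes are linear in
the organ CumAD (e.g. platelets −28%/Gy of marrow dose, noise SD 10%),
and survival is exponential with log-hazard linear in the true mean total
lesion dose (−0.012/Gy around a 91 Gy reference; PFS median 30 months,
OS 57 months at the reference, administrative censoring at 36–72 months).
An optional lognormal patient-level random effect on uptake
(`patient_effect_cv`) is exposed but defaults to 0: no empirical value
for within-patient kinetic correlation is available to match.

What the generator deliberately does *not* emulate: reconstruction-stage
effects (scatter, attenuation, noise correlations between time points),
segmentation error, non-monoexponential kinetics (uptake phases,
biexponential washout), site-specific response differences, and informative
censoring. Passing tests therefore demonstrate that the pipeline recovers
truth *under its own model assumptions* — kinetics really are
monoexponential, PVE really is the configured RC curve — not that those
assumptions hold on any particular scanner or cohort.

## Numerical choices and degenerate inputs

* Monoexponential fits require ≥ 3 distinct positive time points and
  strictly positive dose rates; zero counts give a zero dose rate and fall
  back to the single-time-point path at the cycle level (zero new counts
  give 0 Gy, a valid dose).
* The rate search interval and tolerance above; the plateau fit compares
  the interior optimum against the constant model explicitly.
* RC curves are validated to be strictly increasing in volume and
  nondecreasing in RC with values in (0, 1]; evaluation clamps outside the
  knot range.
* Bootstrap resamples that collapse the dose spread are dropped (counted
  in `n_boot_ok`) rather than propagating errors.
* All simulation, bootstrap and permutation procedures take explicit
  seeds; `generate_cohort()` draws everything from one root seed and is
  byte-reproducible.

## Validation problem sizes

The test suite validates each claim at a size chosen to make Monte-Carlo
noise small relative to the tolerance being checked: 100-point property
sweeps for the kinetics oracle; a full 35-patient Poisson cohort
(~1,200 structure-cycles) for engine recovery; 1,000 replicates for the
monoexponential noise study and the log-rank type-I error; 200 replicates
with 400 bootstrap resamples for dose–response interval coverage; and 21–25
replicates at n = 500 for TCP-slope and Cox log-HR recovery, judged at the
median so the check measures estimator accuracy rather than one draw's
sampling noise (a single n = 500 Cox fit has SE(log HR) ≈ 0.11, larger
than the 10% recovery band being verified).

## Known limitations

* LED ignores photon dose and cross-irradiation; organ doses (especially
  bone marrow from blood and remote sources) are underestimates of a full
  transport calculation.
* The monoexponential back-extrapolation to $t = 0$ ignores any uptake
  phase before 4 h.
* Single-time-point scaling inherits the reference cycle's washout; a true
  kinetic change between cycles biases those doses.
* Baseline-volume dosimetry underestimates the dose to strongly shrinking
  lesions, which flattens the apparent dose–response at the high end —
  one candidate explanation for the plateau.
* The Cox comparisons are univariable by design; no clinical covariates
  are modelled.
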