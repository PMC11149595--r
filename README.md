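# lutadose

VOI-based dosimetry and outcome analysis for [¹⁷⁷Lu]Lu-DOTATATE therapy.

Patients with somatostatin-receptor-positive gastroenteropancreatic
neuroendocrine tumors are treated with a fixed regimen of [¹⁷⁷Lu]Lu-DOTATATE
(typically 4 × 7.4 GBq, 8 weeks apart), yet the absorbed doses actually
delivered to tumors and organs at risk vary widely between patients. Because
¹⁷⁷Lu co-emits imageable γ-photons, serial post-infusion SPECT/CT lets a
physicist quantify those doses per volume of interest (VOI) — and ask
whether they predict tumor shrinkage, hematologic toxicity and survival.
`lutadose` implements that full chain for medical physicists and
biostatisticians working on PRRT dosimetry, together with a seeded
synthetic-cohort generator with known ground truth for validating every
stage.

## The model

**Activity → dose rate** (local energy deposition, density-corrected):

    A  = counts / (duration · cf)                        [MBq]
    Ḋ  = A · 1e6 · E_LED · 3600 / (V·ρ/1000)             [Gy/h]

with calibration factor `cf` (cps/MBq), VOI volume `V` (mL), density `ρ`
(g/mL), and `E_LED = 2.3694e-14` J/decay (≈147.9 keV of locally deposited
electron energy per ¹⁷⁷Lu decay; configurable).

**Time integration** (cycles imaged at 4, 24, 72, 192 h): a monoexponential
`Ḋ(t) = Ḋ₀·exp(−λ_eff·t)` is fitted by log-linear least squares and
integrated analytically, `AD = Ḋ₀/λ_eff` (Gy).

**Single-time-point scaling** (cycles imaged once at 24 h):

    AD_c3/4 = AD_c2 · (counts_24h,c3/4 / counts_24h,c2) · (V_24h,c2 / V_24h,c3/4)

**Partial-volume correction**: `AD_corr = AD / RC(V)` with a monotone
recovery-coefficient curve (RC = 0.5 at 2 mL by default), calibratable from
simulated sphere phantoms. Cumulative dose per structure is the sum over
cycles; per patient, lesions are summarised by their mean/min/max total AD.

**Outcome layer**: plateaued dose–response
`ΔV% = floor + (cap−floor)·exp(−rate·AD)` with patient-cluster bootstrap
CIs; tumor control probability by logistic regression (Firth fallback under
separation); Spearman organ-dose/lab-change correlations; paired t tests;
and median-dichotomized Kaplan–Meier / Cox / log-rank survival comparisons.

## Worked example

```r
library(lutadose)

cfg <- cohort_config(seed = 7)          # 35-patient synthetic cohort
coh <- generate_cohort(cfg)

cycle_doses <- compute_cycle_doses(coh$timepoints, cf = cfg$counting$cf,
                                   rc_curve = cfg$pve)
dosim <- compute_course_dosimetry(cycle_doses)
dosim
#> Patient dosimetry: 343 structures, 35 patients
#>   median mean-total-AD over lesions: 90.97 Gy

les <- select_lesions(coh$lesions)      # bone / <2 mL / >5-per-site rules
les$total_ad_gy <- dosim$structures$cum_ad_gy[
  match(les$lesion_id, dosim$structures$structure_id)]
les$delta_v_pct <- compute_delta_v(les$v_bl_ml, les$v_m3_ml)
sel <- les[les$selected, ]

fit_dose_response(sel$total_ad_gy, sel$delta_v_pct, sel$patient_id,
                  n_boot = 1000, seed = 8)
#> Dose-response fit (plateau model), 169 lesions / 35 patients
#>             floor     cap   rate
#> estimate -45.0735 26.7015 0.0184
#> 2.5%     -53.0547  6.0147 0.0100
#> 97.5%    -37.0923 47.3883 0.0268
#> Spearman rho = -0.622 (p = 1.77e-19)

fit_tcp(sel$total_ad_gy, sel$delta_v_pct <= 0)
#> TCP logistic model (n = 169): intercept = -1.220, slope = 0.0550 /Gy (p = 9.27e-05)
#>   D50 = 22.2 Gy, D90 = 62.2 Gy

idx <- patient_dose_indices(sel)
pfs <- coh$survival[coh$survival$endpoint == "pfs", ]
cov <- idx$mean_total_ad[match(pfs$patient_id, idx$patient_id)]
survival_by_median(cov, pfs$time_months, pfs$event, endpoint = "pfs")
#> Survival comparison (pfs), median cut at 85.03 Gy, n = 35
#>   median survival: low = 25.5 mo, high = 38.5 mo
#>   HR (high vs low) = 0.51 (95% CI 0.22-1.16), p = 0.108; log-rank p = 0.101
```

Reading the output: lesion shrinkage saturates near the −45% floor with a
response rate of ~0.02/Gy (lesions receiving ≳100 Gy sit on the plateau);
the positive TCP slope puts 50% control probability near 22 Gy; and the
high-dose half of the cohort shows a hazard ratio of about 0.5 for
progression — underpowered at n = 35, as the wide CI shows. The generating
truth for this cohort is in `coh$truth`, which is how the test suite
verifies recovery.

`run_pipeline("out/", config = cfg)` runs all four stages on one output
directory and writes the tables, a statistics JSON and a manifest with MD5
checksums; identical seeds reproduce identical checksums.

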