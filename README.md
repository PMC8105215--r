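# clavpk

Quantitative workflow for targeted LC-MS/MS determination of clavulanic
acid in broiler chicken plasma and meat. The package is aimed at
veterinary-residue and bioanalytical chemists who need the *computational*
half of a method-validation and pharmacokinetic study as reusable, tested
code: everything downstream of integrated peak areas, from identity
confirmation to the pharmacokinetic parameter table.

It covers four stages, plus a seeded generator that emulates the study's
data so the whole pipeline runs with no external inputs:

1. **Identity confirmation** — theoretical monoisotopic *m/z* from an
   elemental formula (principal isotopes, electron mass per charge),
   signed mass accuracy
   `MA = (m/z_exp − m/z_theor)/m/z_theor × 10⁶` ppm, and the confirmation
   rule: precursor plus ≥ 3 product ions each within the ppm limit
   (default 5 ppm), optional retention-time agreement.
2. **Calibration** — weighted linear regression of peak-area ratio
   (analyte/internal standard) on concentration with weights `wᵢ = 1/xᵢ`,
   slope/intercept/weighted R² with standard errors, back-calculation, and
   detection limits from a 10-replicate spiked-blank panel:
   `LOD = 3.9·SD(signals)/slope`, `LOQ = 3.3·LOD` (EU guidance
   constants).
3. **Validation** — recovery `measured/expected × 100` with the VICH GL49
   window −20 %/+10 % (pass iff mean recovery ∈ [80, 110] %); within-run
   precision `CV = 100·SD/mean` with limits 15 % below 100 µg·L⁻¹ and
   10 % at or above; specificity from 20 blank vs 20 fortified samples;
   storage stability as percent remaining against an 85 %-remaining
   threshold.
4. **Non-compartmental PK** — for destructive sampling (one bird per
   sample; group means): Cmax/Tmax read from the profile, elimination
   constant `Kel = −slope` of ln C vs t over the terminal phase,
   `T½ = ln 2 / Kel`, linear trapezoidal `AUC(0–t_last)` with a (0, 0)
   oral-dosing anchor, exponential tail `C_last/Kel`, and the exact
   decomposition `AUC(0–∞) = AUC(0–t_last) + AUC(t_last–∞)`.

The synthetic generator reproduces the study design: 6-level 10–2000
µg·L⁻¹ plasma calibration in triplicate with level-dependent relative
noise, a 14-group × 8-bird oral PK experiment under a one-compartment
absorption model (`C(t) = D·ka/((V/F)(ka−ke))·(e^(−ke·t) − e^(−ka·t))`)
in the regime Cmax ≈ 1.82 mg·L⁻¹ at 0.25 h with ke = 0.80 h⁻¹, and
first-order storage decay by condition.

## Worked example

```r
library(clavpk)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
```

```
=== Validation report (seed 1) ===
Identity confirmation: CONFIRMED
  MA limit 5 ppm; 4 ion(s) measured
...
Calibration curve (weighting 1/x): y = 0.0112569 x -0.0965621
  R^2 = 0.9963 (sd over replicate curves 0.0008)
  Sm = 0.000173, Sb = 0.0286; 6 levels over [10, 2000], n = 18
LOD = 0.149, LOQ = 0.493 (x3.9 SD/slope, x3.3 LOD; SD = 0.0004313 over 10 spikes at level 10)
Mean recovery 97.8% (acceptance 80-110%): PASS
Within-run precision: PASS
Specificity: PASS
  20 blanks (threshold 0.00074), 20 fortified
Stability (threshold 85% remaining):
 condition first_unstable_time
      -20C                   1
      -80C                  12
        4C                   1
Non-compartmental analysis
  Cmax  = 1.99 mg/L at Tmax = 0.5 h
  Kel   = 0.8 1/h (SE 0.12, R^2 0.9593 over t = 3, 4, 5, 6 h)
  T1/2  = 0.87 h
  AUC 0-6 h = 2.91; tail = 0.0297; AUC 0-inf = 2.94 mg.h/L
```

Reading this: the four reference transitions confirm identity (all
|MA| < 5 ppm); the weighted fit recovers the generating slope 0.0113
within its standard error; recovery and CVs sit inside the guideline
windows; refrigerated and −20 °C storage lose more than 15 % of analyte
within a week while −80 °C holds through week 4 (so samples must be
processed promptly); and the terminal log-linear fit over 3–6 h returns
Kel ≈ 0.80 h⁻¹, i.e. a half-life of 0.87 h. The 5-min sampling interval
is excluded from the profile by default (unabsorbed dose refluxed at
sacrifice inflates it); `pipeline_config(nca = list(exclude = ...))`
controls this.

Individual stages are plain functions — `monoisotopic_mz()`,
`confirm_identity()`, `fit_weighted_curve()`, `estimate_lod_loq()`,
`compute_recovery()`, `compute_precision()`, `evaluate_specificity()`,
`evaluate_stability()`, `build_profile()`, `fit_kel()`,
`auc_trapezoid()`, `run_nca()` — and accept data frames, so each can be
used on real exported peak tables (CSV schemas in the function docs). A
thin command-line wrapper with `simulate`/`identify`/`calibrate`/
`validate`/`nca`/`run` subcommands is installed at
`inst/cli/clavpk.R`.

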