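---
title: "Methods: validation and pharmacokinetics of a clavulanic acid LC-MS/MS assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validation and pharmacokinetics of a clavulanic acid LC-MS/MS assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clavpk)
```

Clavulanic acid is a β-lactamase inhibitor co-administered with β-lactam
antibiotics (amoxicillin–clavulanate) in poultry medicine. Monitoring its
residues and pharmacokinetics in broiler chickens requires a validated
LC-MS/MS assay in plasma and meat, and the derived PK parameters drive
dosing and withdrawal decisions. `clavpk` implements the computational
workflow of such a study — identity confirmation, weighted calibration
with detection limits, guideline validation, and non-compartmental
analysis — together with a seeded generator of study-structured data, so
that every stage is exercised end to end without instrument exports.

This vignette is the package's account of the underlying methods, the
parameters that matter, and the design choices that were genuinely open.

## Identity confirmation

Targeted acquisition (parallel reaction monitoring, negative ESI) tracks
the clavulanate anion [C~8~H~8~NO~5~]^−^ and three product ions, with
tazobactam [C~10~H~11~N~4~O~5~S]^−^ as internal standard. Theoretical
*m/z* is the sum of principal-isotope masses plus one electron mass per
negative charge, divided by |charge|:

$$ m/z = \frac{\sum_e n_e M_e + z^-\, m_e}{|z|} $$

Isotope masses are carried to ≥ 9 decimals and the electron mass
(5.48579909 × 10⁻⁴ u) is included per charge; both are needed to
reproduce reference anion masses at the 5th decimal (198.04080 for the
clavulanate precursor). Mass accuracy is the signed relative deviation

$$ \mathrm{MA\ (ppm)} = \frac{m/z_{\exp} - m/z_{theor}}{m/z_{theor}} \times 10^6 , $$

and confirmation requires the precursor plus at least three product ions
with |MA| below the limit (default 5 ppm, the PRM confirmation
criterion). Retention-time agreement (default tolerance 0.2 min) is
checked only when a measured RT is supplied, because the observed RT
shifts with matrix (1.26–1.38 min across acetonitrile, plasma, meat for
these analytes). Product-ion elemental compositions are not assigned;
their theoretical masses are the library values, which the confirmation
treats identically to computed ones.

## Weighted calibration and detection limits

LC-MS/MS response ratios have noise roughly proportional to signal, so
ordinary least squares over a 200-fold concentration range would let the
top levels dominate. The curve is therefore fit by weighted least squares
with $w_i = 1/x_i$, minimising $\sum_i w_i (y_i - m x_i - b)^2$ via the
weighted normal equations. Reported with the slope and intercept are
their standard errors from the weighted residual variance (n − 2 df) and
a weighted $R^2 = 1 - SSE_w/SST_w$ with the weighted mean in the total
sum of squares. The "SD of the correlation coefficient" reported
alongside validation tables is interpreted here as the standard deviation
of $R^2$ across the per-replicate curve fits and is labelled `sd_r2`;
this is an interpretation, since the quantity has no unique textbook
definition.

Blanks are excluded from the fit — $1/x$ is undefined at $x = 0$ — and
feed the specificity assessment instead. Back-calculation inverts the
line, $(y - b)/m$; negative results are returned as-is with a warning,
because they are diagnostic of blank-level signal.

Detection limits follow the EU guidance estimator from $n$ replicate
blanks spiked at the lowest calibration level (default $n = 10$):

$$ LOD = 3.9\,\frac{SD(\text{signals})}{m}, \qquad LOQ = 3.3 \cdot LOD . $$

Numerical choices: the SD is the n − 1 sample estimator (the guidance
does not specify; this is pinned by test), panels with fewer than 3
replicates are rejected, and the SD is taken over raw area ratios
(signal domain) with the slope converting to concentration units. The
LOQ/LOD ratio is exactly 3.3 by construction, and both limits are
invariant to rescaling all responses by a constant (the SD and slope
scale together) — properties the test suite asserts.

## Guideline validation

* **Recovery** (accuracy): per level, $100 \cdot \overline{measured}/expected$;
  overall, the unweighted mean across levels. Acceptance is the VICH GL49
  window of −20 % to +10 %, i.e. mean recovery in [80, 110] %. Boundary
  values pass; the comparison carries a 10⁻⁹ tolerance so that a recovery
  of exactly 110 % is not failed by floating-point round-off.
* **Within-run precision**: $CV = 100 \cdot SD/\overline{x}$ per level,
  limit 15 % for levels below 100 µg·L⁻¹ (or µg·kg⁻¹) and 10 % at or
  above — the breakpoint and both limits are arguments.
* **Specificity**: 20 blanks vs 20 fortified samples. A blank offends
  when its response exceeds a fraction (default 0.2) of the response at
  the lowest quantifiable level; each fortified sample must exceed that
  LLOQ response. The 20 % threshold is the common bioanalytical
  convention, chosen because the guideline states the comparison but no
  numeric criterion; it is configurable. Smaller panels warn rather than
  error, since pilot panels are legitimate.
* **Stability**: percent remaining per condition × time × nominal cell
  (triplicate means), flagged against a remaining-fraction threshold
  (default 0.85), with the first unstable time summarised per condition.

An important identity discovered while assembling the pipeline: with
$1/x$ weights and equal replicates per level, evaluating the calibration
set against its *own* fitted curve gives a mean per-level recovery of
exactly 100 % — the weighted normal equation $\sum_i (y_i - b)/x_i = n m$
forces it. Recovery and precision are therefore judged on an independent
validation run (a second simulated replicate set, or a user-supplied
CSV), as a laboratory would do with separate QC samples.

## Non-compartmental pharmacokinetics

The PK experiment is destructive: each bird contributes one plasma sample,
so the profile is the per-time group mean ± SD (14 sacrifice times, 8
birds each). The analysis is model-free:

* **Cmax/Tmax** are read directly from the mean profile; ties break
  toward the earlier time.
* **Kel** is the negative OLS slope of $\ln C$ on $t$ over the terminal
  phase. Window strategies: `last_n` (default n = 4 quantifiable points
  after Tmax — a common NCA default that gives a clean terminal fit in
  this sampling design) or `best_adjusted_r2`, the usual λ~z~ scan over
  all terminal windows of ≥ 3 points. Two-point fits are allowed with a
  warning; non-positive fitted Kel is flagged invalid.
* **T½** $= \ln 2 / K_{el}$, computed with the full-precision constant
  rather than the rounded 0.693 (the difference is below reporting
  precision; summaries print two decimals).
* **AUC** uses the linear trapezoid on the mean profile. A (0, 0) anchor
  is prepended for oral dosing — the pre-dose concentration is zero —
  and can be switched off. The tail beyond the last quantifiable time is
  $C_{last}/K_{el}$, and $AUC_{0\text{–}\infty}$ is stored as the exact
  sum of the two segments. A log-linear-down trapezoid was considered and
  rejected as the default because the method description is explicitly
  the (linear) trapezoidal rule; interval labels use hours even where
  legacy tables subscript minutes (0–1440 min ≡ 0–24 h).
* **Exclusions**: the first sampling interval (5 min) is excluded by
  default in the pipeline, with the recorded reason that unabsorbed dose
  refluxed at sacrifice inflates both its mean and its variance. Which
  points entered the original elimination regression, and whether an
  anchor was used, are not documented anywhere authoritative — both are
  plain configuration here, not guesses presented as fact.
* **Censoring**: concentrations below the LLOQ are flagged; the profile
  builder either drops them (default) or imputes zero. Dropping biases
  terminal means upward, imputing zero downward; with the default design
  the affected times (12 h, 24 h) fall out of the quantifiable range
  either way.

## What the synthetic generator emulates — and what it does not

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `calibration_levels` | 10, 50, 100, 500, 1000, 2000 µg·L⁻¹ | 6-level plasma/ACN scale (meat: 7 levels, 50–2000 µg·kg⁻¹) |
| `response_slope`, `response_intercept` | 0.0113, −0.1093 | plasma curve parameters (area ratio per µg·L⁻¹) |
| `cv_by_level` | 10.9 % at 10 → 2.8 % at 500 → 5.3 % at 2000 | relative SD per level, anchored at the plasma within-run CVs and interpolated between |
| `replicates_per_level` | 3 | triplicate levels |
| `pk_model` | D = 2.5 mg·kg⁻¹, ka = 11.4 h⁻¹, ke = 0.80 h⁻¹, V/F = 1.124 L·kg⁻¹, CV 50 % | one-compartment oral model; ka and V/F solve Tmax = ln(ka/ke)/(ka−ke) ≈ 0.25 h and Cmax ≈ 1.82 mg·L⁻¹; the 50 % log-normal between-animal CV matches Cmax 1.82 ± 0.91 |
| `sampling_times`, `animals_per_group` | 0.08 … 24 h, 8 | the destructive design (14 × 8) |
| `lloq` | 0.01 mg·L⁻¹ | censoring threshold |
| `decay_rate_by_condition` | 4 °C 0.5, −20 °C 0.25, −80 °C 0.03 wk⁻¹ | chosen so 4 °C and −20 °C drop below 85 % within a week while −80 °C holds through week 4 but not week 12 |

The stated dose merits a note: the preparation arithmetic behind it
(2 mL of a 5 g·L⁻¹ solution of a 125 g·kg⁻¹ product to a 0.4 kg bird)
implies roughly 3.1 mg·kg⁻¹ of clavulanic acid rather than 2.5. The
generator does not resolve this; dose is a free parameter with 2.5 as the
default, and every PK quantity scales linearly with it.

Calibration noise is Normal with SD proportional to the mean — exactly
the premise of 1/x weighting — truncated at zero with a flag rather than
resampled, which keeps the draw auditable. Between-animal variability is
log-normal with mean 1 (concentrations are positive and right-skewed).
An optional `contaminated_first_point` switch multiplies the first time
group by a configurable factor so the exclusion rule is testable.

What the generator does **not** emulate: raw spectra or chromatograms
(the pipeline starts at integrated areas, as the computations it
implements do), carry-over, drift within a run, matrix-dependent
interference structure, correlated errors between analyte and internal
standard, or model misspecification in the PK curve (real profiles need
not be one-compartment). Passing tests on generated data therefore
demonstrate correctness of the *computations* under the stated noise
model, not robustness of the assay to real-matrix pathologies.

Determinism: every generator runs under a seed derived from
`config$seed` plus a per-function offset, restores the caller's RNG
state afterwards, and reproduces byte-identical tables for identical
(seed, config). A `run` index draws independent replicate sets (run 1:
calibration; run 2: the validation run) reproducibly.

## Verification design and problem sizes

Oracle checks run against independent routes: the weighted fit against
`stats::lm(weights =)` (10⁻¹⁰) and a brute-force minimiser, the
trapezoid against dense-grid integration of the interpolant (10⁻⁹) with
AUC additivity to 10⁻¹², and the elimination fit against closed forms on
noise-free exponentials (10⁻¹²).

Statistical checks use deliberately sized simulations: calibration-CV
convergence on 2000 replicates (3·SE band), LOD expectation over 300
seeded panels, and Kel recovery over 200 simulated 14 × 8 studies. The
Kel-recovery experiment runs at a between-animal CV of 20 % — moderate,
against the study's ~50 % — with a six-point terminal window; both were
fixed from the closed-form slope standard error,
$SE \approx (cv/\sqrt{n_{animals}})/\sqrt{\sum (t_i - \bar t)^2}$, which
predicts ≈ 97 % of runs inside 0.80 ± 0.04 h⁻¹ under these settings,
versus ≈ 79 % for the four-point default — too near the 80 % acceptance
fraction for the check to be informative about correctness rather than
luck. At the full 50 % CV the four-point Kel wobbles visibly between
seeds (single-study values of 0.70–0.82 h⁻¹ are routine), which is worth
remembering when reading any single destructive-sampling study's ± value.

## Known limitations

* Recovery here is computed from back-calculated concentrations; with a
  separate validation run this is standard, but extraction recovery in
  the physical sense (pre- vs post-extraction spike) is out of scope, as
  are the wet-lab procedures themselves.
* Between-run (intermediate) precision and reproducibility are not
  implemented — the validated design was within-run only.
* Only linear calibration is supported; quadratic or 4PL models are
  deliberate non-goals.
* Meat-matrix defaults share the plasma noise anchors where meat-specific
  CVs exist only at three levels; only the structure, not the printed
  values, is reproduced there.
* The NCA assumes the terminal phase is mono-exponential on the group
  means; destructive sampling precludes per-animal λ~z~ and hence any
  within-animal SE of Kel beyond the regression SE.
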