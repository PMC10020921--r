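---
title: "Methods: simulating and analyzing secular trends in pediatric forearm bone traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing secular trends in pediatric forearm bone traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forearmspa)
library(dplyr)
```

## The problem

Single-photon absorptiometry (SPA) measured forearm bone mineral in children
decades before DXA existed, and a scanner kept in service across four decades
makes a rare natural experiment possible: measuring two cross-sectional
cohorts of children (one historical, one contemporary) on the *same*
apparatus and asking whether bone mineral and bone geometry have changed.
Lower areal bone mineral density (BMD) in contemporary children need not mean
weaker bones: BMD is mineral content divided by projected area, so a wider
bone with the same mineral reads *lower* BMD while being mechanically
*stronger* (bending resistance grows with the fourth power of the radius).
Distinguishing these scenarios requires deriving structural traits --- cortical
areas, cross-sectional moment of inertia (CSMI), section modulus, a strength
index --- from the scan profile, and comparing whole age *trajectories*
between cohorts rather than point averages.

The original participant-level data from such studies are not publicly
available. `forearmspa` therefore provides the complete analysis chain as
tested, reproducible code operating on synthetic data: a generative model of
two-cohort pediatric trait data, a physics-based SPA scan simulator, trace
analysis that recovers mineral content and bone widths, the mechanics
formulas, phantom-based drift correction, and the log-linear trajectory
models --- so every method can be verified end to end against known truth.

## The trait model

Every trait $y$ follows a multiplicative age trajectory. With $S = 1$ for
girls, $C = 1$ for the comparison (2017--2018) cohort, and age $a$ in years:

$$\log y = \log \beta_0 + \log r_{sex}\,S + \log r_{coh}\,C +
\left(\log r_{age} + \log r_{age:sex}\,S + \log r_{age:coh}\,C\right)(a - 7)
+ \varepsilon, \qquad \varepsilon \sim N(0, \sigma_{\log}^2).$$

Age is centered at 7 (the youngest study age), boys and the earlier cohort
are the reference levels, and coefficients are reported as antilogs: $r_{coh}$
is the relative difference at age 7, $r_{age:coh}$ the relative difference in
annual change. A ratio $r$ is presented as $(r - 1) \times 100$ percent (per
year for interaction terms). `fit_trend()` implements exactly this model by
ordinary least squares on the natural-log outcome (Model 1: age, sex, cohort
and the two age interactions; Model 2 adds height and weight), with Wald 95%
confidence intervals computed on the log scale and antilogged. Two-sided
t-based p-values with a 0.05 threshold are reported and no multiple-testing
adjustment is applied, matching standard practice for this family of
normative-cohort analyses. Height is modeled with an additional squared
centered-age term and its sex interaction (`fit_growth_model()`), because
log-scale pediatric growth is visibly curved.

`predict_at_age()` evaluates the multiplicative equation directly, so
predictions at age 16 and cohort differences there can be computed either
from a fitted model or from a published coefficient table via
`trend_coefficients()`.

### Covariate scale in Model 2

The source analyses do not state whether height and weight enter on the raw
or log scale. `fit_trend()` enters them untransformed by default --- the more
common epidemiological choice for covariate adjustment of a log outcome ---
and offers `log_covariates = TRUE` as the alternative. The cohort inferences
are insensitive to this choice in simulation.

## The synthetic-data generator

`default_generative_params()` fixes the generative truth at the published
age- and sex-adjusted (Model 1) estimates for ten distal-forearm traits:
bone mineral content (BMC, mg/cm), BMD (mg/cm^2), bone mineral apparent
density (BMAD, mg/cm^3), periosteal and medullary diameter (mm), cortical
thickness (mm), total area (cm^2), CSMI (cm^4), section modulus (cm^3) and
strength index. Cohort sizes default to the study's 55/61 (boys/girls,
1979--1981) and 238/204 (2017--2018).

Choices the source material leaves open, fixed once here:

* **Age distribution.** Continuous uniform on [7, 16); the studies report
  integer age groups but no age histogram.
* **Residual scatter.** $\sigma_{\log}$ is not a published quantity. Defaults
  are 0.12 for mass/density traits and 0.08 for diameters --- producing
  scatter visually comparable to published per-sex scatter plots --- with
  proportionally larger values for the derived mechanics traits
  (CSMI 0.30, section modulus 0.22, strength index 0.18), consistent with a
  fourth-power dependence on diameter compounding diameter variability.
  All are configurable.
* **Each trait follows its own marginal model.** `generate_cohorts()` draws
  all ten traits independently from their own published trajectory
  coefficients. The alternative --- drawing only diameters and density and
  deriving the mechanics traits per child --- cannot reproduce the published
  mechanics-trait trajectories, because separately fitted models of real data
  are not the analytic pushforward of the diameter models (the derived-CSMI
  age-by-cohort contrast implied by the diameter coefficients is about
  4.2%/year, versus 5.2%/year fitted directly). Since the statistical
  machinery is validated by parameter *recovery*, the generator must treat
  each published trait model as the truth for that trait. The
  geometry-consistent route still exists, but in the physics chain:
* **Latent bone geometry.** `generate_bone_geometry()` expands each child to
  four bones (radius and ulna, both arms) by jittering the child's periosteal
  diameter, medullary diameter and volumetric density on the log scale with
  a between-bone correlation of 0.9 (radius and ulna at this site are nearly
  identical in width --- the two peaks of a real scan cannot be told apart).
  Each bone's linear mineral content is then *derived* as volumetric density
  times cortical area, so within the simulate-then-measure chain BMC, BMAD
  and geometry are exactly self-consistent.
* **Exclusion flags.** Fractures in the preceding year are Bernoulli(0.03)
  (the studies report 4/116 and 9/442 affected children) with a random
  injured arm; per-arm technical scan errors are Bernoulli(0.005).
* **Anthropometry.** Heights and weights follow per-sex quadratic log-age
  curves whose age-16 means match the published cohort contrasts (+1.4%
  height, +7.6% weight for the later cohort, at realistic Swedish absolute
  values).

What the generator deliberately does **not** emulate: puberty timing and its
secular shift, within-child longitudinal correlation (the design is
cross-sectional), non-uniform age sampling, measurement-occasion effects, or
correlated residuals across traits beyond the geometry chain. Passing tests
therefore demonstrate correctness of the estimators under the stated model,
not robustness to every feature of real pediatric data.

## The scan simulator

A forearm scan is a line of areal-density readings at 1 mm steps (the
default; configurable). The water cuff around the arm equalizes the
soft-tissue path, contributing a constant baseline. At position $x$, a bone
with outer diameter $d_o$, medullary diameter $d_i$ and cortical volumetric
density $\rho$ centered at $x_0$ adds

$$\rho \left[\mathrm{chord}(d_o, x) - \mathrm{chord}(d_i, x)\right],
\qquad \mathrm{chord}(d, x) = 2\sqrt{(d/2)^2 - (x - x_0)^2}$$

(zero outside the circle; marrow is water-equivalent). Photon-count physics
is abstracted into additive Gaussian noise per step, because only end-point
coefficients of variation --- not count statistics --- are available to
calibrate against. The simulator's conservation law, asserted in tests, is
that the noiseless trace integral equals gain x density x cortical area.

Instrument drift enters as a relative gain over calendar time
(`drift_model()`), including a step change when the radiation source is
replaced. `calibrated_drift_model()` builds the two-cohort scenario in which
the modern/early phantom segment-mean ratios equal 1.002 (before the source
change) and 1.034 (after), the published correction constants. Simulated
traces record the *nominal* calibration gain separately from the *applied*
(drifted) gain: analysis only knows the former, which is precisely why
phantom correction is needed.

## Trace analysis

* **Baseline**: mean of the outermost five steps on each flank; if the flank
  region is not flat (scan window too narrow, bone support reaching the
  flanks) estimation aborts rather than returning a contaminated value.
* **Segmentation**: contiguous supra-threshold regions of the
  baseline-subtracted signal; a forearm scan must yield exactly two. Any
  other count flags the scan as a technical error, which excludes it
  downstream --- mirroring the manual-era practice of discarding scans with
  technical measurement errors.
* **Periosteal edges**: outermost crossings of 10% of the per-bone peak
  height, refined by linear interpolation between grid steps. The 10%
  threshold biases the width low by well under 0.1 mm for realistic
  geometries (the chord profile falls steeply), far below the published 8%
  width CV.
* **Medullary edges**: under the chord model the profile of a cortical
  annulus attains its two maxima exactly above the medullary wall, so the
  medullary diameter is the separation of the two cortical peaks (parabolic
  sub-step refinement around each grid maximum). The historical procedure
  read widths manually from graphs with no stated criterion; a
  threshold-crossing rule at half peak height cannot work here, because the
  central dip of an annulus profile sits at about 0.58 of the peak --- above
  half height --- so no crossing exists. A cavity is scored only when the
  central dip descends at least 5% of the peak below the lower cortical peak;
  otherwise the bone is treated as solid. At a 0.1 mm step the noiseless
  round trip recovers the medullary diameter within 0.3 mm; at the 1 mm
  working step the error is of order one step, comparable to the published
  width precision.
* **BMC**: trapezoidal integral of the baseline-subtracted signal over the
  detected support (plus a two-step pad for the thresholded-away tails),
  divided by the nominal gain. Noise-dominated negative integrals floor at
  zero with a warning.
* **Averaging order**: BMC and the two diameters are averaged over the
  usable bones (four normally; two when a fracture in the preceding year
  restricts measurement to the uninjured arm), and *then* the derived traits
  are computed from the averaged primitives --- not the other way round. This
  matches the historical computation and is asserted in tests, since the two
  orders differ for nonlinear traits like CSMI.
* Children with no usable bone measurement are dropped and logged, not
  imputed.

## Drift correction and precision

`estimate_correction_constants()` divides the modern-era phantom mean by the
early-era mean, separately for scans made before and after the source
replacement; `apply_correction()` multiplies the early-era *mineral* traits
(BMC, BMD, BMAD, strength index) by the applicable constant and leaves
widths untouched, since the constants derive from mineral-readout phantoms
and the published width drift was separately assessed as negligible. The
correction is exactly invertible. In the calibrated scenario, skipping the
correction shifts the apparent cohort BMD gap by 3.4% --- pure instrument
artifact.

`precision_cv()` implements the root-mean-square CV across subjects, the
standard densitometry QA summary (the source material quotes CVs --- 2.7%
phantom, 4.8% repositioning, 8.0% width --- without naming the formula; RMS
is the field convention).

## Numerical and degenerate-input choices

* Diameters are converted mm to cm before the mechanics formulas, so CSMI
  and section modulus land in cm^4 and cm^3 --- the only unit choice
  consistent with the published (unlabeled) intercepts near 0.042 and 0.087.
  The published "total cortical area" column numerically matches the *total*
  cross-section ($\pi/4 \times 0.9455^2 \approx 0.704$), while BMAD is
  defined via the annulus area; the package keeps total, medullary and
  cortical areas as three distinct columns rather than resolving that naming
  ambiguity.
* Per-bone geometry draws violating medullary < periosteal are resampled (up
  to 50 rounds, then clamped to 0.95 x periosteal) and counted in an
  attribute.
* Bone centers in the pipeline separate adaptively (minimum 15 mm, always
  leaving a 3 mm soft-tissue gap) so large adolescent bones never overlap in
  the scan window.
* Degenerate geometry (medullary >= periosteal, zero cortical area, zero
  width) raises errors rather than propagating NaN.
* All randomness flows from one seed per run (`pipeline_config(seed = )`,
  `generate_cohorts(seed = )`); runs are byte-identical under a fixed seed.

## Problem sizes used in validation

The package's own validation (test suite and acceptance script) uses: the
full study sample sizes (558 children) for single-dataset checks; 200
replicate datasets for parameter-recovery and CI-coverage summaries (chosen
so the Monte-Carlo SE of each mean contrast is a few hundredths of a percent
per year, well below the contrasts being recovered); 0.1 mm steps for
round-trip accuracy checks versus the 1 mm working step; and 10,000 children
for convergence-of-means checks. Coverage of the 95% intervals is required
to fall in [0.93, 0.97], the two-sided binomial band for 200 replicates
pooled over terms.

## Known limitations

Cross-sectional trajectories are not individual growth curves; nothing here
estimates within-child velocity. The simulator omits energy-dependent
attenuation, scatter and detector dead time, and its Gaussian noise model is
an end-point abstraction. Cortical porosity, trabecular architecture and
bone turnover are invisible to a one-dimensional absorptiometry profile, and
radius and ulna are deliberately not distinguished. The marginal trait
generator reproduces each published trait model but therefore does not
enforce cross-trait algebraic identities (those hold only in the
geometry-consistent physics chain).
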