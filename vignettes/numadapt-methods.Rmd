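---
title: "Models and methods behind numadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(numadapt)
```

`numadapt` analyses how numerosity adaptation changes the monotonic
responses of early visual cortex, using model-based fMRI. This vignette is
the package's account of the science it implements: the models and their
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The stimulus and its quantification

Each display shows `n` dots (n ∈ 1–7, 20) of equal size inside a circle of
0.75° radius around fixation. The total dot surface area is held constant
across numerosities — dot radius is `sqrt(A / (n π))` analytically — so
display luminance cannot covary with numerosity. Placement is rejection
sampling under a minimum centre spacing (default 2.2 dot radii, restart
after 10⁴ failed proposals), which spreads items evenly and avoids
perceptual grouping. The defaults that the protocol leaves unstated are
explicit configuration: a single dot has a 0.5° diameter (`A = π 0.25²`
deg²), rasters use 64 px/° over a 2°×2° extent, background luminance 0.5
with black dots at 0 and white oddballs at 1.

Each 1.4 s TR (one fMRI volume) shows an adaptor display (300 ms), a 400 ms
blank, a changing display (300 ms), and a 400 ms blank. The changing
sequence per cycle is 1…7 ascending at 3 TRs each, 12 TRs of 20, 7…1
descending, 12 more TRs of 20; four cycles make a 264-TR, 369.6 s run, and
every changing numerosity 1–7 appears in exactly 24 TRs. The adaptor is
constant at 1 (low condition), constant at 20 (high), or equal to the
changing numerosity (changing — the control condition). Ten percent of
presentations show white dots; these oddballs exist only for the attention
task and are flagged but never enter any predictor.

### Aggregate Fourier power

The monotonic model's predictor is the logarithm of the display's
*aggregate Fourier power*. The package defines this as the sum of non-DC
2D-FFT coefficient **magnitudes** of the mean-removed raster. The choice is
forced by a Parseval argument: the summed **squared** magnitudes equal the
image's pixel variance times a constant, and with total dot area fixed the
pixel variance is fixed, so squared-magnitude full-band power is invariant
to numerosity by construction (we measure Spearman ρ ≈ −0.4, i.e. pure
pixelation noise). The magnitude sum instead grows strictly with
numerosity: smaller, more numerous dots spread the same contrast energy
over more frequency bins, and for a fixed sum of squares a more spread
spectrum has a larger magnitude sum. The squared aggregation (full-band or
band-limited in cycles/degree) remains available in
`aggregate_fourier_power()` for sensitivity analyses. The
numerosity-to-power lookup (`fourier_power_table()`) averages ≥ 20 displays
per level and is deterministic given its seed.

## Response models

**Monotonic.** Neural amplitude per TR is `log(power(n))` (default) or
`log n`; the two modes run through identical code paths and give closely
similar results because power follows numerosity monotonically. The fitted
slope β is the BOLD change per unit increase of the log predictor.

**Numerosity-tuned pRF.** Neural amplitude is a log-Gaussian
`exp(−(ln n − p)² / 2w²)` with preferred log numerosity `p` and log-space
width `w`. Candidates span p ∈ [0.007, 5.491] in steps of 0.01 and
w ∈ [0.03, 3] in steps of 0.0074; candidates with `p > 2.64 + 2w` are
excluded because they only predict responses to the 20-dot baseline.

**HRF.** Neural series are boxcars at the TR grid (sub-TR timing is not
modelled), convolved with a canonical two-gamma kernel (peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6) on a 0.1 s
grid and averaged back to TRs. The kernel is normalised to unit integral so
a sustained neural amplitude `a` converges to a BOLD plateau `a`, keeping β
in neural amplitude units. The kernel is injectable (`hrf_spec()`), since
the original fits' HRF is not printed. Convolution assumes steady state at
run onset (the series is extended backwards at its initial value), matching
the discarded pre-steady-state frames and making a constant adaptor
response exactly constant.

**The adaptor regressor.** The adaptor display enters the design as a
distinct regressor passed through the *same* response function as the
changing display (the symmetric choice; which function the original fits
used for the adaptor is not stated). In the low and high conditions this
regressor is constant and is absorbed by the baseline — it cannot explain
response variance and is dropped. In the changing condition it is
*identical* to the changing regressor; to keep the GLM full rank the two
are merged into one column of doubled amplitude. This reproduces, as a
tested property, the halving of the fitted slope relative to a
changing-only design; it rescales the proportional-reduction metric's
denominator but cannot affect any test statistic.

## Fitting, cross-validation, classification

The monotonic model is fit by OLS; `R² = 1 − SS_res/SS_tot`. The tuned
model is fit by exhaustive search: for each candidate the non-negative
amplitude and free baseline are solved in closed form, and the candidate
with minimal SSE wins, ties breaking deterministically to the lowest
preference, then the lowest width. Because every candidate's prediction is
a fixed HRF-convolved level basis (8 columns) times the candidate's
per-level amplitudes, the whole ~194 000-candidate search reduces to two
small matrix products per voxel (`tuned_grid_context()` caches the shared
state), and the grid fit matches brute-force enumeration exactly on test
grids.

Voxels are classified on the changing condition: runs are split odd/even by
acquisition order and averaged per half; both models are fit on each half
and evaluated on the complementary half with a free **non-negative**
amplitude rescale and a free baseline (halves may come from different
sessions with arbitrary signal scaling, but a prediction may not flip
sign). The re-fit baseline is a documented choice — the alternative of
freezing it is a one-line switch in `ols_rescale_sse()`. Summed cross-fold
SSE decides the winner (ties go to the simpler monotonic model), and
`cv_R² = 1 − ΣSSE/ΣSS_tot` across both folds, a definition the package
fixes since none is printed elsewhere. Tuned winners whose preferred
numerosity exceeds 7 are reclassified monotonic — preferences above the
mapped range cannot be distinguished from monotonic responses — and tuned
voxels below 0.2 changing-condition R² are excluded from tuned-response
analyses (monotonic analyses use the 0.1 threshold at selection).

**Width identifiability.** At zero noise the grid search always recovers
the preference within one grid step, and recovers candidates drawn from the
grid itself exactly. For off-grid truths the width is recovered within one
to two steps while `p + 2w ≤ log 20`; beyond that boundary (the same
geometry as the candidate exclusion rule) the SSE valley is nearly flat in
width, quantisation in preference couples into the width axis, and only fit
equivalence (R² ≈ 1), not parameter distance, is guaranteed. This is a
property of an 8-level design, not of the search.

## Adaptation metrics and group statistics

Selection keeps voxels with (1) preferred eccentricity below 1° — their
spatial pRF covers the stimulus; (2) positive slope in the control
condition, read as the changing-adaptor condition; (3) changing-condition
monotonic R² ≥ 0.1 (the plain within-condition R² by default; the
cross-validated value is a switch). Selected voxels are averaged,
unweighted, into map examples (participant × hemisphere × map); examples
with mean R² < 0.1 in both the low and high conditions are excluded. The
adaptation strength is `(β_low − β_high) / β_changing`, invariant to any
global gain and therefore comparable between maps with different absolute
response amplitudes; it is undefined (and the example dropped, with a
warning) when the control slope is not positive.

Inference: per map, one-sample signed-rank tests of the low and high slopes
against zero and the paired low-vs-high test, each family BH-FDR-corrected
across all maps. The signed-rank null is computed exactly for n ≤ 25 by
dynamic programming over doubled average ranks — exact under ties, matching
full sign-flip enumeration — with the tie- and continuity-corrected normal
approximation beyond. The map effect on proportional reductions uses a
two-factor ANOVA with participant as an additive blocking factor (with one
observation per map × hemisphere the additive two-way model is the standard
realisation of "participant as random factor"; the divergence is confined
to `map_effect_anova()`), followed by Tukey HSD. Cross-region relationships
use pairwise-complete Pearson correlations with an Anderson–Darling
normality check on the regression residuals. Summaries of tuned-response
adaptation (the low-minus-high drop in tuned R², and the slope of
preference change against baseline preference) are computed by
`tuned_effect_summary()` for the same correlation machinery.

## Behavioural validation

The simulated observer answers "test more numerous than the 10-dot
reference" with probability `Φ((test − PSE)/σ)`. Test levels follow a
greedy minimum-expected-posterior-entropy rule over a discrete (μ, σ)
lattice — an idealisation of a Minimum Expected Entropy staircase, whose
exact hyperparameters are not public — or a fixed grid; unanswered trials
are re-queued. PSEs are estimated by Bernoulli maximum likelihood, computed
as probit regression, with a bounded direct optimisation fallback under
complete separation (flagged); least squares on binned proportions, the
classical descriptive fit, is provided and agrees with ML on large samples.
No lapse-rate parameter is modelled (none is specified); adding one is a
config extension. Condition comparisons check paired-difference normality
(Shapiro–Wilk), then run paired t-tests with Bonferroni correction for the
three pairs. The trial count is 100 answered trials per condition per
participant — the protocol's "100 trials" is ambiguous between total and
per condition, and the per-condition reading gives each PSE a stable fit;
it is a config parameter, not a claim about the original experiment.

## The synthetic generator

`generate_voxel_dataset()` emulates exactly the structure the analysis
assumes: monotonic voxels whose amplitude scales with log aggregate power
under condition gains g_low > g_high (defaults g_changing = 1,
g_low = 1.1); a linear V1→V3A/B gradient of true proportional reduction
(default 0.25 to 0.85 in steps of 0.10); a 20% tuned minority in LO1, LO2
and V3A/B with preferences within 1–7, widths 0.4–1, condition-dependent
amplitudes and a linear preference-shift pattern; eccentricities up to 1.5°
and a 5% negative-slope fraction so the selection criteria are exercised;
and white (optionally AR(1)) noise per run, by default 10% of each voxel's
noiseless changing-condition signal SD — after averaging 3 runs per
condition this leaves single-voxel fits at R² ≈ 0.97–0.99, a deliberately
clean regime appropriate for validating recovery. The changing condition's
noiseless response includes the adaptor display's contribution, so the
doubled-regressor accounting is exercised end to end.

What it does **not** emulate: spatial structure on a cortical surface,
physiological (cardiac/respiratory) noise, scanner drift, within-session
amplitude drifts between odd and even runs, HRF variability across voxels,
and partial-volume mixtures of tuned and monotonic populations. Passing
tests therefore demonstrate that the pipeline recovers what it assumes, at
realistic noise — not that real scans satisfy those assumptions.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 8 participants × 2
hemispheres × 7 maps × 8 voxels (896 voxels, three conditions, 3 runs
each), 100-voxel zero-noise recovery suites, 200-replicate behavioural
simulations, and ≥ 20 display seeds per numerosity for the power table —
sizes chosen so the full battery runs in minutes on one CPU while leaving
every recovery margin wide. All generators are pure functions of
(parameters, seed); pipeline artifacts carry a provenance header with the
package version, stage, seed and configuration hash, and re-running a stage
with the same configuration reproduces its outputs byte for byte.

## Known limitations

Sub-TR dynamics and nonlinear BOLD accumulation are not modelled — the
merged changing-condition regressor is an explicitly linear idealisation.
The tuned grid's width axis is weakly identified for broad tunings
preferring high numerosities (see above). The ANOVA treats participant as a
fixed blocking factor. The behavioural staircase is an idealised
entropy-minimising rule, not a reimplementation of any specific toolbox.
Real-data ingestion (delimited or NIfTI time series plus metadata) is
supported structurally but the package's validation is entirely synthetic.
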