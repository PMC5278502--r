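---
title: "Methods: single-cell circadian fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell circadian fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaquant)
```

# The measurement problem

Fluorescent clock reporters read out the state of the molecular circadian
clock in individual pacemaker neurons. Two regimes of data arise. Long
recordings of cultured brain explants (one frame per 3 h for at least
48 h) carry one-to-two cycles of a rhythm whose period runs near 29 h,
with amplitude damping over days in culture, slow baseline drift, and
substantial frame-to-frame noise. Short pharmacology recordings (one
frame per hour for 8 h, with a drug added about 1 h in) are too short to
carry any circadian cycle at all; there the question is not periodicity
but whether a treatment shifts the intensity time course of specific
neuron classes at a specific time of day.

`circaquant` implements the estimators for both regimes, together with the
upstream image quantification and a synthetic-data layer that generates
every input with known ground truth.

# Image quantification

Two schemes mirror the two kinds of preparations.

For brain explants, analysis happens on a **SUM projection** of the z-stack
(`sum_project()`, exact intensity conservation). Cell ROIs are 2D regions
on that projection; each cell's measure is its ROI mean minus the mean of
the mean intensities of exactly **three background regions** nearby
(`corrected_intensity()`). The background enters as a mean of means — not
pooled pixels — so unequal background-region sizes carry equal weight.
Negative corrected values are retained and flagged rather than clipped;
clipping would bias rhythm amplitudes upward at the trough. The corrected
measure is deliberately an ROI *mean*: the downstream analysis uses only
relative (fold-change) quantities, for which mean and area-integrated
measures differ by a constant factor per cell. An area-scaled variant is a
one-line change at the single place the formula lives.

For dissociated neurons, quantification is volumetric: the background is
subtracted voxelwise (floored at zero), voxels above a threshold form
**26-connected 3D components** (`mask_intensity_sum()`), and each
component's summed intensity is the cell's measure. 26-connectivity is the
natural choice for compact somata; component labelling is breadth-first on
the padded volume.

# Trace preparation

Each cell's series is divided by its value at the first acquired frame
(`normalize_to_start()`), so every trace starts at exactly 1 and values
read as fold-change from the start of imaging. The first frame is t = 0
regardless of the Zeitgeber time at which imaging began; no further
baseline correction or detrending is applied. Cells whose first value is
not positive cannot be normalized and are excluded with a logged reason.
Heatmap matrices (`build_heatmap()`) order rows by the maximum normalized
intensity over the first 24 h (a configurable window), descending, with
ties broken by cell id, and can flag values above a display ceiling.

# Period estimation by MESA

Maximum entropy spectral analysis models the mean-centred series as an
AR(p) process and reads the period from the model's power spectrum. The
AR fit uses **Burg's lattice recursion**, which minimizes the combined
forward and backward prediction error order-by-order and guarantees
reflection coefficients in [-1, 1], hence a stable model and a strictly
positive spectrum. No detrending, smoothing or filtering is applied at any
stage — mean-centring only.

Two estimator choices deserve emphasis:

- **Error taper.** Plain Burg shows a phase-dependent bias in the
  estimated frequency of a sinusoid when the record holds only a few
  cycles — exactly this data regime. On noise-free 17-point damped
  cosines the plain-Burg period error already reaches ±1 h depending on
  phase, and under realistic noise only ~55% of estimates land within
  ±1.5 h of truth. Weighting the stage-wise error sums with the parabolic
  (Kaveh–Lippert) window removes most of this bias (>90% within ±1.5 h
  under the same conditions) while preserving the lattice recursion and
  its stability guarantee, since the weighted update is still a weighted
  Cauchy–Schwarz ratio. The taper is the default; `taper = "none"` gives
  the classical recursion.
- **AR order.** The default order is floor(n/3), capped at 20 — for a
  17-point explant trace, order 5: enough poles for one oscillatory pair,
  a trend pole and noise, while keeping estimation variance tolerable.
  Minimum-AIC selection (`order_rule = "aic"`) and fixed orders are
  available.

The spectrum is evaluated on 2048 frequencies over (0, Nyquist]. The
dominant period is the highest *local maximum* of power whose period falls
in the 18–36 h band (endpoints inclusive), refined by parabolic
interpolation of log-power across the three surrounding grid points so
that period precision does not depend on grid density; exact power ties
resolve to the longer period. A monotone spectrum — as produced by pure
drift, whose power concentrates at frequencies below the band — has no
in-band local maximum and yields no period. Under the generators' noise
levels, about 5–10% of pure-drift traces still show a weak noise-driven
in-band peak; the final circadian verdict tolerates this because the trend
criterion must also fire (below).

The estimate is invariant to positive affine transforms of the series, so
raw and normalized traces give identical periods; the package follows the
convention of running MESA on raw intensities.

# The trend criterion and the dual-criterion verdict

The second criterion codifies trend-line-assisted visual screening as a
reproducible procedure. A **degree-6 polynomial** is fitted by ordinary
least squares on an abscissa rescaled to [-1, 1] for conditioning
(degree 6 accommodates the up-to-five interior extrema a two-cycle window
can show). Peaks are the polynomial's interior maxima, located by
root-finding on its exact derivative — never by argmax on a display grid —
and only maxima strictly inside the observed window count, because an
interval to an unobserved peak cannot be measured. The criterion fires
when **at least one** consecutive-peak interval lies in 18–36 h
(inclusive); requiring all intervals in-band is stricter than a visual
screen and would fail traces with one spurious shoulder peak.

A cell is **circadian only when both criteria agree**
(`classify_cell()`). The trend stage contributes a boolean only; the
reported period is always the MESA period. Cohort summaries
(`summarize_cohort()`) report, per neuron class, the detected count
(cells passing QC), the rhythmic fraction, and mean ± SEM (sample
sd / sqrt(n)) of the periods of the rhythmic cells, with periods rounded
to two decimals.

# Drug-response statistics

Each neuron class is analysed as one panel: a two-way fixed-effects ANOVA
with treatment and timepoint as crossed factors on the normalized
intensities, using Type-III (marginal) sums of squares so unbalanced cell
counts are handled; on balanced data this equals the textbook mean-square
ratio. Cells are the unit of observation and their repeated measurements
across timepoints are treated as independent — the convention this
pipeline reproduces; a consequence, verified in simulation, is that the
*omnibus* treatment F-test is anti-conservative when per-cell normalization
induces within-cell correlation, while the per-timepoint contrasts below
remain essentially calibrated because their error variance matches the
pooled mean square.

Treatment groups are then compared against the vehicle group at every
timepoint with t statistics built on the pooled error mean square, and
p-values are Sidak-corrected, `1 - (1 - p)^m`. The family defaults to all
(groups − 1) × timepoints comparisons of a class panel — the reading that
matches per-panel asterisk annotations — and is switchable to
per-timepoint families. Tiers follow the `*`/`**`/`***`/`****` convention
at 0.05/0.01/0.001/0.0001.

# The synthetic-data layer

The generators define the study conditions under which the estimators are
validated; their defaults are fixed, documented values, not tuning knobs.

**Traces** follow `I(t) = [M + A e^(-λt) cos(2π(t-φ)/T)](1 + δt) + ε`,
truncated at zero — the minimal form exhibiting every phenomenon the
pipeline must handle (mesor, damping, multiplicative drift, additive
noise). Defaults: mesor 100 AU, amplitude 50 AU, noise sd 10 AU (so
amplitude/noise — the working SNR definition — is 5), period 29 h,
damping 0.005/h, drift 0.002/h, 3-h sampling over 48 h. The phase draw
for explant-like cohorts is uniform on 2–8 h after recording onset:
explant imaging conventionally starts near the reporter's expression
peak, so cells crest early in the window — which is also the only regime
in which a 48-h window shows the two interior peaks a measurable
peak-to-peak interval needs. Non-rhythmic cells have amplitude 0 and a
stronger positive drift (0.005–0.02/h), emulating the steady rhythm-free
increase characteristic of dissociated neurons. Real traces additionally
show photobleaching nonlinearity, movement artefacts and non-Gaussian
noise which the generator does not emulate; passing tests therefore
demonstrate correctness of the estimators under the stated model, not
performance guarantees on arbitrary real data.

**Cohorts** assign class labels (default LNv:DN1:DN2 = 11:15:8) and
rhythmic status deterministically (largest-remainder counts, stratified
across classes), so ground-truth composition is exact by construction.

**Drug-response experiments** generate flat-plus-noise baselines with a
multiplicative step or ramp effect from the onset time in the affected
(group, class) strata. Effects are multiplicative because the analysis
operates on fold-change. Group labels compose with `+`; a group containing
a blocking co-treatment (e.g. `PDF+TTX` when TTX blocks) stays at
baseline, and unaffected strata are exchangeable with vehicle.

**Image stacks** place cells as solid spheres (radius r, uniform peak)
with a Gaussian rim (sd 1 voxel) over a background with optional gradient
and noise. A filled soma with a soft optical edge keeps ~97% of a cell's
integrated intensity above a 10%-of-peak threshold, so 3D-mask sums can be
scored against the full analytic integral; a pure Gaussian blob would
hold only ~80% of its mass above that contour and could never meet a 5%
recovery contract. Per-cell integrated intensities at every timepoint are
emitted as ground truth, and potentially overlapping cells are flagged.

All generators are bitwise-reproducible for a fixed seed.

# Numerical and degenerate-input choices

- Constant series yield a flagged zero-variance AR model and no period.
- Series shorter than 8 points are not analysed (QC reason recorded); an
  8-point hourly pharmacology trace is by construction shorter than the
  18-h band floor and yields no circadian call — a documented limitation,
  not an error.
- Trend coefficients below 1e-9 of the polynomial's largest coefficient
  are treated as numerical noise before derivative root-finding, so
  constant data do not produce phantom peaks.
- The Sidak adjustment is computed on the log scale and clamped to
  `[p_raw, 1]`, making monotonicity exact in floating point.
- Heatmap row ordering uses the window endpoints inclusively.
- Empty 3D masks return a flagged record with sum 0.

# Problem sizes used in validation

The shipped validation (test suite plus `scripts/acceptance.R`) uses 50
clean 96-h sinusoids for the FFT-oracle comparison, 100 explant-like
traces for period recovery, 200 + 200 cells for classifier operating
characteristics, 200 null replicates for the type-I check, and 50
replicates of each pharmacology scenario — sizes at which the Monte-Carlo
error of each rate is a few percent, run in well under a minute of CPU.

# Known limitations

- Irregular sampling is rejected rather than resampled; Lomb–Scargle-type
  estimators are out of scope.
- The ANOVA ignores within-cell repeated-measures correlation (see above);
  a mixed-effects extension is deliberately not provided.
- ROI definition is manual/ground-truth-driven; there is no automated
  segmentation.
- Period estimates from 3-h sampling carry an intrinsic uncertainty of
  order ±1 h even for the tapered estimator; reported cohort SEMs reflect
  between-cell spread, not this estimator floor.
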