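---
title: "Pixel-wise relaxation-time mapping: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-wise relaxation-time mapping: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxmap)
```

## The measurement problem

Signal intensity in a conventional MR image mixes several tissue properties.
To isolate a relaxation time, a series of images is acquired in which only
one timing parameter varies — the inversion time TI for T1, the echo time TE
for T2 and T2\* — and the known signal equation is fitted per pixel. The
result is a parametric map whose pixel value *is* the relaxation time in
milliseconds. `relaxmap` implements this for seven technique variants:
classic inversion recovery (`T1_IR`), Look-Locker (`T1_LL`), MOLLI
(`T1_MOLLI`), and single-/multi-echo T2 and T2\* (`T2_SE`, `T2_ME`,
`T2STAR_SE`, `T2STAR_ME`). All times are milliseconds end to end, matching
the DICOM InversionTime/EchoTime tags and the exported maps.

## Signal models

* Inversion recovery: $S(\mathrm{TI}) = A - B\,e^{-\mathrm{TI}/T_1^*}$.
  $A$ scales the signal; $B$ measures the inversion depth, $B = 2A$ being a
  perfect inversion. The model is fitted to *signed* data.
* Mono-exponential decay: $S(\mathrm{TE}) = A\,e^{-\mathrm{TE}/T_2}$.
* Offset decay (T2\*): $S(\mathrm{TE}) = A\,e^{-\mathrm{TE}/T_2^*} + C$.
  The constant $C$ absorbs the Rician noise floor that magnitude images
  approach at long TE; it measurably improves T2\* accuracy and is on by
  default (`use_offset`).

### Polarity restoration

Magnitude reconstruction stores $|S|$, so every sample acquired before the
zero crossing at $\mathrm{TI}_0 = T_1^* \ln(B/A)$ has lost its sign. The
fitter restores polarity by a cyclic search: candidate $n$ negates the $n$
lowest-TI samples, $n$ running from 0 (no flips — data acquired entirely
past the null are legitimate) to the number of images with
$\mathrm{TI} < 0.67 \times \text{limit}$. Each candidate gets a full
three-parameter Levenberg–Marquardt fit; the lowest Chi (unweighted sum of
squared residuals) wins, ties going to the smallest $n$ so the least-modified
interpretation of the data is preferred. The search transforms the *data*
and fits the signed model, rather than fitting a folded $|model|$; the two
differ only in the implausible case of a sample sitting exactly on the null.
The `0.67 × limit` cutoff keeps candidates for which a sign flip could be
physically justified given the user's relaxation-time limit, and makes the
computing cost scale with that limit.

Chi is deliberately the plain sum of squared residuals: magnitude noise is
homoscedastic away from zero, and for a fixed number of samples any constant
rescaling (e.g. to reduced chi-square) leaves the candidate ranking
unchanged.

### Look-Locker / MOLLI correction

Repeated readouts along one recovery deflect the curve, so the fitted
constant is an apparent $T_1^*$. The map stores the corrected
$T_1 = T_1^{*}\,(B/A - 1)$, computed from the two remaining fit parameters.
At perfect inversion the correction is the identity; fits with $B \le A$
have no zero crossing, cannot be corrected, and are routed to the same
zero-valued channel as non-converged fits.

## The mapping pipeline and its parameters

`compute_map()` validates the source set (image count vs free parameters,
common field-of-view, presence and distinctness of timing values, layout vs
technique), applies optional rigid shifts, sorts by TI/TE, and fits every
gated pixel in row-major order (results are order-independent by
construction; fitting is deterministic).

* `limit_ms` — the maximum relaxation time. Bounds the polarity search and
  the output range: fitted times above it are *clipped* to the limit rather
  than zeroed, so saturated-but-real signal stays visible and the export
  range stays bounded. 3000 ms is a sensible T1 limit at 1.5 T, 500 ms a
  generous T2/T2\* limit.
* `noise_level` — intensity units. A pixel is fitted iff *any* source image
  exceeds this intensity there (not the mean: a pixel bright in even one
  image carries signal). Level 0 keeps all of the air background — which
  then yields speckled nonsense values where noise-only fits happen to
  converge — while a level a few noise standard deviations up blanks air
  exactly. Raising the level only ever removes pixels.
* `region` — optional `c(row0, col0, n_rows, n_cols)` rectangle (1-based,
  inclusive, R convention) confining the computation; outside pixels are 0.
  The restricted map equals the full map on the region, exactly.
* Zero is the single invalid-pixel encoding: below noise, outside region,
  optimizer failure, non-finite or non-positive fitted time, or
  non-physical correction. Zero regions read as signal dropout.

### Numerical choices

Initialization: $A_0 = \max|S|$, $B_0 = 2A_0$,
$T^*_{1,0} = \mathrm{TI}_{\arg\min|S|}/\ln 2$ clamped to
$[1, \text{limit}]$ (the minimum-magnitude sample approximates the null).
For decay fits, a log-linear regression on the positive samples seeds $A_0$
and the decay constant — for the offset model the regression runs on
$S - C_0$ with $C_0 = \min S$, since regressing raw data that include an
offset systematically flattens the slope. Convergence: at most 200 LM
iterations, relative parameter tolerance $10^{-8}$; analytic Jacobians are
supplied for every model (the tests verify them against central finite
differences, and the LM fits against an independent Nelder–Mead optimizer).
Any optimizer failure or non-finite/non-positive outcome marks the pixel
non-converged.

## Registration

Motion between source images is corrected by per-image integer-pixel
translations (`shift_spec()`, text files with `index dx dy` lines; +dx
right, +dy down). There is no interpolation — displacement is by whole
pixels only — and vacated borders are filled with 0 so they self-exclude
via the noise gate. Rotation, sub-pixel and non-rigid registration are out
of scope. `register_preview()` writes shifted PNGs with a checkerboard
overlay for visual checking.

## DICOM handling

The reader/writer supports uncompressed Part-10 files, explicit VR little
endian on write and explicit/implicit little endian on read, with the tag
set quantitative mapping needs. Timing comes from InversionTime (0018,0082),
falling back to TriggerTime (0018,1060) with a warning — vendor MOLLI
exports differ — then EchoTime (0018,0081). Layout (one multi-image series
vs many single-image series) is inferred from SeriesInstanceUID values.
Exported maps are derived MR image objects (readable by ordinary viewers,
unlike newer parametric-map objects): 16-bit unsigned pixels, 1 LSB = 1 ms,
rescale slope 1/intercept 0, nearest-integer rounding, fresh UIDs, spatial
tags copied from the source. This encoding is a documented convention of
this package; limits above 65535 ms are rejected rather than silently
rescaled. Graphics exports (8-bit PNG, 16-bit TIFF) quantize the 0–limit
range and are for illustration only.

## The phantom simulator

`phantom_spec()` emulates the standardized accuracy experiment of gel-phantom
relaxometry: non-overlapping disk/rectangle compartments with known T1, T2
and proton density on an air background, imaged as 8 magnitude images of
128×128 pixels — TI 100–1400 ms for the inversion-recovery family, TE
20–160 ms for the decay family — with seeded Rician noise
($\sqrt{(S+n_1)^2+n_2^2}$, $n_i \sim N(0,\sigma)$), the distribution of
magnitude-reconstructed complex Gaussian noise: Rayleigh in air,
near-Gaussian at high SNR, and the very reason polarity restoration exists.
The default $\sigma = 20$ is 2% of the default proton density (SNR 50).

Design choices worth spelling out:

* **Look-Locker emulation is phenomenological.** The apparent constant is
  $T_1^* = f\,T_1$ with `t1star_factor` $f = 0.8$; readout physics is not
  simulated (the fit only ever sees the three-parameter curve). Consistency
  of the correction then *forces* $B/A = 1/f + 1$, and the generator rejects
  any contradictory `inversion_quality`, which turns parameter recovery into
  a closed loop: corrected map = true T1, exactly, in the noiseless limit.
* **Preset T1 values {225, 275, 325, 550} ms** (Gd-doped agarose range).
  They are chosen by an explicit conditioning rule: no compartment's null
  crossing — under either the classic-IR or the MOLLI variant — may fall
  within several noise standard deviations of a sampled TI of the 100–1400 ms
  protocol. A magnitude sample near the null measures the Rician floor, not
  the signal, which corrupts ROI-averaged reference fitting regardless of
  the mapping software; with this grid the minimum margin is ≈7.6σ at SNR 50.
* **Preset T2 values {40, 60, 80, 100} ms with TE 20–160 ms**, spanning
  1.6–4 time constants: enough decay for the three-parameter offset fit to
  separate the tail from the baseline (`offset_c` = 40 added to compartment
  pixels in T2\* sets).
* Seeded runs are bit-for-bit reproducible, including generated UIDs; with
  $\sigma = 0$ the output is independent of the seed.

## What the tests show — and what they cannot

The simulator exercises every code path the scanner data would: magnitude
folding, noise gating, layout/timing validation, DICOM round trips. It does
**not** emulate partial-volume borders, susceptibility artifacts at phantom
edges, B0/B1 inhomogeneity, imperfect inversion profiles, cardiac-gating
jitter, or vendor DICOM quirks beyond the timing-tag fallback — passing
tests say nothing about those.

Noiseless phantoms round-trip all seven techniques below $10^{-3}$ relative
error (machine precision in memory; integer DICOM quantization dominates on
disk). At SNR 50 the package's accuracy study compares, per compartment ROI,
the map's ROI mean (zeros excluded) with an independent fit of the
ROI-averaged signal. A known limitation shows up here: per-pixel nonlinear
least squares is slightly biased in noise (a Jensen effect — the estimator
is convex in the data near the solution), so the mean of many noisy
per-pixel estimates sits above a single fit of the averaged, nearly
noise-free curve. The effect grows where the protocol barely constrains a
parameter — slow T2\* decays relative to the echo train, long T1 relative
to the TI range — and shrinks quadratically with SNR. `scripts/acceptance.R`
computes exactly this comparison; at SNR 50 the multi-echo T2\* compartments
with $\mathrm{TE}_{max}/T_2^* < 2$ exceed 1 ms of difference while MOLLI and
T2 stay well below it. This is a property of pixel-wise LM estimation
itself, not of any particular implementation, and should be kept in mind
when ROI statistics from noisy maps are compared against curve fits of
ROI-averaged data.

Problem sizes: full-resolution (128×128, 8 time points) phantoms are used
for the noiseless recovery and ROI-agreement studies; 32×32 phantoms, which
exercise identical code paths, back the remaining unit and property tests.
The polarity-search oracle check runs 1000 randomized trials against
exhaustive enumeration of the leading-negatives family.

## Known limitations

* Variable flip-angle T1 mapping, biexponential/multi-compartment models and
  Bloch-level simulation are out of scope.
* Registration is rigid, integer-pixel, translation-only.
* The DICOM codec intentionally covers only uncompressed little-endian
  single-frame monochrome images.
* Maps encode milliseconds as integers on export; sub-millisecond detail
  survives only in memory or via `tidy()`.
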