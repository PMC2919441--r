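# relaxmap

Pixel-wise T1, T2 and T2\* relaxation-time mapping from magnitude MR images,
in R.

## The problem

T1 (spin–lattice), T2 (spin–spin) and T2\* relaxation times are quantitative
tissue properties, but no single MR image measures them directly: a set of
source images must be acquired with varying inversion time (TI) or echo time
(TE), and the relaxation time extracted pixel by pixel by nonlinear curve
fitting. `relaxmap` automates this for the common acquisition families —
classic multi-image inversion recovery, Look-Locker/TOMROP, MOLLI, and
single-/multi-echo decay sequences — reading DICOM source series, fitting
every pixel, and exporting quantitative maps whose pixel values are
milliseconds. It is aimed at researchers in quantitative tissue
characterization (myocardial T1 mapping, iron quantification by T2\*,
relaxometry method development) who need a transparent, scriptable,
vendor-independent pipeline.

## Models and algorithm

All fits are per-pixel Levenberg–Marquardt least squares (via
[minpack.lm](https://cran.r-project.org/package=minpack.lm)) with analytic
Jacobians:

* **Inversion recovery** (three parameters):
  S(TI) = A − B·exp(−TI/T1\*), with A the signal scale and B the inversion
  depth (B = 2A is a perfect inversion). Magnitude reconstruction discards
  the sign of S, so the fitter runs a cyclic **polarity search**: the signs
  of an increasing number of leading (lowest-TI) images are switched to
  negative — up to the last image with TI < 0.67 × limit — and the sign
  pattern with the lowest Chi (sum of squared residuals) wins.
* **Look-Locker / MOLLI correction**: repeated readouts deflect the recovery,
  so the fitted constant is an apparent T1\*; the map stores
  T1 = T1\*·(B/A − 1), which is exact at perfect inversion.
* **Decay** (two parameters): S(TE) = A·exp(−TE/T2).
* **T2\* with offset** (three parameters): S(TE) = A·exp(−TE/T2\*) + C, the
  constant C absorbing the noise floor at long echo times.

Pixels are fitted only where at least one source image exceeds the
user-defined noise level; non-converged or non-physical fits are assigned
exactly 0 ms, so poor-quality regions appear as signal dropout. Fitted times
above the user limit are clipped to it. Rigid per-image integer-pixel shifts
correct motion misregistration before fitting.

A synthetic multi-compartment gel-phantom simulator (`phantom_spec()`,
`simulate_series()`) with Rician noise generates ground-truth DICOM series
for every supported technique, making the whole pipeline testable end to end.

## Worked example

Simulate a noisy MOLLI phantom series (SNR 50), write it as DICOM, read it
back and map it:

```r
library(relaxmap)

spec  <- phantom_spec(noise_sigma = 20, seed = 7)       # 4 gel compartments
set   <- simulate_series(spec, "T1_MOLLI", out_dir = "molli_demo")
stack <- read_series(attr(set, "paths"))
map   <- compute_map(stack, mapping_config("T1_MOLLI",
                                           limit_ms = 3000,
                                           noise_level = 100))
map
#> <relaxation_map> T1_MOLLI, 128x128, limit 3000 ms
#>   fitted pixels: 5024 / 5029 masked; zeroed: 11360
#>   nonzero values [ms]: median 305.6 (5-95%: 219.9-557.1)
```

The masked pixels are the phantom compartments (air is gated out by the
noise level of 100); the median of 306 ms sits between the compartments'
true T1 values. ROI means recover the ground truth to a fraction of a
percent:

```r
for (k in 1:4)
  cat(sprintf("compartment %d: true T1 %4.0f ms, ROI mean %6.1f ms\n",
              k, spec$compartments$t1_ms[k],
              mean(map$values[phantom_roi(spec, k)])))
#> compartment 1: true T1  225 ms, ROI mean  223.8 ms
#> compartment 2: true T1  275 ms, ROI mean  275.1 ms
#> compartment 3: true T1  325 ms, ROI mean  325.0 ms
#> compartment 4: true T1  550 ms, ROI mean  550.4 ms
```

Single-pixel diagnostics show the polarity restoration and the corrected T1
(T1\* 175.7 ms → 222.4 ms after the Look-Locker correction):

```r
pixel_curve_report(stack, mapping_config("T1_MOLLI", 3000, 100), 32, 32)
#> <pixel_report> (32, 32), T1_MOLLI
#>   relaxation time: 222.41 ms   chi: 1472   flipped signs: 1
#>   params: A=999.5  B=2265  T1star=175.7
```

`autoplot(map)` renders the map; `tidy(map)` / `glance(map)` give per-pixel
and one-row summaries; `export_map_dicom()` writes a 16-bit DICOM whose
stored values are milliseconds (losslessly re-readable), and
`export_map_graphic()` writes PNG/TIFF for illustration. `dump_headers()`
tabulates DICOM headers across images and series for protocol inspection.

A command-line wrapper with `simulate`, `map`, `inspect-pixel`, `headers`,
`register-preview` and `export-png` subcommands is installed at
`system.file("cli", "relaxmap", package = "relaxmap")`.

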