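# batlas

Three-dimensional tracking of echolocating bats from microphone-array
recordings, fused with terrestrial-laser-scan (TLS) vegetation structure.

`batlas` is for movement ecologists and bioacousticians who record bats
with a rigid eight-microphone array and want, in one coordinate frame:
the 3D position of every localisable call, per-position uncertainty,
flight tracks, and each position's distance to the surrounding vegetation
and to landmarks such as a lamppost.

## What it computes

A call arriving at the array yields seven **time-of-arrival differences**
(TOADs) against the reference (top) microphone, estimated by band-limited
cross-correlation with sub-sample peak interpolation:

τᵢ = t(micᵢ) − t(ref)

The source position x̂ minimises the misfit to the spherical-spreading
model

τᵢ(x) = (‖x − mᵢ‖ − ‖x − m_ref‖) / c

solved by multi-start damped least squares (Levenberg–Marquardt). Because
the array is **overdetermined** (8 microphones where 4 suffice), the TOAD
residuals yield localisation error estimates via the linearised
covariance C = s²(JᵀJ)⁻¹, split into a **radial** component (along the
array-to-position line) and a **tangential** component (perpendicular
plane), plus the worst per-microphone misfit as a distance
(c·max|τ_obs − τ_model|). Standard quality rules then apply: positions
within 2 m of the array are dropped, as is any position with either error
component above 0.5 m.

On the vegetation side, TLS clouds are filtered (pulse deviation > 15
removed), voxelised into 0.20 m cubes, and cells with ≥ 10 points become
**vegetation voxels**. A rigid-body transform (Kabsch/orthogonal
Procrustes, reflections excluded) fitted to the array's five frame
reference points — visible in both datasets — maps acoustic positions into
the scan frame, where nearest-vegetation and lamppost distances,
Welch-t and Kolmogorov–Smirnov group comparisons, and track/activity
metrics are computed.

A seeded synthetic-scene simulator (flight paths, FM calls with exact
fractional-sample delays, 1/r spreading, hard trunk occlusion, vegetation
clouds) exercises every stage end to end against known ground truth —
including the acoustic shadows trunks cast, which real deployments use as
a visual check of the acoustic–LiDAR alignment.

## Worked example

```r
library(batlas)
arr <- default_array()
arr
#> Microphone array: 8 microphones, aperture 2 m
#> Reference microphone: 5 (z = 1.00 m)
#> Frame reference points: 5

# localise one call from its TOADs (here: simulated for a source at
# (5, 3, 2) m with 2 microsecond timing noise)
fit <- localise(toads, arr)
as.data.frame(fit)
#>   time    x    y    z radial_error tangential_error max_toad_error residual_rms n_mics valid
#> 1   NA 5.01 3.01 2.01        0.063          0.00384        0.00106     1.73e-06      8  TRUE
```

The position is recovered to ~1 cm; the radial error (6.3 cm) dominates
the tangential one, as expected for a source ~6 m out at 3x the array
aperture — range is always the weakly constrained direction.

A full synthetic corridor study, from waveform synthesis to statistics:

```r
res <- run_end_to_end("corridor", run_config(duration = 6, seed = 1L))
res
#> End-to-end pipeline result
#>   emitted calls: 48, scorable: 48, localised within 0.3 m: 48 (recall 100.0%)
#>   mean position error: 0.005 m; filtered positions: 48; tracks: 1
#>   registration RMSD: 0.0005 m; vegetation voxels: 6548
#>   mean distance to vegetation: recovered 3.27 m, truth 3.27 m

head(res$distances, 3)
#>      time dist_vegetation dist_lamppost label
#> 1 0.00233            4.20          19.0  wide
#> 2 0.12746            4.05          18.4  wide
#> 3 0.25246            3.95          17.8  wide
```

All 48 emitted calls are detected, localised within millimetres of the
simulator's ground truth, registered into the scan frame (sub-millimetre
alignment RMSD over the five reference markers), and measured against
6548 vegetation voxels; the recovered mean distance-to-vegetation matches
the ground-truth value.

There is also a thin shell front door over the same functions:

```sh
Rscript inst/cli/batlas simulate --scenario corridor --out demo/
Rscript inst/cli/batlas localise --wav demo/recording.wav --array demo/array_geometry.csv --out demo/
Rscript inst/cli/batlas pipeline --scenario circling --out run1/
```

## Package layout

- `R/` — array geometry & WAV I/O, detection, TOAD estimation,
  multilateration & error assessment, position filtering & tracks, point
  clouds & voxels, rigid registration, distances & statistics, the scene
  simulator, pipeline, configuration, CLI dispatcher.
- `tests/testthat/` — unit and property tests per stage plus end-to-end
  acceptance checks.
- `vignettes/bat-flight-tracking.Rmd` — the methods vignette: model,
  assumptions, parameter choices, simulator scope, limitations.
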