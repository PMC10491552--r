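# us3dqa

Phantom-based image-quality analysis for 3D ultrasound, comparing two ways
of turning a 2D sweep into a volume:

* **Motorized acquisition (MA)** — the probe rides a stepper-motor rail in
  the elevation direction and the frames are stacked into a volume with no
  interpolation (the elevation voxel size *is* the step size).
* **Freehand acquisition (FA)** — a hand-held, electromagnetically tracked
  probe sweeps the target; hand tremor and tracking noise enter the data,
  and the volume is rebuilt by pixel-nearest-neighbour (PNN) gridding with
  maximum-value compounding and hole filling.

The question this tooling answers is the one a surgical-imaging group asks
before adopting 3D ultrasound for intra-operative *ex vivo* margin
assessment: which acquisition mode gives the more trustworthy volume, and
by how much, measured on a calibration phantom rather than by eye.

The package simulates a CIRS-style multi-purpose grayscale phantom
(contrast cylinders at −9/−6/−3/+3/+6 dB, a 0.1-mm wire, distance filaments
at 10-mm spacing spanning 30 mm axially and 50 mm in elevation, a gently
curved surface under a 10-mm water standoff), acquires it with either
pipeline, and measures five quality metrics:

* **Contrast resolution** — slope of the OLS fit of mean cylinder gray on
  nominal dB level (gray value/dB).
* **Axial / elevation resolution** — full width at half maximum (FWHM) of
  the −6 dB line profile through the wire at 1-cm depth:
  for a Gaussian beam, FWHM = 2√(2 ln 2) σ.
* **Axial / elevation distance calibration** — Distance error =
  |D<sub>a</sub> − D<sub>m</sub>|, the absolute difference between the
  nominal filament span (30 mm axial, 50 mm elevation) and the measured
  peak-to-peak separation.
* **Stability** — segment the phantom surface in the mid-lateral plane
  (threshold 100), take the baseline-to-surface distance f(x) over the
  central 25% of elevation columns, and report
  RMS = √(mean(Df²)) together with min(Df) and max(Df), converted to mm by
  the axial pixel spacing. This is a quantitative tremor measure.

Comparison statistics mirror an acquisition-protocol study: per-method
mean ± SD tables, paired t-tests (stepwise vs continuous, compounding
on/off), Welch's t between methods, and inter-operator agreement by a
two-way random-effects absolute-agreement single-measure ICC(2,1) computed
from the ANOVA mean squares.

## Worked example

Simulate a motorized stepwise sweep of the default phantom and measure all
five metrics:

```r
library(us3dqa)

ph   <- default_phantom()
geom <- image_geometry()          # 4.3 cm depth window, 0.12 mm pixels
beam <- beam_profile()            # FWHM: 0.33 / 0.40 / 1.02 mm
cfg  <- acquisition_config("motorized", "stepwise", step_size_mm = 0.5,
                           sweep_length_mm = 60)

acq <- acquire(ph, cfg, beam, geom, seed = 1)
vol <- stack_volume(acq$frames, step_size_mm = 0.5)
vol
#> <us_volume> 358 x 333 x 121 (axial x lateral x elevation), spacing 0.12 x 0.12 x 0.5 mm, method stack

run_qa(vol, ph, movement = "stepwise", step_size_mm = 0.5, operator = "A")
#> contrast_resolution     6.2999
#> resolution_axial_mm     0.3441
#> resolution_elevation_mm 1.0841
#> dist_cal_axial_mm       0.0000
#> dist_cal_elevation_mm   0.0000
#> stability_rms_mm        0.0189
```

Reading the row: the contrast slope recovers the generator's 6.3 gray/dB
map; the measured resolutions sit at the configured beam widths (elevation
slightly above 1.02 mm because a 0.5-mm step undersamples the beam); the
distance errors are zero because no miscalibration was injected; and an
ideal rail sweep leaves only the gentle surface curvature in the stability
statistic (0.02 mm RMS — a tremor-affected freehand sweep is roughly an
order of magnitude larger).

The freehand side of the comparison:

```r
cfg_fa <- acquisition_config("freehand", velocity = 2, sweep_length_mm = 60)
fa  <- acquire(ph, cfg_fa, beam, geom, tremor = operator_tremor("A"),
               noise = tracking_noise(), seed = 2)
trk <- apply_temporal_offset(fa$tracking, -30)   # or temporal_offset(...)
vol_fa <- pnn_reconstruct(fa$frames, trk, pnn_config(voxel_spacing = 0.22))
run_qa(vol_fa, ph, movement = "freehand", operator = "A")
```

`run_experiment_grid(protocol_grid(), n_repeats = 3, seed = 1)` runs the full
13-experiment protocol (two freehand operators plus eleven motorized
settings, three acquisitions each) and returns the per-acquisition report
with per-method summary tables; `operator_icc_table()` adds the inter-operator
agreement table. `autoplot()` methods display line profiles with their
FWHM, the contrast regression, surface profiles and volume slices.

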