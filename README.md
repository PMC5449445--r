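# cueReg

Landmark-free, adaptive registration of time-lapse phase-contrast image
series from microfluidics experiments.

## The problem

In microfluidics time-lapse imaging, a bacterial microcolony growing inside a
chamber is recorded for one visual field over T equidistant time points
(typically ~1000 × 1000 px at tens of nanometres per pixel). Thermal drift
and vibration slowly rotate and translate the whole field, while the image
content itself changes drastically: the colony doubles every generation, the
signal-to-noise ratio is low, and the background varies between experiments.
Intensity-based registration fails on such data, and there are no anatomical
landmarks to pin. What *is* stable are the structural elements of the chamber
itself — square-like **spacers** that sit rigidly in the field of view.

cueReg detects these spacers in every frame and uses them as **visual cues**
for a rigid (rotation + translation) correction of the whole series.

## The method

1. **Preprocessing** (per frame): grayscale conversion → edge-preserving
   bilateral denoising (σ_spatial = σ_range = 75, neighbourhood diameter
   10 px) → contrast-limited adaptive histogram equalization (clip limit 2) →
   adaptive mean thresholding (11 × 11 px blocks, constant c = 2) →
   3 × 3 morphological dilation → border clearing → central circular mask
   (diameter 0.6 r). The output is a binary mask exposing spacer outlines.
2. **Polygon finding**: border following extracts one closed polygon per
   8-connected component. Each polygon *P_j* is scored by its
   perimeter-to-area ratio

       r_j = S_j / A_j ,

   with the perimeter S the summed Euclidean vertex-chain length and the area
   A the absolute shoelace sum. For a fixed shape the ratio falls as 1/scale,
   so large regular polygons (the spacers) score low; polygons with
   r_j < 5 × 10⁻² px⁻¹ are retained as the frame's visual cues (if none
   qualifies, all polygons are kept as a fallback).
3. **Control points**: each frame's cues are reduced to three ordered points —
   the corners of one cue's minimum-area oriented bounding box (1 cue), the
   first OBB corners of both cues plus a third spanning corner (2 cues), or
   the centroids of the first three cues (3+ cues).
4. **Registration**: the series is partitioned into maximal runs of frames
   with equal cue count J; inside a run, the exact affine transform mapping
   frame t+1's control triple onto frame t's is solved from the 6-equation
   linear system, runs are bridged at J-change boundaries through the matched
   common cues, and the chain of pairwise transforms is composed so every
   frame is warped (bilinear, zero fill) into frame-1 coordinates.
5. **Evaluation**: the per-frame root mean square difference (rmsd, px) of
   matched cue positions relative to frame 1 and the image closeness

       Φ = 100 − rmsd · 100 / r   (percent, r = image rows)

   quantify the registration quality; a probabilistic Hough transform (PHT)
   baseline (Canny-style edges → Hough lines → four best-fit points →
   least-squares rigid fit) is included for benchmarking and fails, by
   design, on scenes without straight structures.

A synthetic scene generator (`makeScene`/`renderSeries`) renders
microfluidics-like series — dark square spacers, an exponentially doubling
colony of bright rod-shaped cells, background gradient, sensor noise, and a
ground-truth random-walk drift trajectory — so the whole pipeline is testable
without any data download.

## Worked example

```r
library(cueReg)

scene    <- makeScene(frames = 8, rgb = FALSE, seed = 1)  # 1004 x 1002 preset
rendered <- renderSeries(scene)
series   <- rendered$series
series
#> FrameSeries: T = 8 frames, 1004 x 1002 px (grayscale)

res <- registerSeries(series)
res
#> RegistrationResult (cueReg): 8 frames, 8 registered
head(registrationLog(res)[, c("t", "J", "scenario", "tx", "ty", "status")], 4)
#>   t J scenario         tx       ty     status
#> 1 1 4        -  0.0000000 0.000000  reference
#> 2 2 4        c -1.3946264 3.535994 registered
#> 3 3 4        c -4.7238864 6.436495 registered
#> 4 4 4        c  0.7216335 3.920427 registered

ev <- evaluateRegistration(res)
#> rmsd before: 3.23 px   after: 0.402 px
#> image closeness before: 99.68%   after: 99.96%
recoveryError(res, rendered$truth)
#> 0.352 px
```

All four spacers are found in every frame (J = 4, scenario "c"), the
per-frame transforms track the simulated drift (tx/ty columns), and after
registration the cue positions agree with the reference frame to ~0.4 px —
an image closeness of 99.96% — while the recovered transforms land the true
spacer centers within 0.35 px of their frame-1 positions.

A thin command-line front end is installed with the package
(`inst/scripts/cuereg`) with `simulate`, `register` and `evaluate`
subcommands over the same functions.

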