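---
title: "Visual-cue based registration: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual-cue based registration: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration model

cueReg corrects rigid motion (rotation + translation) of a time-lapse series
relative to its first frame. The model's central assumption is that the
microfluidics chamber contributes *stationary structural polygons* — the
spacers — that are visible in every frame, while everything else in the image
(the growing colony, the background texture, the noise) may change freely.
Registration therefore reduces to (i) finding those polygons reliably in
every frame, (ii) summarizing them into three control points, and (iii)
solving, exactly, the affine transform that maps one frame's control triple
onto the previous frame's. Composing the pairwise transforms expresses every
frame in reference (frame 1) coordinates.

Because the transform is solved from exactly three point correspondences, the
solve is a 6 × 6 linear system with a unique solution whenever the triple is
non-collinear; there is no iterative optimization anywhere in the pipeline,
which is what makes the method robust to the drastic appearance changes that
defeat intensity-based registration on this kind of data.

Coordinates are (row, col), 0-based, origin at the top-left pixel; x ≡ col
and y ≡ row throughout the transform math.

## Preprocessing parameters

| parameter | default | units | role |
|---|---|---|---|
| `sigma_spatial`, `sigma_range` | 75, 75 | px, intensity | bilateral filter scales; at these values the filter acts as a strong, nearly box-like smoother that still respects the high-contrast spacer edges |
| `bilateral_diameter` | 10 | px | bilateral neighbourhood diameter |
| `clahe_tile` | 100 | px | CLAHE tile side (see below) |
| `clahe_clip` | 2 | – | CLAHE contrast (clip) limit |
| `thresh_block` | 11 | px | adaptive-threshold block side |
| `thresh_const` | 2 | intensity | margin below the local mean |
| `dilation_window` | 3 | px | dilation structuring element |
| `mask_diameter_fraction` | 0.6 | of r | retained central circle |
| `invert` | TRUE | – | foreground = darker than local mean |

Three of these deserve explanation.

**CLAHE tile size.** The tile parameter is commonly stated as a *grid*
(e.g. a 10 × 10 grid of contextual regions) rather than a pixel size, and the
two readings differ by an order of magnitude on a ~1000 px frame. We default
to 100 px tiles (a ~10 × 10 grid) for a quantitative reason: with clip limit
L and B histogram bins, the largest intensity step that clipped-histogram
redistribution can introduce into an otherwise flat region is ≈ L·255/B ≈
1.99 for L = 2, B = 256 — *just below* the threshold margin c = 2, so CLAHE's
own quantization artifacts can never become threshold foreground. With 10 px
tiles (100 px per tile) the integer clip floor forces steps of 255/100 ≈ 2.55
> c, and the threshold fires on CLAHE artifacts all over the background. The
two constants only interlock under the grid reading, which is therefore the
one we adopt. Implementation detail: the image is reflect-padded to a whole
number of tiles and cropped back after equalization.

**Threshold polarity.** Whether "foreground" should be above or below the
local mean depends on whether the spacers are darker or brighter than their
surroundings. Chamber spacers image dark; the default (`invert = TRUE`)
makes a pixel foreground iff it is strictly below (local mean − c). The
opposite polarity is one switch away, because real chambers vary. The local
mean uses reflect padding so image borders do not seed spurious foreground.

**Circular mask semantics.** The final stage keeps a circle of diameter
0.6 r centred in the image and removes *entire* connected components that
have any pixel outside it — a component-level decision, not pixel clipping —
because clipping would manufacture artificial polygon fragments along the
circle. The 0.6 default keeps the cue search in the central image area and
can be reduced further for data whose periphery is unreliable; values up to
1.5 are accepted (useful for small test canvases where the cue ring would
otherwise cross the circle).

## Polygon scoring

Polygons are the outer boundaries of 8-connected foreground components,
traced by border following; holes are ignored (the cues are solid shapes, and
the shoelace area assumes a simple polygon). Components with fewer than 5
boundary pixels are discarded before scoring: they cannot form a meaningful
polygon and their ratio is numerically unstable. The perimeter-to-area ratio
uses strict inequality at the 0.05 px⁻¹ threshold — a side-80 square, at
exactly 0.05, is excluded. When no polygon passes, the whole set is retained:
a frame with only complex polygons is still better registered with imperfect
cues than not at all.

**Centroid choice.** Cue anchor points are the *area* centroid of the
boundary polygon, not the arithmetic mean of its boundary vertices. Boundary
pixel chains sample jagged stretches more densely than straight ones, so the
vertex mean wanders as boundary noise redistributes vertices; the area
centroid is a first moment of the enclosed region and is insensitive to
vertex density. On preset synthetic scenes this halves the per-cue
localization jitter (≈ 0.17 px vs ≈ 0.30 px per frame). For clean
near-square cues the two definitions agree to well under a pixel. A zero-area
degenerate polygon falls back to the vertex mean.

## Control-point scenarios

With J cues per frame (after a stable lexicographic ordering by the minimum-y,
then minimum-x vertex corner):

* **J = 1**: the first three corners of the cue's minimum-area oriented
  bounding box (rotating calipers over the convex hull; corners ordered
  counterclockwise from the corner nearest the coordinate origin).
* **J = 2**: the first OBB corner of each cue, plus — as the third point —
  the corner of the first cue's OBB that spans the *largest triangle* with
  the two first corners. A fixed "second corner" rule can degenerate: if the
  two cues happen to lie along the same axis as the first OBB edge, the three
  points are collinear and the affine solve is singular. The max-area corner
  is deterministic and non-collinear whenever the OBB itself is
  non-degenerate. When a consecutive frame pair is solved, the corner index
  is chosen on the earlier frame and reused on the later one so the point
  correspondence is consistent.
* **J ≥ 3**: the centroids of the first three cues. Remaining cues are not
  used in the solve (which stays exact with 3 equations) but still
  participate in evaluation.

Control triples whose triangle area is below 1 px² are rejected as collinear
and the frame pair is treated as unregistrable rather than producing an
ill-conditioned transform.

## Interval adaptability and bridging

The series is partitioned into maximal runs of constant J. Within a run,
consecutive frames are matched cue-for-cue (minimal-displacement assignment —
exhaustive for up to 8 cues, greedy beyond) and solved pairwise. At a run
boundary the cue counts differ, so the bridging pair is estimated from the
*matched common cues* (min(J, J′) of them), reduced to a control triple by
the same scenario rules. A matched displacement larger than half the image
width aborts the pair: beyond that shift, cue identity is no longer
guaranteed. If a pair cannot be estimated at all (a frame with no cues), the
chain carries the last composed transform forward and flags every downstream
frame "unbridged" — frames are never silently dropped.

Warping is inverse-mapped bilinear interpolation with zero fill (binary masks
use nearest-neighbour to stay binary); transforms are kept in double
precision end-to-end, so warping is the only lossy step. RGB payloads are
warped channel-wise with the grayscale-derived transform.

## Evaluation metrics

Per frame, the rmsd is the root mean square of Euclidean distances between
that frame's cue anchors and the reference frame's, after minimal-displacement
matching (so a relabeling of cues cannot change the number). The reported
mean excludes frame 1, whose self-comparison is identically zero. Image
closeness Φ = 100 − rmsd·100/r is affine in the rmsd with slope −100/r and
equals 100 exactly for a perfect registration.

For the static (zero-drift) no-op check, "deviation from identity" of a
recovered transform is decomposed as the rotation angle plus the translation
measured *at the image center*, where the specimen sits. The raw offset
parameters of a 3-point affine extrapolate the (tiny) angular error of the
solve all the way to the coordinate origin at the image corner, which
overstates the deviation by an order of magnitude relative to any point in
the field of view.

## The PHT baseline

The comparison method follows the classical line-based recipe: Gaussian-blur
gradient edges (top 1% of gradient magnitudes), a sampled Hough accumulator
(1° × 2 px bins, up to 4000 edge points, seeded sampling), and a
least-squares rigid fit (scale locked to 1 — the instrument magnification is
fixed) onto the reference frame. Two implementation points matter for
fairness and stability:

* detected lines are refined to sub-pixel (θ, ρ) by total least squares on
  their inlier edge points, with a wide first band so that a physical line of
  finite width contributes both of its gradient edges and the fit settles on
  the centerline rather than flipping between edges across frames;
* the "four best-fit points" are the intersections of the strongest
  non-parallel lines (for a rectangular chamber, its corners), which are far
  more stable than segment endpoints.

The vote threshold (max of 100 and 4% of sampled points) separates genuine
wall lines (hundreds of collinear pixels) from the tangent alignments of
curved structures (tens). On scenes without straight structures the
accumulator has no qualifying peak and the baseline raises its documented
"no lines detected" error — the expected failure mode that motivates
cue-based registration in the first place.

## The synthetic scene generator

`makeScene`/`renderSeries` emulate the benchmark data's properties: a
1004 × 1002 px canvas; four dark square spacers of side 90–120 px placed on a
ring inside the central circle; a colony of bright 24 × 8 px rod-shaped cells
doubling every 10 frames from one cell and capped at 300 individuals
(rendered in frame-t coordinates, so it moves rigidly with the chamber, but
playing no role in the ground truth — it is a structured distractor, exactly
its role in real data); a mild background gradient fixed to the chamber;
additive Gaussian sensor noise of σ = 8 intensity levels added *after* the
geometric mapping, independently per frame; and a cumulative random-walk
drift (≤ 3 px translation and ≤ 0.3° rotation per frame, mimicking thermal
drift rather than i.i.d. jumps). All randomness flows from a single seed and
renders are bit-reproducible. Optional features exercise specific behaviours:
a per-frame visible-spacer schedule (interval adaptability), disc-shaped
spacers (line-free scenes for the baseline's failure mode), and straight
chamber walls (scenes the baseline can handle).

What the generator does **not** emulate: phase-contrast point-spread
physics, focus drift, illumination flicker, cell motility inside the colony,
or spacers that deform or detach. Passing the synthetic suites therefore
demonstrates the geometry and robustness of the pipeline under the stated
noise and drift model, not performance on any particular microscope's data —
on real data the preprocessing constants (polarity, mask fraction, threshold
margin) are the knobs to re-examine first.

## Problem sizes used by the test suite

The end-to-end suites run the full-size 1004 × 1002 preset with T = 30
frames for five seeds (drift recovery), T = 10 for the cue-count switch and
the static case, and T = 3–4 for the baseline scenes; unit tests use 512 px
canvases and ≤ 32 px images for the pixel-level oracles. These sizes were
chosen so the whole suite exercises realistic image dimensions while staying
comfortably inside a routine development cycle.

## Known limitations

* Two consecutive frames with at least one common cue are required; a series
  whose cue set changes completely between two frames cannot be bridged.
* Shifts larger than half the image width are rejected by design.
* The exact 3-point solve uses at most three cues; a least-squares solve over
  all cues would average more evidence but is deliberately out of scope — the
  method's robustness rests on the exactness and predictability of the solve.
* Sub-pixel cue localization (e.g. intensity-weighted refinement) is not
  implemented; accuracy is bounded by the rasterized boundary of the
  thresholded spacers (≈ 0.2 px per cue per frame on the synthetic preset).
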