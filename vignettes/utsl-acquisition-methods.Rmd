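---
title: "Methods: multi-scale UTSL acquisition, simulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale UTSL acquisition, simulation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(utslmap)
```

## The problem

An ultrathin-section library (UTSL) is a collection of thousands of 30 nm
tissue sections, tape-collected and mounted in strips on 100 mm silicon
wafers. Imaging such a library exhaustively at synaptic resolution is not
feasible: a single ~0.5 × 2.5 × 3 mm block cut into 17,000 sections and
imaged at 5 nm in-plane would take a 10 MP/s microscope more than 15 years
and produce over 5 PB (`estimateScanTime()`, `estimateStorage()`).
The alternative is *targeted* acquisition: map every wafer once at low
resolution, align the section overviews into a navigable 3-D map, choose
small target regions, and drive the microscope to exactly those regions on
every section — re-finding them reliably across stage error, wafer reloads
and focus drift.

`utslmap` implements that multi-scale workflow end to end, hardware-free:
all mapping, detection, calibration, alignment, targeting, focus/quality and
planning algorithms run against a simulated scanning electron microscope
(`simScope()`) that renders images from a procedural tissue/wafer phantom
with known ground truth. The microscope contract (move stage, set working
distance / scan rotation / stigmation, scan) is a set of S4 generics, so a
hardware backend could be added without touching the pipeline.

## The phantom

`makeTissuePhantom()` defines a deterministic, continuous intensity function
of physical position and section index — nothing is stored on a voxel grid,
so the same phantom renders consistently from 4 nm tile pixels up to 100 µm
wafer-map pixels. Its components are chosen for the features the algorithms
must respond to, not for visual realism:

* a multi-octave band-limited value-noise texture (finest octave ~0.25 µm)
  that gives cross-correlation something to lock onto at every scale;
* dark membrane-like ridges along the iso-contours of a smooth noise field
  (sharp edges for the focus/quality metrics);
* rounded dark cell-body blobs and *flat* vessel-like discs; the discs
  suppress local texture and are deliberately poor autofocus targets
  (exercised by `chooseFocusSpot()`);
* serial coherence along z with a decorrelation scale of ~1.5 µm (≈50
  sections at 30 nm), so adjacent sections align well while alignment over
  long spans must track content drift.

Rendering is band-limited: noise octaves whose wavelength approaches the
requested pixel size are faded out, and the nonlinear ridge profile widens
with pixel size. Without this, sub-pixel octaves alias under point sampling
and visibly bias sub-pixel correlation estimates — an 0.3–0.5 px systematic
error we observed before adopting band-limited sampling. Saturation is a
smooth `tanh` shoulder for the same reason: hard clipping creates flat pools
with aliasing-prone boundaries.

`makeWaferScene()` lays tape strips of near-rectangular sections on the
wafer with pose jitter, places four corner fiducial marks and debris
distractors, and records the full ground truth (centroid, rotation, strip,
tape order, z-index per section). Defaults follow the study conditions:
162 sections in 10 strips on a 100 mm wafer, translation jitter σ = 200 µm,
rotation jitter σ = 3°, two debris blobs. Jitter magnitudes are our own
assumption (tape-mounting variability is not documented anywhere we know
of); they are exposed as `waferLayout()` parameters. `makeUtslTruth()`
chains wafers so consecutive wafers carry consecutive z-ranges
(cross-wafer alignment is testable), deriving per-wafer seeds from the
master seed by a fixed offset of 1000.

## The simulated microscope

`simScope()` holds mutable instrument state (an environment inside the S4
object) and renders through the current reload perturbation at the *actual*
— error-perturbed — stage position, while metadata records the commanded
pose. The error model has three parts, each a `simParams()` entry:

* **Targeting error field.** A smooth, seeded, position-dependent field
  (single-octave noise, 40 mm wavelength, ±15 µm amplitude) displaces every
  move. This emulates the wafer-map chain error that limits fiducial-only
  targeting to about ±15 µm: it is repeatable and locally almost uniform,
  which is exactly why image-based stage correction can remove it — a
  correction move of a few micrometres lands where it was aimed. A fresh
  i.i.d. per-move error of that size would make the documented post-IBSC
  accuracy physically impossible, which is why the fresh component is a
  separate small jitter (σ = 0.1 µm).
* **Defocus/astigmatism blur.** σ_blur = σ₀ + k·|WD − z_surf(x, y)| with
  σ₀ = 0.5 px and k = 0.2 µm of blur per µm of defocus; stigmation error
  elongates the blur anisotropically with |s|, so settings of equal
  magnitude and opposite sign blur identically. The wafer surface height
  field z_surf is smooth and bounded (default amplitude 10 µm within a
  25 µm flatness bound; planar and flat variants exist for focus tests).
* **Noise.** Additive Gaussian with σ ∝ 1/√dwell (σ = 0.02 at 1 µs).

Hardware autofocus is emulated behaviourally: each focus-stig-focus
sequence silently fails with probability 0.05, leaving a working distance
drawn uniformly from ±10 µm. The per-tile quality gate, not the focus
routine, is what catches these failures.

All randomness flows through a private, counter-based stream
(`reseedScope()`): repeated scans after identical reseeds are bitwise
identical, and the acquisition loop reseeds per section so that an
interrupted and resumed run reproduces an uninterrupted run exactly.

## Wafer mapping

The full-wafer image (either an SEM-style montage render or an
optical-style render with a lateral shading gradient) is registered into
stage space by a closed-form least-squares similarity fit
(`fitSimilarity()`) from ≥3 point correspondences. Thresholding
(`thresholdMask()`) turns the wafer image and an example-section cutout
into binary masks; `automapSections()` then correlates the rotated example
mask across the wafer mask by FFT at each rotation (default ±15° in 3°
steps) and takes, per position, the maximum over rotations of the *overlap
fraction* — overlap pixel count divided by the rotated example's area, so
the heat is in [0, 1] and the detection threshold (default 0.8) does not
depend on section size.

Two details differ from a naive reading of "threshold the heat map and take
region centroids", and both were forced by the study conditions themselves:

* **Centre-surround heat.** With the default pitch (section width + 500 µm)
  and jitter (σ = 200 µm), the plain overlap fraction exceeds 0.8 *between*
  close neighbours (both sections contribute under the kernel), bridging
  their heat regions; physically overlapping pairs produce heat-1 plateaus
  wider than a section. We therefore subtract half the occupancy fraction
  of a 2 px ring around the rotated example. An isolated, centred section
  still scores 1 (the ring sits on background), while bridge and off-centre
  positions are penalised. `surroundPenalty = 0` restores the plain
  statistic.
* **Non-maximum suppression.** Peaks are extracted by thresholding plus
  greedy non-maximum suppression at the merge radius (half the example's
  smaller dimension), with each kept peak refined to the heat-weighted
  centroid of its neighbourhood. Connected-component centroids merge
  touching pairs into one detection between the two sections and collapse
  tape-order labelling downstream.

With these two choices the detector finds and correctly labels ~100% of
sections on default wafers; the ring and its weight are exposed parameters.

`numberSections()` clusters centroids along y (single-linkage with a gap
threshold, default 1 mm), orders strips top-to-bottom and sections
left-to-right (per-strip `reversed` flags handle serpentine mounting), and
continues the library-wide label counter across wafers. Ambiguous
clustering — two strips closer than a section height — is flagged for
manual strip assignment. `editSections()` is the programmatic counterpart
of the manual add/remove step and relabels after every edit.

`calibratePixelToStage()` measures the pixel-to-stage conversion factor
from commanded +x and +y moves; displacements are measured by
`measureShift()`, a two-stage estimator (integer FFT peak, then sub-pixel
refinement restricted to the trimmed overlapping crop, with the final
fraction evaluated directly in the Fourier domain). The two-stage design
matters: at displacements that are a large fraction of the field, the
circular-correlation wrap tilts the broad blurred peak and biases a naive
sub-pixel estimate by several tenths of a pixel — enough to corrupt a
0.5% calibration. Calibration should be run focused; the workflow drives
to a textured anchor and autofocuses first.

`acquireFiducials()` images each corner mark at 3 µm/px (findable after a
coarse reload offset) and 0.25 µm/px (precise registration). The simulated
fiducial pattern carries coarse structure (cross, off-axis dot and tick)
for the low-resolution pass and a fine central square/dot/notch for the
high-resolution pass. `acquireOverviews()` scans one image per section
(default: pixels slightly under 1 µm, field of view one millimetre larger
than the section on every side), focusing at each section by default.

## Alignment and target setup

`registerRigid()` finds (Δx, Δy, θ) maximising the zero-mean unit-norm
normalised cross-correlation: a coarse rotation sweep (default ±10° in 1°
steps) with an FFT translation search per angle, a fine sweep at a tenth of
the step around the best angle, and a parabolic sub-pixel peak. Ties break
toward the smallest |shift|, then the smallest |θ|. Near-constant images
yield a flagged zero-score identity result rather than an error.
`alignOverviewStack()` registers every section *directly against one
template* — never chained pairwise — so errors do not accumulate along the
stack and one bad section cannot derail its neighbours; later wafers pass a
template drawn from the previous wafer's aligned stack, which places the
whole library in a single frame.

`alignTargetPoints()` refines the alignment right at the chosen target
point: a small window (default 400 px; tests use 48–96 px) is resampled
from each overview *in the aligned stack frame* and registered
translation-only against the unweighted mean of the last `runningDepth`
(default 10) aligned windows; the first section's window seeds the average.
Resampling in the stack frame is deliberate — cropping axis-aligned windows
from rotated overviews leaves each window rotated by its section's mounting
angle, which biases translation-only correlation by ~1 px per few degrees.
Rotation is otherwise ignored at this scale. Windows scoring below 0.2 are
flagged, fall back to the global alignment, and are excluded from the
running average. The running average is what lets the local alignment
follow the slow z-decorrelation of tissue content where direct alignment to
the first section degrades (a regression test pins this behaviour).

## High-resolution acquisition

After a wafer reload, `reloadCorrection()` drives to each stored fiducial
through the operator's coarse offset, re-images at low then high
resolution, locates each mark by two-stage correlation against the stored
images, and fits a least-squares *rigid* transform from mapped to current
stage coordinates (residual RMS reported; scores below 0.2 raise a
"fiducial not found" error naming the corner).

`ibsc()` (image-based stage correction) takes a quick scan at the commanded
target under overview-like conditions, band-passes both the scan and the
stored aligned window with a difference-of-Gaussians filter (σ = 5 and
12 µm — cell-body scale), cross-correlates, applies the offset as a stage
correction and verifies with a second scan (at most 2 iterations). The
stored stack-frame window is derotated by the section's stack rotation
first, so the correlation is rotation-matched. Sections whose correlation
stays below 0.2 are flagged and imaged uncorrected.

The per-kernel quality metric follows the two contrast-pattern families on
a 3 × 3 kernel: S sums the four absolute differences of adjacent row/column
means; U is the absolute difference between the two interleaved
checkerboard groups (corners + centre vs edge mid-points). The combination
rule q = S − βU with β = 4.87 is our choice, calibrated in closed form so
that E[q] ≈ 0 for i.i.d. Gaussian noise kernels
(E[S]/E[U] = 4√(2/3)/√0.45 ≈ 4.87, verified by simulation); structure
scores positive, single-pixel noise is penalised. `qualityCheck()` reads a
grid (default 200 × 200, reduced for small images) of such kernels and
averages the best 1% — "a small percentage of the best grid points" left
unspecified; the top fraction is a parameter. Aggregating over the best
regions makes the score robust to vessels and section edges; sampling a
sparse grid keeps it fast on large tiles.

`autofocus()` sweeps the working distance across a bracket (default ±25 µm,
11 steps), scores small scans with the quality metric, refines with a 5-
point fine sweep and parabolic fit, and flags brackets whose best sample
lies on an edge. `autoStig()` grid-searches the two stigmator axes at the
found focus; `focusStigFocus()` chains focus–stig–focus. `fitFocusPlane()`
fits z = ax + by + c to ≥3 non-collinear focus points for the 3 × 3-grid
strategy. Four focus strategies are selectable per montage (`per_montage`,
`per_section` — the default, `plane_3x3`, `pooled_2x2`).

`planTiles()` lays out the tile grid with pitch = FOV − overlap (default
overlap 4 µm), centred at the target plus the configured offset, all
rotated by the north angle, which is also applied as scan rotation so every
section is acquired in the same stage orientation. Tiles are ordered by
distance from the focus spot. `acquireMontage()` drives the whole loop —
IBSC, focus-spot choice (highest-contrast block, ties toward the centre),
focus strategy, quality-gated tiles with one refocus-and-retake before
flagging, JSON-lines logging of every move/quality/retake, per-section
previews — and is resumable: sections with a complete tile set on disk are
skipped, and per-section reseeding makes the resumed output bit-identical.
`stitchPreview()` pastes tiles at their planned grid positions (no feature
matching) with a green/red per-tile quality overlay.

## Numerical and validation choices

* Pixels are 1-based with integer centres; transforms map (col, row) to
  stage (x, y), stage x grows with columns, y with rows (y-down), angles in
  degrees rotating +x toward +y, all stage units µm.
* Tie-breaks: registration ties toward smallest |shift| then |θ|; focus-spot
  ties toward the image centre; tile-order ties row-major.
* Degenerate inputs are either flagged results (constant images in
  registration, low-contrast focus spots) or errors naming the offender
  (out-of-bounds target window, unfound fiducial corner, collinear focus
  points, degenerate similarity fits).
* The test and validation runs are deliberately desk-scale — sections of a
  few hundred µm, ~1 µm overview pixels, single 20 µm tiles, 10–30-section
  wafers, a 20-wafer detection study at 100 µm map pixels — while the
  defaults of every operation keep the full-scale values (3 mm overviews,
  1 mm margins, 3/0.25 µm fiducial pixels, 200 × 200 quality grids). The
  miniature runs preserve every coordinate hand-off of the full-scale
  workflow.
* The end-to-end validation (`simulateEnd2End()`) measures, against the
  phantom's ground truth, the distance between the achieved central-tile
  centre and the true stage position of the target tissue point, per
  section, with all error sources enabled; ≥95% of sections within 2 µm is
  the pipeline-level pass bar, and the run also exercises reload recovery,
  calibration and the quality gate.

## What the phantom does not model

No charging artifacts or detector physics; no section folds or tears
(occlusion can be emulated by blanking a window, and the target alignment's
flag-and-fall-back path is tested that way); no tape or wafer background
texture; debris is intensity-matched but shape-mismatched to sections. The
simulator's error magnitudes follow the documented instrument behaviour
where available (±15 µm uncorrected targeting, reload offsets of hundreds
of µm, ~5% focus failures) and are otherwise stated assumptions exposed as
parameters. Passing the suite therefore demonstrates the correctness and
robustness of the *algorithms* under controlled, truth-known conditions —
not the image quality of any particular microscope.
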