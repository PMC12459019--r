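---
title: "Volumetric ULM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric ULM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vulm)
```

## The problem

Ultrasound localization microscopy (ULM) reconstructs microvasculature far
below the diffraction limit by localizing individual microbubble contrast
agents in thousands of ultrafast frames and linking them into trajectories.
In its volumetric form, a matrix probe acquires full 3-D volumes at a high
rate; each bubble appears as a point-spread-function-sized blob drifting
with the blood. The reconstruction yields two products: a super-resolution
*density* image (how often a track visited each voxel) and a voxelwise
*speed* map. From these, `vulm` computes three biomarkers designed to read
out glioblastoma-driven microvascular disruption in the mouse brain:

* **VD (vascular dropout)** — skeleton centerline voxels per mm³ inside a
  region of interest; functional vessels that disappear lower it.
* **BS (bilateral symmetry)** — the dice overlap between a preprocessed
  vessel volume and its mirror across the sagittal midline; a growing,
  displacing mass lowers it.
* **LHR (localized hemodynamic reduction)** — mean bubble speed in
  concentric spherical shells around a tumoral-side point versus the
  mirrored contralateral point; slowed peritumoral flow appears as
  negative left-minus-right differences at small shell radii.

Because raw volumetric acquisitions are enormous (hundreds of gigabytes
per session), the package includes a synthetic vasculature and bubble
simulator that reproduces the statistical structure each stage relies on,
so that the entire chain is testable on a laptop.

## The acquisition model

All geometry derives from the ultrafast sequence constants:

```{r}
acquisition_params()
```

A 7.81 MHz center frequency in 1540 m/s tissue gives a wavelength of
0.197 mm; the beamforming grid is isotropic at λ/2 (98.6 µm). Five
compounded plane waves fired at a 2500 Hz pulse repetition frequency give
500 volumes per second, and a 200 s contrast infusion yields 100 000
volumes per session. The rendered image uses a λ/20 (9.9 µm) grid; the
bilateral-symmetry analysis works at λ/5.

## The synthetic data generator

`generate_vessel_network()` grows random binary branching trees (radius
and length decaying per generation) confined to the left hemisphere and
mirrors every segment across the lateral midline, plus a dominant midline
vessel along the elevation axis emulating the superior sagittal sinus.
This makes the lesion-free network *exactly* bilaterally symmetric — the
property the BS metric is calibrated against. Segment centerline speeds
are drawn within the healthy range of roughly 1–30 mm/s, faster in larger
vessels. The generator is best-effort topology: real cortical vasculature
is not a forest of binary trees, so passing tests show the pipeline's
correctness on plausible geometry, not anatomical realism.

`tumor_spec()` + `apply_tumor_model()` implement the lesion: within the
core radius a fraction of segments (default 80 %) is removed; surviving
segments inside the periphery have speeds resampled into 0.1–0.8 mm/s,
the range reported for this glioma model — an order of magnitude below
healthy flow. This single mechanism drives all three biomarkers in the
expected directions.

`simulate_mb_transits()` injects bubbles into segments as a Poisson
process with entry rates allocated by segment length so the expected
load matches `mean_mb_per_volume` (default 90, within the 60–100 per
volume regime the analysis assumes), including entries before the first
frame so the count is stationary. Bubbles advect exactly
`speed / volume_rate` mm per frame along the centerline and carry a fixed
radial offset drawn uniformly within the vessel radius. We deliberately
draw the offset once per bubble rather than per frame: it keeps a
zero-speed bubble's position constant (the physically sensible limit),
approximates a streamline, and still gives vessels finite width in the
render.

`synthesize_volume_stack()` stamps a Gaussian blob of one-wavelength FWHM
(two λ/2 voxels) at each bubble's subvoxel position, adds a static
spatially smooth tissue field, adds i.i.d. Gaussian noise per voxel per
frame, and rectifies. Two choices matter:

* **Tissue is rank one in time** (one static field). This is the minimal
  clutter model the SVD filter addresses and makes its behavior
  analytically predictable; real tissue clutter occupies several singular
  components (motion, reverberation). Consequently the synthetic
  "correct" discard count is small, while in vivo work discards 10–15 %
  of components.
* **Noise defaults to 1 % of the bubble peak (40 dB)**. The detection
  chain's first step removes the noise floor at 3–4 % of the volume
  maximum, which presumes noise below that fraction of the bubble peak;
  the default places the simulator in the regime the chain is built for.

## The processing chain and its parameters

**SVD clutter filter** (`svd_filter()`, `svd_filter_batch()`): batches of
200 volumes (0.4 s) are reshaped to a Casorati matrix (voxels × time) and
the largest `round(discard_fraction × 200)` singular values are zeroed
(default 10 %, the lower end of the 10–15 % range used in practice). The
decomposition is computed from the 200 × 200 temporal Gram matrix, which
is exact and far cheaper than a full SVD of the tall matrix; tests verify
elementwise agreement with a brute-force `svd()` reconstruction. The
magnitude of the reconstruction is taken so downstream thresholds see
nonnegative intensity. The 0.4 s window makes the filter blind to bubbles
that barely move within it: a bubble at 0.4 mm/s travels ~1.6 voxels per
batch and much of its energy is indistinguishable from tissue. This is a
real limitation of the method, reproduced (and asserted) by the
slow-flow test — tumor-core vessels yield fewer tracks than healthy ones
at the same bubble budget.

**Localization** (`localize_stack()`): per batch, intensity is leveled
across depth by dividing each depth plane by its batch mean (`V_dep`),
the software equivalent of flattening time-gain compensation. Leveling
presumes a depth-dependent gain and a noise floor, as beamformed data
has; on a noise-free phantom `V_dep` is driven by the bubbles themselves
and the division distorts blob shapes, so `localize_stack(level = FALSE)`
is the right setting for clean phantoms and is what the accuracy fixtures
use. Each volume is then (1) thresholded at 3.5 % of its maximum
(configurable in the 3–4 % band) to remove the noise floor, (2)
median-filtered (3×3×3, the smallest isotropic kernel), (3) convolved
with an isotropic Gaussian of σ = 0.8 voxels — the matched filter for a
PSF whose FWHM is two voxels, σ = FWHM/(2√(2 ln 2)) = 0.85 rounded to the
0.8 used as the kernel parameter — with border renormalization, (4)
normalized to maximum one (per volume; per batch would couple frames for
no benefit), and (5) background-equalized with a white top-hat (spherical
element of radius 3 voxels, larger than the PSF footprint so blobs
survive the opening). Blobs are segmented at `mean + k·sd` (k = 2 by
default within the empirically tuned 1–3 range; noisy data wants 3) with
26-connectivity — blobs are isotropic, so the most permissive
connectivity is the safe reading — and each component contributes one
intensity-weighted centroid. Voxel centers sit at `(index − 0.5) ×
voxel_size` on axes ordered (depth, lateral, elevation); all I/O uses
this convention. On noiseless 20-bubble stacks the median centroid error
is ~0.04 voxels; at a 10 dB intensity signal-to-noise ratio (noise at one
tenth of the bubble peak) it stays below half a voxel with k = 3.

**Tracking** (`track_microbubbles()`): frame-to-frame linking minimizes
total Euclidean distance by the Hungarian algorithm (a shortest
augmenting path solver in compiled code, verified against brute-force
permutation enumeration), with links longer than 0.2 mm forbidden —
0.2 mm per frame is 100 mm/s at 500 vps, above any plausible flow.
Unmatched detections start new tracks; a terminated track never resumes
(no gap closing, matching the nearest-neighbour tracker convention this
procedure follows). Tracks shorter than ten points are discarded before
smoothing (the discard is membership-invariant to smoothing, so the
order only affects efficiency); survivors are smoothed per coordinate
with a third-order, nine-point Savitzky–Golay filter (endpoints by the
filter's polynomial extension), which reproduces cubic trajectories
exactly. Segment speed is the distance between consecutive smoothed
points times the volume rate. Per-bubble mean speeds recover 5–30 mm/s
within a few tenths of a percent on clean phantoms; at 1 mm/s the
per-frame step (2 µm, a fiftieth of a voxel) sits at the method's
resolution limit and recovery degrades to roughly the ten-percent level —
a slow-flow bias consistent with the filter-window limitation above.

**Rendering** (`render_density()`, `render_velocity()`): each track's
smoothed polyline is traversed by uniform supersampling at quarter-voxel
steps (error < ¼ voxel, deterministic, simpler than an exact 3-D line
walk); a voxel increments once per *track passage* — the natural reading
of track-count intensity, localization count being the other candidate —
and the final density image is Gaussian-filtered with σ = 0.8 render
voxels. The velocity map accumulates each traversed segment's speed and
stores the per-voxel mean together with a `support_count`, so alternative
aggregations remain recomputable. Before hemodynamic analysis the map is
median-filtered over 3³ neighbourhoods restricted to supported voxels
(zero-support voxels carry no speed sample and must not drag the median);
Gaussian filtering of the speed map is for display only.

## The biomarkers

**VD**: the density image is binarized (any positive voxel) and thinned
to one-voxel-wide centerlines by a homotopy-preserving 3-D thinning:
simple points — deletion leaves the object's 26-topology and the
background's 6-topology unchanged — that are not curve endpoints are
removed in six directional subiterations until stability. Any
homotopy-preserving thinning is an acceptable implementation of this
step; correctness is asserted by the cylinder oracle (the skeleton of a
solid cylinder counts within ±10 % of its axis length). "Number of
vessel centerlines summed" is interpreted as the count of skeleton
voxels: a connected-component count would be nearly scale-free and could
not meaningfully be divided by the ROI volume. VD is that count divided
by the ROI volume in mm³; the default ROI is the left (implant-side)
hemisphere.

**BS**: the density image is mean-pooled to λ/5 voxels, centered
laterally by an integer center-of-mass shift onto the grid midline,
rotationally centered about the depth and elevation axes (a ±10° grid
search in 1° steps per axis maximizing the mirror dice — rotation about
the lateral axis cannot change the comparison and is skipped),
power-compressed (exponent 0.5), dilated with a spherical kernel of 0.4 λ
radius, Gaussian-filtered, binarized at nonzero, and compared with its
lateral reflection by dice. Two implementation notes: centering is
performed after pooling rather than before — the binarized λ/5 support is
what enters the comparison, so the result is the same and the search is
~60× cheaper; and the centering exists to align a brain that is off-axis,
which means a volume lying strictly in one hemisphere is *folded onto
itself* by the shift — the raw one-hemisphere-versus-mirror comparison
(dice 0) is available via `center_lateral = FALSE`.

**LHR**: spherical shells (outer radii 0.25–4 mm in 0.25 mm steps,
0.25 mm thick — the granularity implied by the radii at which effects
are reported) are grown from the tumoral-side point and from its
contralateral mirror (lateral coordinate reflected about the midline).
Shell means are taken over supported voxels only, and per-shell supported
voxel counts are reported because small shells sample few vessels and
their means are correspondingly noisy. The difference is **left minus
right** (tumoral minus contralateral), so slowed tumoral flow is
negative; the alternative sign convention appears in places but is
inconsistent with reporting tumor slowdowns as negative values, which is
the convention adopted here. The axial coordinate of the reference point
is taken 3 mm below the *top of the vascular support* in synthetic runs —
a stand-in for "3 mm below the skull", which real data must supply.

## Problem sizes and defaults of the end-to-end runs

`pipeline_config()` defaults describe the synthetic study conditions:
a 48³ λ/2 grid (a 4.7 mm cube), 800 volumes (1.6 s, four 200-volume
filter batches), 5 trees per hemisphere plus the midline sinus, 90
bubbles per volume, tissue clutter at 10× bubble peak, noise at 1 %, and
rendering at λ/10. These sizes were chosen so a paired control/lesion
experiment is a minutes-scale computation while every stage still
operates in its intended regime; the beamformed domain is smaller than a
real mouse head and the acquisition is far shorter than 200 s, so
absolute biomarker values are not comparable to in vivo numbers — the
paired *directions* (lower VD, lower BS, negative small-radius LHR under
a lesion) are the reproducible content. Rendering at λ/20 with full-size
domains is supported by configuration. The synthesize → filter →
localize stages stream batch-by-batch, so memory stays bounded by one
batch plus the render grids.

Paired runs share the master seed (the control and lesioned networks are
identical up to the lesion) and the implant-site reference point for the
shell analysis, mirroring how the real analysis anchors both groups at
the known implantation site.

## What passing tests do and do not show

The simulator emulates: bilateral near-symmetry, healthy and
tumor-modified flow ranges, per-volume bubble loads, static
high-amplitude clutter, subvoxel PSF sampling, and Poisson bubble
arrivals. It does not emulate: skull aberration and shadowing, tissue
motion (clutter with temporal rank above one), bubble size/intensity
dispersion, flow profiles within a vessel (plug rather than laminar
flow), vessel curvature at sub-segment scale, or network-routed transit.
Tests passing on this generator therefore validate the *processing
chain* — its numerics, contracts and directional sensitivity to a
lesion — not performance on in vivo data.

## Numerical choices and degenerate inputs

* Gaussian kernels truncate at ±3σ; the matched filter renormalizes at
  borders (replicate-like), the render display filter zero-pads.
* A nominally integer structuring-element radius computed as a voxel
  ratio is kept from spilling into the next integer shell by a 1e-9
  tolerance.
* All-zero volumes: the filter warns and returns zeros; localization
  returns no records; an empty image yields VD 0 and a flagged BS of 0.
* Depth planes with zero mean are exempted from leveling (division
  guard, reported via a message).
* Trailing partial filter batches use a proportionally scaled discard
  count, at least one component, reported via a message.
* Assignment cost ties are broken by the lowest detection index; the
  rotation grid search resolves ties toward 0°.
* Empty shells report `NA`, never 0 — a missing mean is not a zero speed.

## Session info

```{r}
sessionInfo()
```
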