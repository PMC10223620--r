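---
title: "Quantifying bone ingrowth in porous implant micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bone ingrowth in porous implant micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseoquant)
```

## Scope and model

`osseoquant` measures the bone-ingrowth ratio (BI) of lattice-structured
implant cross-sections from 2D optical micrographs. The measurement model
assumes three visually distinct textures inside the implant region:

* **metal** — polished titanium strut cross-sections: bright, spatially
  smooth;
* **bone** — mineralised tissue grown into the pores: mid-gray with
  high-frequency texture (trabecular structure, staining granularity);
* **holes** — pore space not filled by bone: dark and smooth (embedding
  resin or void).

BI is the filled fraction of the *original* pore space,
`BI = A_Oss / (A_Oss + A_Hole)`, with `A_Oss` the bone area and `A_Hole`
the detected hole area, both in pixels. Metal never enters the ratio, so BI
is invariant to strut thickness and magnification. For solid control
implants the denominator is zero and BI is reported as undefined (`NA`,
`defined = FALSE`) and excluded from batch means — never silently coerced
to 0.

## Stage 1: implant extraction

`segment_implant()` composes: grayscale conversion (luma weights
0.299/0.587/0.114) → global mean threshold → Sobel edge magnitude of the
thresholded grayscale → sliding-window foreground classification →
mask combination → morphological closing → largest connected component.

Rationale for the defaults (`stage1_config()`):

* **Global mean threshold.** The implant (bright metal + mid-gray bone)
  lies above the image mean whenever the background is dark resin; a
  local-mean variant (`local_mean = TRUE`) exists for images with strong
  shading. Foreground is *strictly above* the mean, so a constant image
  yields an empty mask and a clean "segmentation failed" error rather than
  an arbitrary split.
* **Sliding window** (`window = 32` px, `stride = 16` px): a window is
  foreground if at least 2% of its pixels exceed 0.25× the maximum Sobel
  magnitude. This removes background debris that passed the intensity
  threshold but carries no edge structure. Windows overlap half-and-half
  and combine by OR; a flush window is added at each image edge so every
  pixel is covered.
* **Combination = intersection** of the two evidence masks (configurable to
  union): a pixel must be both bright and near edge structure.
* **Closing radius 35 px** (disk): the implant *region* for stage 2 is the
  filled footprint — pores must be inside it. At the package's reference
  scale of 10 µm/px a 600 µm pore is 60 px, and a closing element of ~0.6×
  the pore diameter bridges empty pores and rim bays into the footprint. If
  your images have a different µm/px, scale `close_radius` with them.
* **Failure definition**: any stage producing a mask below 1% or above 99%
  of the frame aborts with the stage name; an all-background or saturated
  image should fail loudly, not return a plausible-looking mask.

The mask is a subset of the closing of the union of the two evidence masks
by construction — the pipeline invents no foreground outside its operators'
outputs.

## Stage 2: holes, then bone vs metal

The texture partition runs in the order: dark holes first, roughness on the
remainder second. Holes are the only class defined by *both* intensity and
smoothness, and removing them first means the roughness rule faces a clean
two-class problem.

**Chan–Vese holes.** `evolve_contour()` minimises the discrete two-phase
Chan–Vese energy (data terms plus `mu` × contour length, the length counted
as 4-neighbor label-discordant pixel pairs). The implementation makes the
spec-level guarantee — energy non-increasing over accepted iterations — hold
*by construction*:

* explicit gradient steps on a signed-distance level set, localised by a
  smoothed Dirac delta (`eps = 1.5` px);
* a descending step-size ladder (8×…1/16× of the step that moves the
  fastest pixel one pixel-unit) with monotone acceptance: a candidate is
  adopted only if the exact energy of its partition (with region means
  re-optimised) does not increase;
* one *threshold move* candidate per iteration — every pixel assigned to
  the nearer of (c1, c2), the exact minimiser of the data term at fixed
  means — accepted under the same monotone rule. This clears misclassified
  blobs far from the contour, which delta-localised updates cannot reach
  (a checkerboard initialisation stalls at IoU ≈ 0.5 on a disk without it);
* re-initialisation to a signed distance function (exact Euclidean distance
  transform) every 5 accepted iterations, preserving the partition;
* convergence after `patience = 5` consecutive accepted steps whose
  relative energy change is below `tol = 1e-4` — a single small step right
  after a symmetric initialisation is not convergence.

For hole detection the contour is restricted to the implant region
(`domain` argument); pixels outside contribute nothing to means, energy or
length. The default initialisation seeds the contour with pixels darker
than `hole_seed_max = 0.30` — holes are by definition the dark class, and a
dark-seeded local minimum keeps c1 dark. A global two-phase split can
legitimately group {holes + bone} against {metal} when bone dominates the
pore space, which would be a correct minimum of the energy but the wrong
answer to "where are the dark voids"; the seed, plus a sanity cap
(`hole_mean_max = 0.45`: if the converged darker region is not actually
dark, there are no holes), prevents this failure mode. If no dark seed
exists the holes mask is empty with a warning — that is the expected
outcome for fully ingrown or solid implants. Hole components smaller than
`min_hole_px = 20` (8-connected) are discarded as noise.

**Roughness rule.** `classify_roughness()` scores each remaining pixel by
the Roberts cross gradient magnitude averaged over a `neighborhood = 9` px
square window, and labels bone where the average exceeds a threshold
(per-image Otsu split by default, floored at `min_roughness = 0.08` so a
texture-free remainder — a solid implant — is not split by noise). Two
refinements matter in practice:

* Only Roberts responses whose full 2×2 support lies inside the remaining
  region enter the average. Otherwise the intensity cliff at every hole
  boundary would leak high magnitudes into the adjacent metal.
* The metal/bone interface itself is an intensity step whose gradient
  magnitude exceeds bone's *internal* texture; window averaging smears this
  ridge ~half a window onto the metal side, systematically inflating bone
  area (a +0.03…+0.05 BI bias in testing). Bone is therefore additionally
  required not to be metal-bright: `bone_intensity_max = "otsu"` splits the
  remaining-region intensities (bimodal: bright metal vs mid-gray tissue)
  and excludes pixels above the split. A radius-1 closing then reabsorbs
  isolated speckle-bright pixels inside bone, and a radius-2 opening
  (`bone_opening`) removes isolated specks on metal. All three are
  configurable; disabling them recovers the bare roughness rule.

The three masks are asserted on every run to tile the implant region with
pairwise-empty intersections; the partition invariant is not a test-only
property.

## The synthetic generator

`lattice_phantom()` / `render_phantom()` produce the study conditions the
package is validated under, since no real micrographs are deposited:

* disc footprint of radius 0.44× the canvas (default 320 px) with a thin
  solid rim (the implant's machined outer contour; it also closes pores cut
  open at the section boundary);
* six strut patterns at a 600 µm design pore mapped to 60 px (10 µm/px; the
  true magnification of the source study's microscope is unknown, so the
  scale is a documented free choice) plus solid controls;
* intensity conventions: metal 0.85 ± 0.03 (smooth low-frequency drift
  only), bone 0.55 ± 0.15 uniform per-pixel speckle, holes 0.15 ± 0.02
  smooth, background 0.08 — bright polished titanium, mid-gray tissue, dark
  voids. At zero noise the neighborhood-averaged Roberts magnitude over
  bone exceeds metal's by well over 3×, so the texture classes are
  separable by design;
* bone placement: per-pore filled fractions are jittered (SD 0.12) around
  the designed global fraction, shifted in common and rounded by largest
  remainder so the global bone share of pore space equals `designed_bi`
  exactly up to one pixel. Within a pore, bone grows as a crescent from one
  random point on the pore wall — ingrowth in real sections is one-sided
  and patchy. (A uniform wall-inward annulus was considered and rejected:
  at low designed BI it produces 1–3 px shells, which are sub-resolution
  for any windowed texture score and are not what micrographs show.)
* `add_noise()` adds seeded Gaussian noise and an optional linear shading
  ramp, clipped to [0, 1].

Everything is deterministic given the spec seed. What the phantoms do *not*
emulate: grinding scratches, staining variability, histological artefacts,
partial-volume blur at texture boundaries, or uneven illumination beyond a
linear ramp. Passing the recovery tests therefore shows the pipeline's
logic is sound under the stated texture model, not that it is robust to
every real-world acquisition artefact — on real data the tunable thresholds
(`hole_seed_max`, roughness threshold, intensity gate) are the knobs to
revisit, ideally against a few manually outlined sections via
`agreement()`.

## Numerical choices

* Images are numeric matrices in [0, 1]; 8/16-bit inputs are divided by
  their type maximum on load. Coordinates are 1-based `[row, col]`, origin
  top-left.
* Convolution borders: edge-repeating reflection. Roberts responses anchor
  at the top-left of each 2×2 block with the last row/column reflected.
* Thresholds are strict (`>`): constant inputs yield empty masks, and
  raising a threshold never adds foreground (monotonicity).
* Binary morphology treats masks as subsets of an infinite background
  plane; closing pads by the element radius before dilating, so closing is
  extensive and idempotent. Disk elements use the exact Euclidean distance
  transform; an earlier frame-local convention (erosion treating outside as
  foreground) was rejected after it produced bulges where the dilated
  implant met the canvas border.
* Connected components are 8-connected (4-connected labels merged across
  diagonals).
* Otsu thresholds use a 256-bin histogram over the relevant value range.
* The pipeline is fully deterministic: no RNG is consumed at analysis time,
  so identical input and configuration give bit-identical masks and
  reports. Generator and noise seeds are explicit arguments.

## Problem sizes used in validation

The shipped tests and `scripts/acceptance.R` validate at the generator's
reference scale: 320 px phantoms with 60 px pores for end-to-end recovery
(30 images: six lattices × designed BI 0.1–0.9 at σ = 0.02), 160 px
phantoms with 30 px pores (and `close_radius` scaled to 18) for unit tests,
a 128×128 disk for Chan–Vese correctness, and ≤16×16 random images for
operator/oracle equivalence. These sizes were chosen as the smallest at
which each property is meaningfully exercised — pores must be several
texture-window widths wide.

## Known limitations

* Single implant per frame; no registration across serial sections.
* 2D only — no µCT/3D metrics (trabecular connectivity, mineral density).
* The Chan–Vese model is two-phase; images whose holes are not the darkest
  coherent class (e.g. stained void fillers) need a different `init`
  seeding.
* The roughness rule assumes bone is *texturally* rougher than metal at the
  working magnification; heavily polished sections imaged at low
  magnification may violate this.
* BI compares areas within one section; it is not a volumetric ingrowth
  fraction.
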