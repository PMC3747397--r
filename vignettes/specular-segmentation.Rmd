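---
title: "Specular reflection segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specular reflection segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specseg)
```

## The problem

Specular reflections are mirror-like glare on moist tissue: white or
light-colored spots that appear wherever the surface normal bisects the
illumination and viewing directions. In laparoscopy they are present in
nearly every frame, and because they carry illumination rather than tissue
information they have to be masked before segmentation, classification or
registration of the underlying anatomy.

The physically motivated route — dichromatic modelling, which splits
reflected radiance into a surface (specular) and a body (diffuse) term
with separable spectral factors — assumes dielectric surfaces and in
practice fits human tissue poorly. Working detectors therefore threshold
some color representation to find the bright specular core and then
expand into the surrounding *specular lobe*, the halo where specular
reflection is still strong but diffuse reflection grows.

The hard cases are small, weak reflections on curved tissue far from the
endoscope. Their interior luminance overlaps the brightest tissue, so a
global threshold that captures them also floods tissue with false
positives; at any workable operating point they are simply missed. What
they do have is a step-shaped border. The hybrid detector in this package
exploits that: it finds closed contours in an edge map and uses them both
to delineate bright reflections precisely and to recover the weak ones no
threshold can see.

## The detectors

Let `I : Ω → R³` be the RGB image, `Y` its BT.601 luminance
(`0.299 R + 0.587 G + 0.114 B` — the classic YUV luma; the choice of
weights is a convention, the methods only need a monotone brightness
scale).

**Gray-level thresholding.** `S = {x : Y(x) > t_gray}`. The baseline;
one global knob, `t_gray` (default 230, 8-bit scale).

**Specular-peak thresholding.** The image is first transformed as
`I_t(x) = (1 − S(x)) I(x)`, with `S` the HSV saturation. Colored
(tissue) pixels move toward black while near-neutral glare is untouched,
which widens the histogram gap between the two. The luminance histogram
of `I_t` is smoothed with a Gaussian kernel (σ, default 2 bins, merges
peaks produced by distinct reflections) and the threshold is placed at
the valley before the brightest peak: among positions where the descent
indicator `h̃(t) = 1{h(t) − h(t+1) > 0}` switches off, take the largest
`t` that still has histogram mass above it and exceeds `t_min` (default
100). Two robustness rules matter here:

- *the mass rule*: the raw "last descent" criterion always selects the
  final downslope of the histogram, above which nothing lies — it would
  segment nothing, ever. Requiring positive mass above the candidate
  restores the intent (threshold under the brightest peak) while changing
  nothing elsewhere.
- *the `t_min` veto*: if no admissible valley is bright enough, the image
  is treated as reflection-free and an empty mask is returned rather than
  thresholding bright tissue. `select_specular_peak_threshold()` returns
  `NA` in that case, never an error.

**Cone thresholding.** Neutral colors lie on the gray axis
`n = (1,1,1)ᵀ` of RGB space. A pixel is accepted iff its distance to the
axis is strictly less than `a · (p − x0)`, with `p` the axial projection
`⟨n, I⟩/|n|`. `x0` (cone tip, axial-projection units: a gray level `v`
projects to `v·√3`; default `100·√3`) and `a` (slope, default 0.3) are
hardware-dependent, since RGB is a hardware-defined space; the model
implicitly assumes reasonable white balance. Pixels with `p ≤ x0` can
never be members — the right-hand side is non-positive.

**Specular lobe growing.** Every 8-connected component of the core mask
is grown by region growing with a per-component threshold `c · μ`, where
`μ` is the component's mean *raw* luminance and `c` is a scaling factor
(default 0.7; values above 1 would permit no growth on clipped cores).
Growth uses raw luminance rather than the saturation-suppressed
transform: the lobe is defined photometrically on the image itself, and
the core set is kept wholesale because the final segmentation is the
union of core and lobe. 8-connectivity is used for both component
extraction and growth — standard for blob-like bright regions, and it
avoids splitting thin diagonal glints. Overlapping lobes simply merge.

## The hybrid closed-contour detector

Three process lines run per image:

1. **Thresholding**: cone segmentation gives the candidate cores.
2. **Contours**: Canny on raw luminance (Gaussian σ 1.0; Sobel gradients
   normalized to intensity units per pixel; 4-sector non-maximum
   suppression; hysteresis), then morphological closing with a disk of
   radius `closing_radius` to bridge small gaps. "Enclosed by a contour"
   is operationalized as border-seeded flood fill of the edge-map
   complement: regions the outside cannot reach are *enclosed
   components*. The flood fill uses 4-connectivity, the duality partner
   of 8-connected edge curves — with an 8-connected flood, any diagonal
   step in a contour would leak and nothing would ever be enclosed.
3. **Classification**:
   - enclosed components containing at least one thresholded pixel are
     **Type 2** (small bright step-edged reflections); their mask is the
     contour interior plus the edge pixels touching it — the glare rim
     is part of the glare, and including it keeps Type 2 masks contiguous
     with the cores.
   - thresholded components with no closed contour are **Type 1** (large
     reflections with clipped centers and slow radial decay, whose rims
     are too irregular and shallow for reliable contour closure); these
     are expanded by lobe growing, since the contour line offers no
     boundary for them. Types 2/3 are not grown: their precise boundary
     *is* the contour.
   - remaining enclosed components are **Type 3** candidates and are kept
     iff all four strict constraints hold: mean interior luminance
     `> t_av`; mean interior minus mean over the one-pixel ring just
     beyond the contour `> t_diff`; size `> t_cc_min`; size `< t_cc_max`.
     The surround ring is taken *beyond* the contour rather than on it,
     so the drop constraint measures glare-to-tissue contrast, not
     glare against its own anti-aliased rim. A candidate whose ring is
     empty (e.g. flush against the border) cannot be evaluated and is
     excluded with a warning.

The final mask is the union of the three type masks.

### Edge-map parameters

The Canny hysteresis thresholds are **absolute gradient magnitudes** (on
the 8-bit luminance scale, Sobel normalized so a unit intensity ramp has
gradient 1), not fractions of the per-image maximum gradient. A
per-image-relative threshold moves the operating point whenever an
unusually strong edge enters the frame, which makes weak-reflection
detection depend on unrelated image content; absolute thresholds keep it
deterministic. Defaults: low 3, high 6, i.e. roughly "above background
texture, below any reflection edge" for 8-bit material. All contour and
constraint parameters are exposed and searched by `optimize_parameters()`
— none of them are claimed optima, because the reference optimization was
done on non-public clinical material and its numeric results are not
available.

### Numerical conventions

- Strict inequalities throughout (`>`, `<`), exactly as the set
  definitions state them, including all four Type 3 constraints.
- Histograms bin rounded luminance; smoothing kernels are truncated at
  `±⌈3σ⌉` and renormalized to unit sum; boundaries are mirror-reflected,
  which preserves total mass exactly.
- Morphological disks are rasterized as `dr² + dc² ≤ r² + 1`, keeping the
  rasterized disk 8-connected; in particular the radius-1 disk is the
  full 3×3 square, so a radius-1 closing bridges a 1-pixel contour gap
  (a pure diamond would fail the erosion step at the bridge).
- Connected-component labels are assigned in raster-scan order of each
  component's first pixel, making labelling deterministic.
- Grid search breaks score ties by the lexicographically smallest
  parameter tuple.
- Degenerate inputs: an image with no edges reduces the hybrid exactly to
  cone thresholding plus lobe growing; a uniform image yields empty masks
  from every detector (for the peak detector via the `t_min` veto).

## Evaluation

The Jaccard index `tp/(tp+fp+fn)` scores pixel overlap; true negatives
are deliberately absent from it because glare covers a tiny fraction of a
frame and specificity would look excellent even for grossly oversized
masks. Two empty masks score 1, so reflection-free images do not have to
be dropped. Mean and type-7 (linear interpolation) quartiles are
reported over the per-image distribution.

Because small reflections contribute little pixel overlap, detection is
also scored at the object level: a ground-truth reflection counts as
detected when the prediction shares at least one pixel with it — the most
permissive rule, and the one under which tiny Type 3 detections register
at all; a predicted component touching no ground truth is one false
positive. Sensitivity is reported per type and averaged two ways:
unweighted over the three types (the headline, matching the per-type
table layout) and weighted by reflection counts (for transparency). The
number of true-negative reflections is undefined — there are only
reflections and background — so instead of specificity the positive
predictive value `tp/(tp+fp)` is reported; it is `NA` ("n/a" in written
reports) when nothing was predicted at all.

`optimize_parameters()` evaluates mean Jaccard over an exhaustive
Cartesian grid and returns the argmax plus the full score surface
(`autoplot()` draws it). The end-to-end benchmark optimizes each
thresholding detector jointly with the lobe factor `c`; the hybrid
inherits the optimized cone and lobe parameters and then searches its
edge-map and constraint grid. This staging keeps the search space small
and mirrors how the pipeline composes.

## The synthetic world

The generator (`generate_scene()`, `generate_corpus()`) exists so that
every algorithm and metric can be exercised — and the hybrid's central
claim tested — without clinical data. Its defaults are a designed stress
world, fixed once:

- **Tissue background**: a smoothed Gaussian random field, rank-normalized
  to `f ∈ (0,1)` (rank rather than min–max, so the area above any level is
  seed-independent), mapped to liver-like channels
  `R = 90 + 45f`, `G = 40 + 25f`, `B = 35 + 20f` plus a neutral "wet
  sheen" `45f²` added to all channels. Bright tissue is thereby both
  brighter and whiter — the color-space overlap that limits thresholding
  detectors is built in, not accidental. Background luminance spans
  roughly 54–130; additive Gaussian noise (sd 2) on each channel.
- **Type 1** (2 per scene): Gaussian radial profile (scale 5–7 px) with
  angular amplitude modulation (depth 0.8, three lobes) added as white
  light; the amplitude `1.05 · (255 − min channel)` clips all three
  channels at the center, so clipped centers are pure white, as real
  clipped glare is. The modulation puts part of every rim below any
  workable edge threshold: large glare has irregular rims and open
  contours, which is exactly why the hybrid classifies it by *absence* of
  a closed contour. Ground truth is cut at 10% of the amplitude — a
  Gaussian tail has no natural boundary, so some convention is required;
  the fraction is exposed as `type1_mask_frac`.
- **Type 2** (3 per scene): near-white disks, radius 2.5–4.5 px,
  luminance 235–255, ≤1 px of anti-aliasing so the step border is real.
- **Type 3** (4 per scene): local tissue color plus a neutral lift,
  placed on darker tissue (`f ≤ 0.35`). The lift is chosen to put the
  disk at a gray-axis distance-to-projection ratio of ~0.30 — inside the
  locus occupied by bright wet tissue — and the resulting luminance band
  (85–112) lies inside the background's upper range. Consequences, by
  construction: any global luminance threshold that catches a Type 3 also
  fires on bright tissue, and any cone wide enough to admit one admits
  bright tissue too. Type 3 is recoverable only through its step edge.
- Reflections are placed mutually disjoint, 4 px apart and away from the
  border, with bounded retries (a placement error is raised when the
  requested counts cannot fit).

What the generator does **not** emulate: lens distortion and vignetting,
smoke and fluid, motion blur, interreflections, sensor demosaicing
artifacts, and the gradual rim geometry of real organs. A green test on
this world establishes that the algorithms behave as designed under the
stated geometry and photometry — it does not establish clinical
performance, and the clinical numbers reported for this method family
(computed on a non-public corpus) are neither reproduced nor asserted
anywhere in the package.

Two synthetic outcomes are worth flagging. First, on this world the
specular-peak detector's Type 2 sensitivity is very low (~0.05 on the
default corpus): pure-white clipped Type 1 peaks sit above the Type 2
peaks in the histogram, and the single-peak assumption fails more
strongly here than on clinical material. Second, the hybrid's mean
Jaccard is slightly below the cone's on this world, because several
Type 1 rims do produce partial contour arcs that tighten the Type 1 masks;
the hybrid's advantage is in what it *detects*, which is what the
object-level metrics measure.

## Running the benchmark

```r
bench <- run_end_to_end(n_images = 20, seed = 1)
bench$report
```

takes about a minute on one CPU and reproduces the qualitative
comparison: every detector finds every Type 1 reflection; gray-level and
cone thresholding find every Type 2 but no Type 3 at their Jaccard-optimal
settings; the hybrid recovers most Type 3 reflections and lifts the
unweighted average sensitivity from 0.67 to ~0.90 at essentially
unchanged PPV. `scripts/acceptance.R` re-runs exactly this computation
from a fresh seed.

## Known limitations

- Contour closure for very small or low-contrast reflections is the
  failure mode: when a Type 3 rim loses too much contrast against a
  locally bright background, its ring stays open and the reflection is
  missed. On the default world the hybrid recovers ~70% of Type 3.
- Guaranteed-closed contour constructions (polar transform with
  shortest-path closing) were deliberately not implemented: closing every
  open contour indiscriminately converts open tissue edges into false
  reflections at scale, so morphological closing with small radii is the
  chosen trade-off between sensitivity and PPV.
- No inpainting or removal of the detected glare; the product is the
  mask.
- TIFF input is not supported in this build (no TIFF reader available);
  PNG is the interchange format.
- The cone detector presumes decent white balance, and its parameters are
  camera-dependent; re-optimize per hardware.
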