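# specseg

Segmentation of specular reflections (glare) in laparoscopic RGB images.

Moist tissue produces mirror-like highlights wherever the surface normal
bisects the illumination and viewing directions. These white or
light-colored spots corrupt nearly every downstream step of endoscopic
image analysis — segmentation, classification, registration — so masking
them out is a standard preprocessing stage. Most detectors threshold the
bright specular core in some color representation and then grow the
surrounding "specular lobe". That works for large, clipped highlights, but
small weak reflections overlap bright tissue in color space and no single
threshold can recover them.

`specseg` implements the classical thresholding detectors, the lobe
growing step, and a hybrid detector that adds closed-contour analysis of a
Canny edge map to recover exactly those weak reflections, together with
evaluation metrics and a synthetic benchmark generator.

## Methods

**Thresholding detectors** of the specular core `S_spec`:

- *Gray-level*: `S = { x : Y(x) > t_gray }` with BT.601 luminance
  `Y = 0.299 R + 0.587 G + 0.114 B`.
- *Specular peak*: transform `I_t(x) = (1 − S(x)) I(x)` (HSV saturation
  suppression pulls colored tissue toward black, widening the gap between
  glare and bright tissue), histogram the luminance of `I_t`, smooth with
  a Gaussian kernel `N(t, σ)`, and place the threshold at the valley before
  the brightest peak: the largest `t > t_min` where the descent indicator
  `h̃(t) = 1{h(t) − h(t+1) > 0}` switches off and positive mass remains
  above `t`.
- *Gray-axis cone*: accept `x` iff
  `|I(x) − p(x)| < a (⟨n, I(x)⟩/|n| − x0)` where `n = (1,1,1)ᵀ` and `p(x)`
  is the projection of `I(x)` onto the gray axis — a cone with tip `x0` and
  slope `a` around the locus of neutral colors.

**Specular lobe**: each 8-connected core component `S_cc,i` with mean
luminance `μ_cc,i` is grown by region growing; a pixel joins when
`I(x) > c · μ_cc,i`. The segmentation is `S_spec ∪ S_lobe`.

**Hybrid closed contour**: Canny edges on luminance are closed
morphologically; regions of the edge-map complement not reachable from the
image border are *enclosed components*. An enclosed component containing a
cone-thresholded pixel is a **Type 2** reflection (small, bright,
step-edged) and is segmented by its contour. Thresholded components with
no closed contour are **Type 1** (large, clipped center, slow radial
decay) and receive lobe growing. Remaining enclosed components are
**Type 3** candidates — weak reflections invisible to thresholds — and are
kept when four strict constraints hold: mean interior luminance `> t_av`,
interior-minus-surround drop `> t_diff`, and size strictly inside
`(t_cc_min, t_cc_max)`. The final mask is
`S_Type1 ∪ S_Type2 ∪ S_Type3`.

**Evaluation**: pixel-level Jaccard index `tp/(tp+fp+fn)` (mean and
quartiles over images), object-level per-type sensitivity (a ground-truth
reflection is detected if the prediction touches it), positive predictive
value `tp/(tp+fp)` over predicted components, and exhaustive grid-search
parameter optimization by mean Jaccard.

## Worked example

```r
library(specseg)

# a 128x128 liver-like scene: 2 large clipped (Type 1), 3 bright
# step-edged (Type 2), 4 weak (Type 3) reflections with ground truth
scene <- generate_scene(scene_spec(seed = 42))
scene
#> <specseg_scene> 128 x 128, 9 reflections (2/3/4 of Types 1/2/3), seed 42

res <- hybrid_segment(scene$image,
                      cone = cone_params(x0 = 140, a = 0.5),
                      contour = contour_params(canny_low = 2.5,
                                               canny_high = 5,
                                               closing_radius = 2),
                      constraints = type3_constraints(t_av = 60, t_diff = 8,
                                                      t_cc_min = 3))
res
#> <specseg_segmentation> 128 x 128 | components: 3 Type 1, 2 Type 2, 3 Type 3 | union area 554 px

tidy(res)          # one row per detected component
match_reflections(res$union, scene$labels)$per_type
#> # A tibble: 3 x 3
#>    type detected total
#>   <int>    <int> <int>
#> 1     1        2     2
#> 2     2        3     3
#> 3     3        3     4
jaccard(res$union, Reduce(`|`, scene$labels$mask))
#> [1] 0.4601283
autoplot(res)      # per-type masks as a ggplot
```

The full comparison protocol — simulate a corpus, optimize every
detector's parameters by mean Jaccard, evaluate each at its optimum:

```r
bench <- run_end_to_end(n_images = 20, seed = 1)
bench$report
```

On this corpus the three thresholding detectors find every Type 1 and
(gray/cone) every Type 2 reflection but no Type 3 at their Jaccard-optimal
settings, while the hybrid recovers ~70% of the Type 3 reflections and
lifts the average per-type sensitivity from 0.67 to 0.90 — the qualitative
behaviour that motivates the hybrid design.

A command-line wrapper for shell use is installed at
`system.file("cli", "specseg.R", package = "specseg")` with
`segment | evaluate | optimize | simulate | bench` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default 20-scene corpus from the given seed, re-runs the
per-method grid optimization and evaluation from scratch, and prints the
comparison table (the JSON output records the run).

## Limitations

The synthetic scenes are a designed stress test, not photorealistic
endoscopy: no lens distortion, smoke, fluids or motion blur, and clinical
performance numbers cannot be inferred from them. See the methods
vignette (`vignettes/specular-segmentation.Rmd`) for the generator's
design and the reasoning behind every default.
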