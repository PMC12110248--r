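---
title: "Gray-value profiling of meibomian glands: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-value profiling of meibomian glands: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meibotrace)
```

## The measurement problem

Infrared meibography images the inner surface of the everted eyelid; healthy
meibomian glands appear as bright, quasi-vertical stripes on the darker
tarsal plate, and gland atrophy shows up as stripes that are missing or
truncated from the distal (upper) edge. Clinical grading of these images is
still largely visual. `meibotrace` implements a fully automated
quantification: it turns the image into a small set of per-eye numbers — the
number of long, medium and short glands (`N_L`, `N_M`, `N_S`), the mean
gland width per class (`AveWidth`), and a single atrophy score

$$\mathrm{AtrophyIndex} \;=\; \frac{N_L - (N_M + N_S)}{N_T},
\qquad N_T = N_L + N_M + N_S,$$

which spans $[-1, 1]$: $+1$ when every visible gland runs the full depth of
the everted field, $-1$ when every gland is shortened.

The method deliberately avoids dense segmentation. Instead it samples
one-dimensional gray-value profiles along a few lines that follow the lid
shape, detects glands as intensity peaks on each profile, and then solves a
small combinatorial problem — which peaks on different lines belong to the
same gland — as a sequence of shortest-path queries on a layered graph.

## Inputs and coordinate conventions

Two images of identical size are required: the grayscale meibography frame
(nominally 1280 × 720) and a binary eyelid mask whose foreground marks the
everted tarsal plate (on the originating device this mask comes from the
built-in alignment overlay; here it is simply an input). Throughout the
package an image is a base-R numeric matrix `img[y, x]` with 8-bit values,
row 1 at the top; `x` is the column and `y` the row, so "deeper into the
lid" means increasing `y`. All distances and thresholds are in pixels at the
native resolution.

## Contrast-enhancement chain

`preprocess_pipeline()` applies six stages in a fixed order; each stage
preserves dimensions and the `[0, 255]` range, each is individually
toggleable for ablation, and all parameters live in `mg_config()`:

1. **Histogram centering** (`center_target = 100`): under-illuminated frames
   are shifted additively so the mask-foreground mean lands on 100. Only
   darker-than-target frames are shifted (brighter frames pass through);
   clipping at the range ends can leave the achieved mean slightly off
   target, which is why the contract is "within ±1 plus clipping loss".
2. **Specular-reflection inpainting**: the light reflex of the wet lid
   saturates the sensor. Saturated pixels (`saturation_floor = 250`) are
   grouped into 8-connected components; a Canny-style edge response (3 × 3
   Sobel aperture, hysteresis thresholds at the two extremes 0 and 255,
   reduced by the zero lower threshold to the strong directional maxima)
   localizes the reflex, and each confirmed component is filled with the
   rounded mean of its contour — the 8-neighbour ring just outside it. The
   edge map is only ever a locator; the working image is never replaced by
   it. A component with no contour (one covering the whole frame) falls back
   to the foreground mean with a warning.
3. **Dark suppression** (`dark_threshold = 50`, strict `<`): genuinely dark
   pixels become pure black, sharpening the gland/tarsus separation. The
   comparison direction at exactly 50 is not self-evident from the rule's
   usual phrasing; the strict reading is used and configurable.
4. **CLAHE** (`clip_limit = 12`, `grid = 20 × 20` tiles): removes the slow
   illumination gradient across the lid while the clip limit bounds noise
   amplification. The image is edge-padded to a grid multiple and cropped
   back; images too small for the grid fall back to the minimal 2 × 2 grid.
5. **Gray-level closing** (disc of diameter 5): removes small dark holes
   inside gland bodies; the output is pointwise ≥ the input and idempotent.
6. **Global histogram equalization**: the cumulative-histogram rule with the
   minimum occupied bin anchored at 0 and the maximum at 255, separating
   background from foreground. Constant images are returned unchanged.

## Profile lines and sampling

The mask's bounding columns are split into 5 equal-width vertical zones. In
each zone the band's top and bottom boundary rows are estimated as the
*median* of the per-column extremes; the median is used rather than the
zone-wide min/max because on a curved lid the extreme rows come from
different columns and systematically pull the anchors upward — far enough,
in testing, to push the shallowest line out of the band. An anchor is placed
at `top + depth × (bottom − top)` at each zone's horizontal center for each
of the four depth fractions (0.10, 0.45, 0.55, 0.75), and consecutive
anchors are joined by straight segments, extended flat to the foreground's
ends. The result is four piecewise-linear lines that follow the lid.
Sampling is one gray value per integer column (the line's interpolated row
is rounded to the nearest pixel), matching the "gray value over x position"
reading of a profile.

## Peak detection

Each profile is smoothed with a linear (order-1) Savitzky–Golay filter of
window 11 — for a symmetric window this equals a moving average — and
normalized to `[0, 1]` by division by 255. Local maxima with prominence
≥ 0.1 *on this normalized scale* are gland candidates (0.1 of the full gray
range ≈ 26 levels; interpreting the threshold on raw gray levels would make
it absurdly permissive). An exploratory moving average with window 200 is
retained as a configurable alternative smoother but is not the default.

**Width.** The reported gland width is the interpolated width of the peak at
half its height *above its own base*, i.e. at the evaluation level
(apex − prominence/2). Two details matter:

* Half-height is referenced to the peak's base rather than to zero. On a
  tarsus baseline the two definitions diverge badly: a Gaussian stripe of
  scale $\sigma$ and amplitude 90 on a baseline of 60 has a
  base-referenced half-height width of $2\sqrt{2\ln 2}\,\sigma \approx
  2.355\sigma$ (the FWHM), but an absolute-half-height width of roughly
  $3.8\sigma$. Only the base-referenced reading recovers the closed-form
  FWHM, which is what the validation suite checks.
* Widths are measured on the **raw** (unsmoothed, normalized) profile at the
  location found on the smoothed one. The window-11 boxcar adds
  $(11^2-1)/12 = 10$ px² of variance to the stripe cross-section, inflating
  a $\sigma = 5$ stripe's FWHM by ~18%; measuring on the raw profile removes
  this bias while detection still benefits from smoothing.

Peaks closer than 10 px (strict) are double detections of one gland and are
fused left-to-right, repeatedly, into a peak at the rounded midpoint with
the *sum* of the two widths (so a chain of mutually close peaks collapses
with accumulated width); the fused height is the maximum of the pair
(configurable to the mean — the choice is not dictated by the fusion rule
itself). Peaks wider than 90 px (strict) are background structures and are
dropped. The validity gate `min_width = 2` px uses the same width.

## Gland tracing

Peaks become nodes of a layered graph: one layer per profile, no edges
within a layer, full bipartite edges between consecutive layers weighted by
the Euclidean pixel distance between peaks, plus a zero-weight supersource
above the top layer and supersink below the bottom one. Dijkstra's algorithm
(via igraph) finds the minimum-weight source-to-sink path; its length — the
sum of the real edge weights, the virtual ones being zero — is the gland
length. Among equal-length shortest paths the lexicographically smallest
node-id sequence is taken, making extraction deterministic.

Extraction proceeds in phases:

1. **All four layers.** Extract the shortest path; accept it as a gland
   while its length is ≤ 100 px, remove its nodes, repeat. The stopping rule
   ("stop once the minimal path exceeds the threshold") is genuinely
   ambiguous in direction; both readings are implemented
   (`tracing$accept_leq`) with accept-≤ as default, consistent with the
   two-layer phase where *shorter-than* threshold edges are glands — both
   thresholds screen out implausibly long diagonal connections.
2. **Top layer dropped.** The supersource reattaches to the new top layer
   and extraction repeats over three layers with the same 100 px threshold
   (no separate value is specified for this phase; the same screening logic
   applies). Glands shorten from the distal edge of the everted field, which
   is why it is the *top* layer that is removed; the symmetric variant
   (dropping the bottom layer) is not part of the procedure.
3. **Bottom two layers.** Every remaining adjacent-layer edge strictly
   shorter than 60 px becomes a two-node gland, taken greedily shortest
   first with node removal.

A gland's label follows the number of layers it spans: 4 → L, 3 → M,
2 → S. An empty intermediate layer disconnects the graph rather than being
bridged, so no gland can "skip" a profile. The absolute 100/60 px thresholds
tie the method to the native image scale: they presuppose inter-profile
spacings well under 100 px, i.e. an everted band whose vertical extent is on
the order of 100–200 px in a 720-row frame. Both thresholds are config
values for other scales.

## Census

A gland carries one width per member peak; its summary width is their mean
(configurable to median). `AveWidth` of a class is the mean of the summary
widths over that class's glands and is *absent* (`NA`), not zero, for an
empty class, so cohort averages are not dragged down by empty cells. The
atrophy index is computed from the counts; it is undefined (an error from
`atrophy_index()`, `NA` in a census) when no gland was found.

## The synthetic-scene generator

`synth_truth()` / `synth_render()` produce ground-truthed phantoms for
validation: a curved eyelid band (parabolic bow 40 px, vertical extent
140 px — a realistic everted strip, and consistent with the 100/60 px
path-length thresholds above) on a 1280 × 720 canvas, tarsus gray 60,
surrounded by skin-gray 75 (an infrared frame has no black void around the
lid), glands as Gaussian-profile stripes (σ ∈ [5, 15] px, amplitude
90 ± 15) truncated at a class-determined fraction of the band depth, at an
anatomical center-to-center pitch of 50–80 px (≈ 1–1.5 mm at this
magnification) with at least 40 px clearance between center paths and a
small (≤ 5 px) tilt. The visible band hugs the gland field plus a 30 px
flank on each side — a lid showing few glands exposes a correspondingly
narrow strip. Optional ingredients: saturated reflection discs (value 255),
a multiplicative left–right illumination gradient, and additive Gaussian
noise (default sd 5), all driven by one explicit seed; the same truth
renders bit-identically.

Class intents map to covered depth fractions drawn safely inside each
class's admissible interval (L: 0.95–1.00 of the band depth, M: 0.63–0.88,
S: 0.48–0.53), so that pixel rounding can never flip which profile lines a
stripe crosses; a stripe ending exactly on a line counts as crossing it,
matching the renderer's inclusive truncation. `expected_census()` derives
the ground-truth census from these crossings with the same census formulas
the pipeline uses, and takes the closed-form FWHM $2.355\sigma$ as each
gland's expected width.

**What the phantom does not emulate** — and hence what passing tests do not
show about clinical data: real tarsus texture and vasculature (the phantom's
tarsus is flat plus i.i.d. noise), conjunctival prolapse and incomplete
eversion (only expressible here as mask irregularity), gland branching and
tortuosity, and device-specific optics. One consequence observed during
validation is worth stating plainly: in band regions with no gland content
(above shortened glands), CLAHE at clip limit 12 amplifies noise extremes
into occasional spurious peaks, which can promote a medium gland to long
when such a peak lands within reach of the top profile; over twenty clean
phantom scenes this affects ~2–3% of glands. This mirrors the method's
documented sensitivity to image quality rather than a phantom-specific
artifact, but its *rate* on real lids cannot be inferred from the phantom.

## Validation suite and problem sizes

The test suite validates each stage against brute-force oracles written by
definition (exhaustive local-maxima/prominence scanning; exhaustive
enumeration of all source-to-sink paths) on randomized inputs, and the whole
pipeline against the generator's ground truth on twenty seeded clean scenes
at full 1280 × 720 resolution (6–12 glands each, noise sd 5, no
reflections): the gland count must be recovered exactly on every scene, at
least 90% of gland class labels must be correct overall, and the mean
absolute atrophy-index error must stay within 0.1. The index tolerance is
deliberately a suite mean: the label criterion itself tolerates up to 10%
flips, and a single L↔M flip in an 8-gland eye moves that eye's index by
0.25, so a per-scene ±0.1 bound would contradict the label allowance.
Stability is checked by re-rendering one truth under three noise seeds
(class counts may move by at most 1) and by adding a reflection disc away
from the stripes (census unchanged by more than one gland).

## Known limitations

* The 100/60 px tracing thresholds and the 20 × 20 CLAHE grid are tuned to
  the native 1280 × 720 scale; other magnifications need rescaled configs.
* Four profile lines discretize gland length coarsely; glands crossing fewer
  than two lines are undetectable by construction.
* The mask is trusted as given; poor eversion or prolapse degrade results
  exactly as they do for the underlying measurement idea.
* Per-gland widths mix layers with one summary number; within-gland width
  gradients are not reported.
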