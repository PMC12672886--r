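---
title: "Methods: stereo sizing, ripeness scoring and yield clustering"
author: "tomatoPheno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo sizing, ripeness scoring and yield clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomatoPheno)
```

`tomatoPheno` turns detector output (bounding boxes on an RGB frame) plus
a pixel-aligned depth map into per-fruit phenotypes and per-plant yield
figures. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic test bed does and
does not demonstrate.

## Geometric model and its assumptions

The camera is an ideal pinhole: a metric extent $L$ at depth $z$ spans
$L f / z$ pixels for focal length $f$ in pixels. Under that model a box
of pixel extents $(w, h)$ at depth $z$ has metric size
$w_\mathrm{real} = w z / f_w$, $h_\mathrm{real} = h z / f_h$, and the
box centre back-projects to camera coordinates
$X = (c_x - p_x) z / f_w$, $Y = (c_y - p_y) z / f_h$, $Z = z$
(millimetres throughout; image origin top-left, x right, y down; boxes
stored centre+extent, with VOC/YOLO corner conventions converted at
I/O). Assumptions worth stating:

* the depth map is pixel-aligned to the RGB frame; no re-registration is
  attempted, and lens distortion is assumed corrected upstream;
* depth counts of zero (and non-finite values) mean "no measurement",
  as stereo devices commonly emit;
* the fruit fills its box reasonably well, so the box extent is a proxy
  for the fruit extent.

**Depth sampling.** The depth of a detection is the median of valid
counts inside the box shrunk to 50% of its extent about the centre,
times `depthScale` (mm per count). The shrink excludes background caught
at box corners; the median resists the remaining contamination — up to
half the sampled pixels can be background before the estimate moves. A
box with no valid count yields an invalid measurement (flagged, never an
exception), so one bad detection cannot abort a scene.

**Diameter.** The default estimator is the arithmetic mean
$(w_\mathrm{real} + h_\mathrm{real}) / 2$. A variant that re-multiplies
the already-metric extents by $z / (f_w + f_h)$ is retained behind
`mode = "literal"` for fidelity with formulations that write the
diameter that way; it is dimensionally inconsistent (the result scales
with depth) and the mean is the only reading under which a projected
sphere round-trips to its true diameter — a property the test suite
asserts to machine precision. The two coincide exactly when
$z = (f_w + f_h) / 2$.

**Volume.** Fruits are idealised as spheres,
$v = \tfrac{4}{3}\pi (d_\mathrm{real}/2)^3$, scaled by a cultivar
ellipticity factor $k$. Values of $k$ outside the typical 0.85–0.95
band are accepted with a warning; $k \le 0$ is an error. The default is
$k = 0.9$, the band midpoint.

## Ripeness scoring

Three component scores, each mapped to $[0, 1]$, are fused by convex
weights and thresholded into immature / ripe / overripe.

**Colour.** The dominant hue of a detection is the mode of 1°-binned hue
over pixels inside the inscribed ellipse of the box with saturation
$\ge 0.3$ and value $\ge 0.2$ (ties go to the lower bin; the cutoffs
drop shadowed and washed-out pixels, the ellipse drops box corners). The
piecewise score is 1.0 in the red bands $[0°,20°) \cup [330°,360°]$,
$h_1 + c_1(40 - H)$ in the orange/brown band $[20°,40°)$, and
$h_2 + c_2(H - 50)$ in the green/yellow band $[50°,100°)$, with defaults
$h_1 = 0.5$, $h_2 = 0.2$, $c_1 = 0.015$, $c_2 = 0.01$. Hues in
$[40°,50°)$ and $(100°,330°)$ belong to no band: the model assigns a
configurable `fallbackScore` (default 0) and sets a flag rather than
extrapolate — there is no principled rule to extrapolate with. HSV is
used because hue is largely invariant to illumination changes, which a
greenhouse supplies in abundance.

**Size.** Against cultivar thresholds
$d_\mathrm{unripe} < d_\mathrm{ripe} < d_\mathrm{overripe}$ (default
50/70/85 mm for a beefsteak type) the score ramps as
$s_1 d / d_\mathrm{unripe}$ below the first threshold, as
$s_1 + s_2 (d - d_\mathrm{unripe}) / (d_\mathrm{ripe} - d_\mathrm{unripe})$
between them, and decays as
$1 - s_3 (d - d_\mathrm{ripe}) / (d_\mathrm{overripe} - d_\mathrm{ripe})$
beyond, floored at zero ($s_1 = 0.3$, $s_2 = 0.7$, $s_3 = 0.2$).
Numerical choices: the branch inequalities as commonly written are
strict and leave the threshold diameters unassigned, so boundaries are
attached to the middle branch — value-identical, since the function is
continuous there (asserted numerically for random valid thresholds);
an overripe threshold equal to the ripe one would zero the third
branch's denominator, so profiles require strict inequality at load
time.

**Shape.** With deviation $\delta = |r - 1|$ of the aspect ratio $r$:
$1 - p_1\delta$ for $\delta \le 0.3$, $0.7 - p_2(\delta - 0.3)$ for
$0.3 < \delta \le 0.7$, $0.4 - p_3(\delta - 0.7)$ floored at zero
beyond ($p_1 = 0.2$, $p_2 = 0.3$, $p_3 = 0.4$). The breakpoints are
genuine discontinuities (0.94 vs 0.7 at $\delta = 0.3$; 0.58 vs 0.4 at
0.7) and are implemented literally — they encode a hard penalty for
leaving the "plausibly a tomato" shape regime. Contour circularity
($4\pi A / P^2$ of the largest mask component, with the perimeter taken
as the Euclidean length of the traced boundary polygon) is reported as
a diagnostic only; no defined mapping takes it into the fused score.

**Fusion and classification.** $S = \omega_c S_\mathrm{color} +
\omega_d S_\mathrm{size} + \omega_s S_\mathrm{shape}$ with
$\omega_c + \omega_d + \omega_s = 1$. The defaults 0.5/0.3/0.2 follow
the qualitative ordering that colour is the most discriminative maturity
cue and shape the least (shape mostly flags overripe deformation); they
are profile-overridable, as any weighting should be adapted to cultivar
and use. Classification is immature below 0.4, ripe on $[0.4, 0.7]$
(both boundaries inclusive on the ripe side), overripe above.

**A deliberate inconsistency, and how the package resolves it.** A
textbook ripe fruit — red hue (colour 1.0), standard size
($S_\mathrm{size} \approx 0.9$), round ($S_\mathrm{shape} \approx 1$) —
fuses to roughly 0.95, which the thresholds label *overripe*. The
attribute bands and the score thresholds, taken together, are therefore
not mutually consistent, and the package does not paper over this: the
score model is implemented literally, and ground truth in the synthetic
scenes is defined as *the classifier applied to the true attributes*
(the only self-consistent reading), with the nominal sampling stage
recorded alongside. Users who want band-consistent stage labels can
remap the classification thresholds in their cultivar profile.

## Plant clustering and yield

Fruit 3D centroids are clustered with DBSCAN, written in full here
(standard semantics: core points have at least `minSamples` neighbours
within `eps`, self included; clusters are maximal density-connected
sets; the rest is noise) because it is part of the method proper. The
implementation is validated against an independent oracle — connected
components of the `eps`-threshold graph, via igraph — with which it must
agree exactly when `minSamples = 1`, and cluster ids are canonicalised
by smallest member index so the partition is reproducible under input
reordering.

Defaults: `eps = 300` mm (fruits on one plant hang within a few hundred
millimetres of each other; adjacent plants in a managed row sit farther
apart) and `minSamples = 1`, so an isolated fruit is its own plant
rather than noise. Noise can only arise when `minSamples > 1` and is
always reported, never dropped.

A design choice worth recording: one printed formulation clusters the
feature triple $(w_\mathrm{real}, h_\mathrm{real}, z)$ — two fruit
*sizes* and a depth. Size is not a spatial coordinate, and same-plant
fruits are only proximal in actual space, so the default clusters the
back-projected centroids $(X, Y, Z)$; `literalCoords = TRUE` reproduces
the printed triple for comparison.

Per plant, the package reports the fruit count and the volume-based
estimate $\omega \sum_i v_i$. The density $\omega$ (default
$10^{-5}\,\mathrm{mm}^{-3}$, stored per cultivar) is a calibration
constant whose units make the product a count only if calibrated
per-volume; no claim of biological accuracy is attached to the default,
which is why the count is always reported alongside.

## Detector component numerics

Three architectural components are provided as framework-independent
reference implementations, each checked against an independent oracle:

* **Ghost composition**: a dense convolution produces $m$ intrinsic
  maps; each is expanded to $s$ maps by cheap per-map linear kernels,
  the first fixed to the identity so the intrinsic map itself is
  emitted (the indexing of the concatenated output requires $s$ maps
  per intrinsic map, and the identity choice is what makes the ghost
  count a superset of the intrinsic maps). Channels-first, zero
  padding, stride 1, forward only. Tested to $10^{-6}$ against a
  triple-loop convolution.
* **AReLU/ELSA**: slope $C(\alpha) \in [0.01, 0.99]$ for negative
  inputs, $1 + \sigma(\beta)$ for non-negative ones — ReLU provides the
  base nonlinearity and the learned attention adds a residual, hence
  the $1 +$ on the positive branch while the bare attention weight is
  $\sigma(\beta)$ alone. Analytic partials (zero for $\alpha$ at clamp
  saturation) are verified against central finite differences at
  relative $10^{-5}$, and a small gradient-descent demo recovers known
  slopes from activation pairs.
* **EIoU / Focal-EIoU**: the centre-distance term uses the squared
  Euclidean distance between box centres normalised by the squared
  enclosing-box diagonal; width and height get separate squared-
  difference penalties. The focal weight $\mathrm{IoU}^\gamma$ is a
  plain multiplicative factor (no gradient-stopping semantics), with
  $0^\gamma := 0$ for $\gamma > 0$ and default $\gamma = 0.5$ —
  unstated in common formulations, chosen as a mild emphasis;
  configurable.

## The synthetic test bed

`generateScene()` renders fruits as filled axis-aligned ellipses (each
the inscribed ellipse of its own box) at pinhole-projected positions,
into an RGB frame and a depth map carrying each fruit's depth in mm;
farther fruits are drawn first, so nearer fruits occlude naturally in
both channels. Hue, diameter and aspect ratio are drawn from the
cultivar's per-stage bands at least 10% of the band width inside the
edges; aspect ratios additionally stay 0.04 away from the shape-score
breakpoints in $|r-1|$, and attribute draws whose fused score lands
within 0.05 of a classification threshold are resampled. Those margins
are the generator's definition of "away from decision boundaries": the
score thresholds and shape breakpoints are the discontinuities at which
a one-pixel measurement difference could flip a label. Immature
diameters are sampled from the detectable part of the band (above
~20 mm) — smaller fruitlets would not be detected in practice and their
boxes would be too small for the 50% depth sub-box to stay inside the
rendered ellipse. The default scene (640×480 px, $f = 700$ px, two
plants 700 mm apart at 1.5 m, five fruits per plant within ±140 mm of
the plant centre) keeps plants several `eps` apart and fruits well
within `eps` of plant-mates, and everything is a deterministic function
of the seed.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: leaves, stems and cluttered backgrounds;
specular highlights and mixed illumination (illumination variation is
value-channel only, by the HSV rationale); partial fruit visibility
other than box-overlap occlusion; depth noise, quantisation and stereo
shadow; non-ellipsoidal fruit shapes. End-to-end recovery on synthetic
scenes demonstrates internal consistency of the chain, not field
accuracy.

## Problem sizes and runtime choices

The test suite runs the geometry round-trip on 1000 random
sphere/depth/intrinsics triples (machine precision), the DBSCAN oracle
on 100 random point sets of up to 200 points, the gradient checks on
1000 random inputs, the ghost oracle on 4×8×8 tensors, and the
end-to-end recovery on the default 2×5 scene — sizes chosen so the
whole suite completes in well under a minute on one CPU while exercising
every branch. Scene images are rendered at 640×480; nothing in the
implementation depends on that size.

## Known limitations

* Depth and RGB must be pre-registered; there is no disparity
  computation or alignment.
* The dominant-hue estimator assumes the fruit dominates the inscribed
  ellipse of its box; heavy occlusion by leaves violates this and the
  colour score degrades accordingly.
* The greedy confidence-ranked matcher in `detectionPrAp()` is the
  standard evaluation choice; in adversarial geometries it can differ
  from exhaustive TP-maximising assignment (the suite checks agreement
  on realistic, well-separated instances).
* $\omega$-based yield is only as good as its cultivar calibration;
  uncalibrated, use the per-plant counts.
* Aspect ratio conflates true fruit shape with box noise at small box
  sizes; the shape score carries the smallest fusion weight partly for
  this reason.
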