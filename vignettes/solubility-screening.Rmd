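---
title: "Visual solubility screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual solubility screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solscreen)
```

## The screening problem

Whether a solute has fully dissolved is decided in many laboratories by a
person looking at a flask. `solscreen` automates that decision from two
photographs of the flask taken on a tablet that displays, in turn, a plain
white background and a checked grid. The solution seen through the flask
bottom forms a circular region whose appearance carries the dissolution
state:

* **DS** (dissolved): the liquid is clear; the background shows through
  unchanged.
* **US1** (undissolved, cloudy): the solute is barely dissolved and
  scatters light; the solution is turbid, typically darker toward the
  center, and it obscures the checked grid.
* **US2** (undissolved, particulate): undissolved solute persists as dark
  particles, from isolated fine grains to clumps.

Nine handcrafted features are extracted per sample and a small classifier
(dense network or linear SVM) maps them to the three classes. Handcrafted
features are deliberate here: labelled industrial solution images are
scarce, and the decisive evidence can be a handful of dark pixels that
end-to-end models at this data scale routinely miss.

## Pipeline and features

Each capture is converted to 8-bit gray (BT.601 luma) and the solution disk
is located with a gradient-voting circle Hough transform. Detection uses a
median-blurred copy; the accumulator threshold starts conservatively and
decays geometrically (factor 0.8) until candidates appear, and the
candidate closest to the image center wins — flask walls, reflections, and
background structure rarely sit dead center. Candidates are refined by an
algebraic (Kåsa) circle fit over radially aligned edge pixels in the modal
distance band, iterated three times; a candidate whose refined circle lacks
angular support (under half the circumference) is rejected as a vote
pile-up and the next candidate is tried. Everything outside the closed disk
is set to zero.

A Moiré-suppression stage runs on both masked captures before analysis.
Display-capture interference (Moiré) produces dark stripes and dots that
masquerade as particles. The stage upscales the ROI 2x (bilinear), applies
a two-step contrast stretch `dst' = clip(1.2 src)`,
`dst = clip(2 dst' - 128)` — which saturates every pixel at or above
intensity 160 to white, stripping low-amplitude stripes off the bright
liquid field while darkening genuine particles — then denoises with
non-local means (strength 10, patch 7, search window 21) and downscales by
2x2 block averaging so downstream coordinates are unchanged. Patch
distances are noise-compensated by `2σ²` (σ = 5 by default, the assumed
post-stretch sensor noise), the classic correction without which the filter
under-weights genuinely matching noisy patches. Upscaling is bilinear; the
downscale is an exact block mean so that a factor-2 round trip preserves
geometry.

The nine features, in canonical order:

| Feature | Capture | Analysis |
|---|---|---|
| MMG, MSG, SMG, SSG | white | grid homogeneity |
| minimum value, curvature, MSE | white | radial profile |
| number of particles | white | particle amount |
| superposition ratio | checked | superposition |

**Grid homogeneity (GHA).** The square circumscribing the ROI is tiled by
cells of side `n`; a cell is kept only if all four corner pixels lie
strictly inside the circle. Per-cell intensity mean and population standard
deviation are summarized as MMG (mean of means), MSG (mean of SDs), SMG (SD
of means), SSG (SD of SDs); population (divide-by-count) conventions are
used throughout. Tiling starts at the square's top-left corner and partial
cells at the right/bottom are discarded. One discretization consequence is
worth knowing: a square of even pixel width centered on an integer pixel is
necessarily one pixel asymmetric, so horizontally flipping a capture and
re-running the grid construction reproduces the features only to within
that one-pixel phase (a few percent on textured scenes); the features are
exactly flip invariant over the mirrored cell set, which is what the test
suite asserts.

**Radial profile (RPA).** Twelve diameter profiles are sampled through the
circle center at 30° steps (`L = 2r` bilinear samples each; sampling rays
of the original image is mathematically identical to rotating the image and
reading the horizontal diameter). The pointwise mean profile is fitted by
the even quadratic `y = a x² + c` on the normalized abscissa `x ∈ [-1, 1]`
via closed-form normal equations. Curvature `a`, minimum `c`, and the mean
squared residual are the features: clear solutions give a flat, tight fit;
cloudy ones a deep parabola; particles inflate the residual. Samples within
3 px of the rim are excluded from the fit because bilinear interpolation
there mixes in masked-out and flask-wall pixels.

**Particle amount (PAA).** Fine particles are pixels strictly below their
Gaussian-weighted local mean (block 151, σ tied to the block) minus an
offset `c = 10`; the window is computed after replacing outside-ROI pixels
with the ROI mean so the rim step cannot bias it. Clumps are segmented by a
four-orientation Gabor bank (wavelength 24 px, envelope σ 8, aspect 0.5).
The maximum absolute response is rescaled to [0, 255] against an absolute
reference — the response of the kernel's positive lobe on a full-contrast
feature — and thresholded at 51, then closed with a disc of radius
wavelength/2 to fill clump interiors and intersected with dark in-ROI
pixels. The absolute rescale matters: normalizing to the scene maximum
would let a dots-only scene self-normalize its dots over threshold and
double-count them (and would amplify pure noise on clean scenes). With this
design, isolated fine dots are left entirely to the adaptive threshold, a
40 px blob is covered completely by the clump stage, and a structureless
ROI produces nothing. The feature is the sum of both masks' pixel counts
inside the ROI eroded by 5 px (the circle edge itself is a strong
local-contrast structure); overlapping pixels count twice, matching the
additive definition.

**Superposition (SA).** On the checked capture the visible grid is
detected (adaptive threshold, Canny edges at 50/150, ρ–θ Hough accumulator
with per-line segment extraction at minimum length 20 px and maximum gap
5 px, then 3×3 dilation and closing). Row/column projection profiles yield
up to six line coordinates per axis by iterated peak picking with ±25 px
non-maximum suppression; a local centroid refines each peak because the
dilated strokes plateau the profile. The four coordinates per axis closest
to the ROI center are drawn as the predicted nine-part grid at a fixed
4 px width, and the feature is `|predicted ∩ detected| / |predicted|` — the
fraction of the expected pattern actually seen. A fixed predicted width
(rather than one estimated from the detected strokes) keeps the denominator
independent of detection thickness, without which the ratio jitters
non-monotonically along a turbidity ramp. Fewer than four peaks on either
axis means the pattern is essentially gone and the ratio is 0 by contract.
Intersection over the prediction was chosen over IoU because the quantity
of interest is how much of the expected pattern is obscured.

## Classifiers

Features are z-scored per column (population SD; the scaler is fitted on
training rows only and reused verbatim on test rows; a zero-variance
feature is an error naming the feature). The network is fully connected
9 → 64 → 128 → 256 → 3 with ReLU hidden activations and a softmax output,
trained with cross-entropy and Adam at learning rate 0.001 (batch 32,
100 epochs by default; He-scaled initialization; fully deterministic given
the seed). No deep-learning framework is required — at these sizes the
forward/backward passes are a few small matrix products. The linear SVM
(C = 30) wraps `e1071`'s binary solver one-vs-rest, predicting the class
with the largest decision value. One practical detail: libsvm orients
decision values by the first class encountered in the data, not by factor
levels, so each binary model's sign is calibrated on its training rows.

Evaluation reports accuracy, the 3×3 confusion matrix, and one-vs-rest
TPR = TP/(TP+FN) and PPV = TP/(TP+FP) per class; the PPV of a class never
predicted is reported as 0 with an explicit flag rather than NaN.
Cross-validation is stratified by class, with the scaler re-fitted inside
each training fold to avoid leakage. Flip augmentation (identity,
vertical, horizontal, both; times two backgrounds = eight images per
sample) is available for training data; by default cross-validation runs
on unaugmented rows so that near-duplicate copies of one sample can never
straddle folds.

## The synthetic scene generator

The original validation data for this kind of screening is private, so the
package ships a parametric renderer that makes every stage testable with
pixel-level ground truth. A scene is a circular solution disk on a white or
checked background (grid pitch 48 px, line width 4, intensities 255/40 at
the default 320×320 rendering), with:

* a flask-rim annulus (3 px, intensity 70) just outside the disk — the
  glass wall that makes even a perfectly clear solution visible to the
  detector; it is drawn strictly outside the closed disk, so a clear scene's
  interior equals the background exactly;
* turbidity `t ∈ [0, 1]`: the background seen through the liquid is first
  Gaussian-blurred with σ = 4t px (forward scattering destroys transmitted
  detail, not just brightness) and then alpha-blended toward the liquid's
  brightness profile `I(ρ) = c0 + a0 ρ²` (default a flat milky 235);
* hard-rasterized dark particle disks drawn last, so the ground-truth
  particle mask is exact;
* optional additive sinusoidal Moiré stripes, attenuated by `(1 - t)`
  inside the disk (a display grid seen through a turbid liquid loses
  coherence), optional RGB tint, and Gaussian pixel noise (σ = 2 default).

Class parameter defaults are separable by construction: DS draws turbidity
from [0, 0.1] with no particles; US1 from [0.6, 0.95] with a darkened
center (`a0 ∈ [40, 90]`, `c0 ∈ [50, 110]`) and no particles; US2 from
[0.05, 0.5] with 20–2000 particle pixels (mostly radius 1–3 grains, 10%
clumps of radius 6–10). Solution radius is 0.41–0.47 of the frame with a
±6 px center jitter; 30% of samples get Moiré, 30% a mild tint. The
ground truth records the label, the exact particle mask and count, and the
fraction of in-disk check-pattern pixels occluded.

What the generator does **not** emulate: glass refraction and meniscus,
shadows and uneven illumination, camera perspective, sensor demosaicing,
real clump texture (rendered clumps are uniform disks, which the adaptive
threshold segments more easily than real aggregates), and the actual
intensity statistics of any particular chemistry. Passing tests therefore
demonstrate that the pipeline's geometry, algebra, and orderings are
correct and that the method separates the three phenotypes under
controlled conditions — not field performance on laboratory captures.

## Scale-dependent parameters

Two window parameters are tied to capture resolution. At full tablet
resolution (flask diameter around 600 px) the grid cell is 80 px and the
adaptive-threshold block 151 px — the package-level defaults. The default
synthetic scenes render the flask at about 280 px diameter, and the
pipeline configuration scales both accordingly (cell 40, block 75). The
block size matters more than it looks: a Gaussian window spanning most of
the flask is no longer local, and on a convex brightness profile its mean
sits far enough above the center pixels to breach the `c = 10` offset,
flooding the fine-particle mask on perfectly particle-free cloudy scenes.

## Numerical choices and degenerate inputs

* Closed-disk masking (distance ≤ r is inside). A circle fully containing
  the frame masks nothing; one partially overhanging the frame is an error.
* Circle radius search band: [0.15, 0.49]·min(H, W); the detected radius
  lands mid-rim, about 2 px above the true solution radius.
* Hough votes are accumulated at integer pixels and smoothed with a 9×9
  box sum before peak detection; gradient-direction noise otherwise spreads
  the center peak over several pixels.
* The quadratic fit needs at least 3 samples; profiles require r ≥ 16 px.
* A blank frame raises a typed no-circle condition; an undetectable check
  pattern degrades to ratio 0 rather than erroring the batch.
* Feature extraction failures are recorded per manifest row with their
  reason; the batch continues.
* Default problem sizes: module tests run on 160–320 px scenes; the
  end-to-end study set is 100 samples per class at 320×320, about two
  seconds per sample through the full pipeline.

## Known limitations

* The superposition ratio saturates to 0 above roughly t = 0.45 under the
  default scattering model; it separates cloudy from clear but does not
  grade degrees of heavy turbidity (the radial-profile features carry that
  information instead).
* Uniform rendered clumps understate how much real clumps rely on the
  Gabor stage, and overlapping fine/clump detections double-count by
  design.
* The Hough line detector assumes an axis-aligned-ish grid at the 1°
  accumulator resolution; strong perspective distortion of the tablet would
  need a homography step that is out of scope here.
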