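---
title: "Methods: RBC morphometry, deformability and classification at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RBC morphometry, deformability and classification at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Red blood cells (RBCs) are elastic biconcave discs, typically 6-9 um
across. When a field of RBCs immobilized in a soft gel is compressed
gently from above, each cell spreads laterally; how much it spreads is a
direct mechanical readout of its deformability. The measurement this
package implements is entirely image-based: the same field is photographed
before and after compression, each cell is segmented in both frames, and
the per-cell deformation index

$$ D_r = \sqrt{S_d / S_{ud}} $$

is computed from the pixel area after compression ($S_d$) over the pixel
area before compression ($S_{ud}$). Because $D_r$ is a ratio of areas of
the *same* cell measured by the *same* chain, most systematic segmentation
errors cancel; this is what makes the index robust enough to survive a
low-cost optical path.

Alongside mechanics, the package computes the standard morphometric
descriptors used in blood-film work - mean diameter, circularity and the
Feret axis ratio, each with a population distribution width - and fuses
them with a learned image embedding in a small diagnostic classifier. A
method-comparison suite (Bland-Altman, Passing-Bablok, ROC, mountain plot)
covers the statistics used to validate such a device against laboratory
comparators.

No real micrographs ship with the package. Every stage is exercised
against a seeded synthetic scene generator with exact per-cell ground
truth, which is first-class, tested code.

## The synthetic scene generator

`sample_population()` draws per-cell geometry from a `class_profile()`:
diameter from a normal truncated at zero, axis ratio from a normal
reflected into $q \ge 1$, orientation uniform. `apply_stress()` draws a
per-cell $D_r$ from the profile's distribution for the chosen compression
setting and scales the in-plane area by $D_r^2$, shape preserved
(compression is treated as isotropic in-plane; an anisotropic mode was
considered and rejected because the readout is area-based, so in-plane
anisotropy would be invisible to it). Draws that would be non-positive are
resampled, with a retry cap of 100 rounds so a mis-specified profile fails
loudly.

The healthy-class deformability defaults are the device calibration
values: mean 1.194 (SD 0.045) at the low setting and 1.241 (SD 0.033) at
the high setting. All other per-class morphology defaults (macrocytic
cells in megaloblastic anemia, microcytes in iron deficiency,
high-axis-ratio schistocyte-like populations in TTP, spherocyte-trending
aged storage samples, and so on) are package defaults chosen once from
standard blood-film morphology; they are deliberately documented as
calibration placeholders, not published values, and should be re-fit
against local data for any quantitative use.

`render_pair()` places cells uniformly at random with a guard gap of 3
pixels between non-stacked cells (so their rendered masks are provably
disjoint) and renders each as an ellipse with a biconcave radial
intensity profile: bright background (gray 220), dark rim (depth 140) and
a brighter center (concavity constant 0.45), i.e.
$I(\rho) = 220 - 140\,(0.45 + 0.55\rho^2)$ for normalized radius
$\rho \le 1$. The photometric constants are package constants: the
qualitative dark-rim/bright-center appearance is what matters for testing
the hole-filling and thresholding chain, not photometric fidelity. A
configurable fraction of cells is placed deliberately overlapping a host
cell (center distance 0.6-0.95 of the sum of effective radii), emulating
settled, partially stacked cells; both members are flagged `is_stacked`
in the ground truth. A multiplicative linear illumination ramp and
additive Gaussian sensor noise are applied last, and the frame is clamped
to 8 bits. Cell placement is identical in the two frames, as cells are
immobilized in the gel.

Ellipse rendering ties per-cell circularity geometrically to the axis
ratio, so the ground-truth circularity is derived (Ramanujan perimeter)
rather than independently sampled; the `circularity_*` profile fields are
consistent reference values used for checks, not an independent knob.

Default pixel scale is 0.25 um/px, so a 7.5 um cell spans 30 px - enough
for stable perimeter estimation. Every stochastic stage draws its seed
from one master seed; identical configurations are bit-identical.

## Segmentation chain and pinned estimators

`segment_frame()` runs grayscale conversion (ITU-R 601 weights),
percentile contrast rescale (1st/99th percentiles to 0/255; strictly
monotone, so it never reorders intensities), Otsu thresholding with
cells-darker-than-background polarity (invertible by flag), hole filling
(background components not connected to the border; foreground
8-connected, background 4-connected - the standard duality), 8-connected
labeling, and stacked-cell removal.

Pinned numerical choices:

* **Perimeter**: the Crofton 4-direction estimator (boundary intercepts
  along rows, columns and both diagonals, weighted $\pi/8$ with diagonal
  spacing $1/\sqrt2$). It converges to the true perimeter for smooth
  convex shapes - a rasterized disc of radius 30 px gives circularity
  $1.00 \pm 0.03$ - which is exactly the property the circularity
  descriptor needs. The cost is anisotropic shapes: a 10x10 axis-aligned
  square reads about 8% short (36.8 versus 40). Documented tolerance:
  10% on blocky shapes, 3% on disc-like cells.
* **Feret diameters**: caliper widths of the convex hull of the pixel
  *corner* points (rotating-calipers equivalent: hull diameter for the
  maximum, minimum edge-normal width for the minimum), so a single pixel
  has nonzero extent; by convention a single-pixel region reports both
  Ferets equal to the pixel size. Near-circular cells are the worst case
  for the Max/Min ratio: because the maximum picks the luckiest direction
  and the minimum the unluckiest, the ratio of a rasterized disc is
  biased upward - about +4% at 15 px radius and +2% at 30 px radius.
  The recovery tests therefore run at 0.125 um/px, where the bias is
  comfortably inside the 3% recovery budget; users measuring axis ratios
  near 1 should prefer fine pixel scales.
* **Stacked-cell rule**: a region is rejected when pixel area exceeds 1.8
  times the median region area, solidity (area over corner-hull area)
  falls below 0.85, or circularity falls below 0.6; each rule is
  individually switchable and all thresholds are surfaced in the
  configuration rather than hard-coded. With fewer than 3 regions the
  median rule is skipped. Known limitation, established analytically from
  disc-union geometry and confirmed on rendered scenes: a *partially*
  overlapping doublet of below-median-size cells can evade all three
  rules (its union area can sit below 1.8 medians while staying fairly
  convex), so exact count conservation holds on stacking-free scenes and
  for well-separated doublets of typical size, not universally. Removal,
  not splitting, is the intended behavior.
* **Border policy**: regions touching the frame border are flagged and
  excluded from morphometry and pairing by default.

## Morphometry conventions

* **Mean diameter** is the printed device formula $\sqrt{A/\pi}$, kept
  exactly as defined. Note that for a disc of geometric diameter $d$ this
  equals $d/2$ (the equal-area radius); the generator's ground-truth
  `true_diameter` is the geometric diameter, and recovery tests compare
  like with like.
* **Circularity** is $4\pi A/P^2$ with the Crofton perimeter; convex
  regions may overshoot 1 by the estimator tolerance (documented
  $\varepsilon = 0.05$).
* **Distribution width** is the coefficient of variation in percent,
  $100\,\mathrm{SD}/\mathrm{mean}$ with the sample SD ($n-1$), mirroring
  the hematology RDW convention the parameter names evoke; a plain-SD
  mode is exposed for users who read "width" literally.
* The 8-parameter population vector is exposed in a fixed documented
  order: diameter mean/width, circularity mean/width, axis-ratio
  mean/width, $D_r$ mean/width (`population_vector()`).
* **Concentration** converts counts via field area x chamber depth
  (default 20 um, the chip cavity depth) and a user-supplied dilution
  factor; the count-to-concentration mapping is otherwise a free choice.

## Matching and deformability

Cells are matched between frames on centroids alone - areas change under
compression, so area similarity is deliberately not a matching feature.
Candidate pairs are gated at 3 um (gel-immobilized cells barely move);
within each connected component of the candidate graph the
Jonker-Volgenant assignment maximizes the number of matches, then
minimizes total centroid distance. Gating before solving keeps the
assignment exact and fast at thousands of cells, because components are
tiny when cells are immobilized. $D_r$ is computed per matched cell from
pixel areas (the scale cancels); unmatched and stacked-flagged cells are
excluded from the statistics and reported.

On clean scenes the whole chain - simulate, segment, match, $D_r$ -
recovers per-cell truth to well under 2% (typical worst case 0.9% at
0.25 um/px), with the residual dominated by rasterization jitter of the
two area counts. The test suite reproduces the calibration experiment at
its published size (2,362 cells, twelve 250 um tiles) and recovers the
high-setting mean within $4\sigma/\sqrt{n}$.

## The fused classifier

The diagnostic head follows the device architecture exactly: a 32-value
image embedding concatenated with the 8 population parameters forms the
40-wide first fully connected input, followed by hidden layers of 64 and
20 units and a softmax class layer. Dropout (default rate 0.5) acts on
hidden activations during training only. Training runs stratified
random 90/10 development/validation splits, re-shuffled each cycle, with
all inputs standardized by the training-split mean/SD (stored with the
model). The optimizer is full-batch Adam (default learning rate 1e-2,
500 epochs) - the original training hyperparameters are unspecified, so
these defaults were chosen once for reliable convergence of the small
head at desk scale, and all are surfaced in `classifier_config()`.

The image backbone is a deliberate design decision: three convolution
blocks (8, 16, 32 filters with ReLU, average pooling and a global average
pool) whose weights are drawn once from a seeded He-scaled Gaussian and
frozen - a random convolutional feature extractor. Only the fusion head is
trained. Random convolutional features preserve enough image structure
for the fusion contracts to be meaningful while keeping the package fully
trainable offline in seconds, with no downloaded weights and no
deep-learning runtime; an ImageNet-pretrained path would change the
embedding, not the architecture around it. The consequence is stated
plainly: classification power on synthetic data comes mostly from the
8-parameter block, and the image branch contributes weakly informative
texture features. The three ablation variants (parameters only,
parameters + image, + mechanics) are one `features` switch.

What passing the synthetic tests shows: the architecture widths are
enforced (32 + 8 = 40; 224 x 224 inputs from 0.1 mm crops), splits and
training are deterministic under the seed, separable parameter classes
are learned to 100% validation accuracy, label-shuffled data sits at
chance, and adding the mechanical features never hurts
mechanics-separated classes. What it does not show: any claim about real
patient data, for which no images or tables are deposited.

## Method-comparison statistics

* **Bland-Altman**: bias, sample SD of differences, limits of agreement
  fixed at bias +/- 1.96 SD. The difference direction (`y - x` or
  `x - y`) and absolute-versus-percent mode are explicit parameters
  because published comparisons mix conventions (percent for morphology,
  absolute for counts).
* **Passing-Bablok**: the classical shifted-median procedure - all
  pairwise slopes, slopes equal to -1 discarded, median offset by the
  count of slopes below -1; intercept $\mathrm{median}(y - bx)$;
  rank-based confidence bounds from the normal approximation of the
  Kendall statistic. Verified against direct $O(n^2)$ enumeration.
* **ROC**: empirical curve, trapezoid AUC (identical to the Mann-Whitney
  probability with ties counted half - asserted, not assumed), Youden-
  optimal threshold with ties broken toward sensitivity, Clopper-Pearson
  intervals for sensitivity/specificity, DeLong interval for the AUC
  (cross-checked against an independent implementation). All CI methods
  are named in the output because the original software's choices are
  unstated.
* **Mountain plot**: ranked differences with Hazen percentiles
  $100(i - 0.5)/n$, folded above 50; the center is the median difference
  and the reported 5th/95th percentiles use the inverse empirical CDF
  (so integer-valued difference sets report the intuitive values).

## Problem sizes and determinism

The shipped tests run entirely on generated scenes: recovery properties
use 200+ cells per class at 0.125-0.25 um/px in fields of 110-250 um;
the deformability calibration experiment uses 2,362 cells in twelve
tiles; the classifier suite uses 6 classes x 60 samples with one rendered
field each. These sizes were chosen as the smallest at which the
statistical tolerances above are meaningful. Every stochastic path -
sampling, placement, noise, splits, initialization, dropout,
augmentation - flows from explicit seeds, and identical seeds give
bit-identical images, tables and metrics.

## Known limitations

* The generator renders ellipses with a radially symmetric biconcave
  profile; real micrographs show focus drift, halos, debris, platelets
  and white cells, none of which are simulated. Passing recovery tests
  here demonstrates correctness of the computation chain, not robustness
  to every real-world artifact.
* Near-circular axis ratios are biased upward at coarse pixel scales
  (caliper extreme-value effect, quantified above).
* Partially overlapping small doublets can evade the default
  stacked-cell rules (quantified above); tighten `k_area` or `c_min`
  for dense smears.
* The random-feature image backbone is not a trained AlexNet; image-only
  discrimination is weak by design. The optional use of a pretrained
  backbone would require external weights and is out of scope offline.
* Per-class morphology profiles are placeholders to be calibrated by the
  user; only the healthy-class deformability is anchored to published
  calibration values.
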