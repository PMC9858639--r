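---
title: "Calibrated wound assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated wound assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundmetry)
```

This vignette is the package's account of its methods: what is computed,
under which assumptions, which parameters matter, and where the design
was genuinely open and a choice had to be made.

## The problem

Wound healing is monitored by tracking the wound's area and its tissue
composition over repeated clinic visits. Photographs from arbitrary
smartphones are the cheapest measurement device available, but two
quantities needed for comparison are missing from a raw photo: the true
colors (white balance, illuminant and sensor all shift them) and the
physical size of a pixel. `woundmetry` solves both with a single printed
card placed next to the wound: a 75 × 35 mm chart carrying four 12.7 mm
square binary fiducial markers at its corners and a 6 × 4 grid of
6.35 mm color patches — the classic 24-patch color rendition chart — at
its centre.

## Chart model and fiducial dictionary

The chart geometry is parameterized in `chart_spec()`. Two quantities are
not dictated by the printed dimensions and were fixed as package design
choices:

* **Marker bit patterns.** The four markers use a package-defined 4 × 4
  bit dictionary (`"wm4x4"`). Its four patterns were chosen so that all
  sixteen rotations are pairwise distinct, which makes the in-plane
  orientation of the photograph recoverable from any single decoded
  marker; a unit test asserts this property. Users printing their own
  chart render it with `render_chart()`, so renderer and detector share
  one dictionary by construction.
* **Layout margins.** Markers sit 2 mm inside the card corners and the
  patch grid is centred on the card. The derived margins are recorded in
  the render ground truth so the layout is fully reproducible.

Rasterization places the centre of pixel `[r, c]` at physical
coordinate `((c − ½)/ppm, (r − ½)/ppm)`; ground-truth marker corners and
patch centres are therefore exact, bit-stable functions of the spec.

## Automatic calibration

Detection follows the standard square-fiducial recipe: global
thresholding (two candidate thresholds, half the median intensity and
the mid-range, are tried), connected-component labelling, convex-hull
quad extraction, and sub-pixel refinement in which the component's outer
boundary pixels are assigned to the four sides, a total-least-squares
line is fitted per side, pushed outward by half a pixel (boundary pixel
centres sit inside the true edge), and adjacent lines intersected. The
6 × 6 cell grid inside each candidate quad is then sampled through a
local homography; candidates whose border cells are not uniformly dark
are rejected, and the inner 4 × 4 bits are matched against the
dictionary under all four rotations.

With all four markers decoded, the sixteen corners and their known
physical positions give the chart-to-image homography by the normalized
direct linear transform. Using a full homography (rather than a
similarity) lets the same code handle oblique views; the metric scale is
then valid in the chart plane, and out-of-plane wound surfaces are
measured approximately — planar measurement is an explicit modelling
assumption of this package (no curvature or depth correction).

**Color transform.** The correction is the least-squares *linear* map
`M = pinv(S) T` from observed to reference patch colors, fitted and
applied in device 8-bit RGB without gamma linearization, and with no
intercept — black maps to black. A linear map in device space is a
deliberate, simple model: it can absorb channel gains and cross-talk but
not clipping. Colors pushed out of gamut at capture time are
unrecoverable by any linear correction, which is why the synthetic cast
generator (below) samples gamut-preserving casts.

**Patch sampling** averages a 7 × 7 grid of samples over the central 40%
of each patch side (the window size is a robustness choice: wide enough
to average noise, narrow enough to avoid edge bleed), projected through
the homography so perspective is handled exactly.

**Scale.** `mm_per_px` is the mean of `marker_side_mm / side_px` over
all sixteen projected marker sides. Markers are used rather than patches
because their corners are localized to sub-pixel accuracy. Missing
markers are a hard error naming the missing IDs: a partial calibration
would silently corrupt every downstream mm² value.

## Synthetic scenes

The generator emulates what matters about a clinical wound photograph
for this pipeline, with exact ground truth:

* skin-toned background with per-pixel texture noise;
* a smooth closed wound contour — an ellipse perturbed by low-order
  Fourier modes (orders 2–4, amplitude SD 0.06) — so contours are
  irregular but realistic;
* a wound bed partitioned by multiplicatively weighted nearest-seed
  growth into granulation and necrotic regions, with an epithelial rim
  at the margin (epithelium regrows from the edge inward). Necrotic
  seeds claim ~1/k² the area of granulation seeds (k = 1.8),
  compensated in the seed-class probabilities, so necrotic tissue
  appears as small scattered patches while the expected area shares
  still follow the mixture weights. Default weights are 0.15 / 0.75 /
  0.10 (epithelial / granulation / necrotic): granulation-dominated
  wounds with rare, small necrosis, mirroring the class imbalance of
  real wound collections;
* tissue colors drawn from truncated Gaussians around clinically
  described appearances: granulation beefy red (185, 50, 55),
  epithelium deep pink (230, 140, 160), necrosis dark yellow-brown
  (105, 82, 40);
* the chart composited frontally at the known scale, then a global
  invertible 3 × 3 color cast and additive Gaussian sensor noise over
  the whole frame.

`random_cast(strength)` samples casts with non-negative entries and
column sums ≤ 1. This keeps every 8-bit color in gamut, so the cast
remains exactly invertible by the linear correction; strength 0.4 is a
mild indoor shift, 0.8 a strong one. What the generator does **not**
emulate: specular highlights, shading gradients across the frame,
motion blur, chart occlusion, depth and curvature. Tests passing on
these scenes therefore demonstrate the correctness of the pipeline's
geometry, algebra and learning dynamics — not clinical-grade
performance on real photographs.

Cohorts (`generate_cohort()`) attach subject IDs, shrink each subject's
wound radius by a per-visit factor (0.80–0.88), and drift the mixture
toward healing, giving strictly decreasing true wound areas for
longitudinal tests.

## The segmentation model

The network is a U-shaped encoder-decoder with **two output branches**
sharing one decoder: a 2-class wound/background head and a 4-class
tissue head, both 1 × 1 convolutions followed by a per-pixel softmax.
The two tasks are related but distinct — the wound extent is not the
union of the tissue classes a priori — and the shared representation
lets each branch regularize the other. At inference the package reports
the tissue argmax both as-is and masked by the wound branch
(`tissue_labels_in_wound`), since tissue labels outside a predicted
wound are contradictory; which view to use is left to the caller.

Encoder configurations:

* `tiny_test` — 3 levels of double 3 × 3 convolutions, widths
  8/16/32, downsampling factor 4. This is the configuration actually
  trained in the package's tests and experiments; it is small enough to
  train on a CPU in seconds per epoch.
* `mobilenet_v2_style`, `efficientnet_b2_style` — 5 levels of MBConv
  inverted-residual blocks (1 × 1 expansion, 3 × 3 depthwise, 1 × 1
  squeeze, residual where shapes match; expansion ratio 6) with width
  and depth plans condensed from those architectures' stage layouts to
  the five U-Net resolution levels. They build and run forward
  correctly (tested), but training them at their native 1024² input is
  a GPU-scale undertaking and out of scope here. No pretrained weights
  are used or distributed.

The decoder upsamples with 2 × 2 stride-2 transposed convolutions,
concatenates the encoder skip of matching resolution, and applies one
3 × 3 convolution per level. A single decoder convolution (rather than
the classic double) was chosen to keep CPU training within practical
budgets; with the color-dominated synthetic task this costs no
measurable accuracy.

All layers were implemented natively (im2col + GEMM convolutions in
RcppArmadillo, exact hand-derived gradients). The backward pass is
verified against central finite differences in the test suite; weight
gradients agree to ~10⁻⁶ relative error.

**Loss and optimizer.** The loss is the sum over branches of the mean
over pixels of `−w[class] · log p[class]`. Class weights default to
inverse pixel frequency computed on the training fold (normalized to
mean 1), the standard counter to extreme class imbalance: background
pixels outnumber necrotic pixels by orders of magnitude. Optimization
is Adam (β₁ = 0.9, β₂ = 0.999) with learning rate 10⁻³, weight decay
10⁻⁴ added to the gradient, batch size 4 and 100 epochs by default —
the conventional recipe for this model family; the scaled-down
experiments below override epochs/batch for CPU budgets. The checkpoint
kept is the one with the lowest validation loss. Given a seed, training
is bit-reproducible: parameter init, shuffling and augmentation draws
all flow from one RNG stream.

**Augmentation.** Central crop, horizontal/vertical flips, grid
distortion, brightness, contrast and Gaussian noise, each enabled op
applied with probability ½ per image; geometric ops transform image and
masks identically (masks by nearest neighbour). The grid distortion is
the rotated gradient of a random stream function interpolated from a
5 × 5 control grid — a divergence-free field — so it bends contours
without inflating or shrinking regions: per-class pixel counts change
by well under 2% on large masks, preserving the class statistics the
weighted loss relies on. Exact magnitudes of the photometric ops are
configurable, not canonical. Full-size photographs are standardized by
scaling the shorter side to 1280 px and centre-cropping 1024 × 1024
(`center_square_resize()`); synthetic experiments skip this step since
scenes are generated at the network input size.

## Evaluation design

Pixel accuracy and IoU are computed per class per image from TP/TN/FP/FN
pixel counts. Three conventions required decisions:

* **0/0 IoU** (class absent from prediction *and* truth): returned as 1
  and flagged (`iou_defined()`), so correctly predicting the absence of
  necrosis is not penalized; summaries are emitted both over all images
  and restricted to images where the class is present.
* **Aggregation**: mean ± SD across images is the primary summary; a
  per-fold breakdown is also emitted for auditing fold effects.
* **Inter-rater agreement**: per unordered rater pair and class, IoU per
  image, mean ± SD across images; the overall per-class figure is the
  unweighted mean of the pair means.

The cross-validation splitter produces 10 outer × 9 inner folds over
*subjects*, never images: all images of a subject share every role, so
no model is ever tested on a subject it trained on. Outer test sets
partition the subjects with sizes differing by at most one; the scheme
gives every image exactly one held-out prediction, so a full-dataset
evaluation is possible even for small collections.

## Scaled-down experiments and what they show

Two standing experiments (run in the test suite) exercise the full
pipeline at CPU scale; the problem sizes are the package's chosen
operating points for desk-scale verification:

* **Model recovery.** A `tiny_test` network trained for 15 epochs
  (Adam, lr 2 × 10⁻³, batch 2, flips) on 12 of 16 synthetic 128 × 128
  chartless scenes reaches held-out wound IoU ≈ 0.96 and granulation
  IoU ≈ 0.82, with the thin epithelial rim and the small necrotic
  patches markedly harder — the same ordering by class size that makes
  minority tissue classes the weak point of any such model.
* **Calibration benefit.** On 160 × 160 scenes with per-scene random
  strong casts (strength 0.8), a model trained and evaluated on
  chart-calibrated images beats the identically-seeded model trained on
  raw cast images in mean held-out wound IoU on every seed tried
  (e.g. 0.84/0.91/0.96 vs 0.72/0.85/0.66 over seeds 1–3). This is the
  directional claim that color normalization, not extra capacity,
  carries the improvement.

The 128 × 128 scenes used for training are chartless wound crops; in
the intended workflow calibration runs on the full photograph and the
fitted transform is applied before cropping, which the 160 × 160
experiment reproduces end to end (the smallest frame that holds a
decodable chart at 2 px/mm).

## Numerical and degenerate-input choices

* Homographies are estimated with Hartley-normalized DLT via the
  eigenvector of AᵀA (stable down to the minimal 4-point case);
  homographies with vanishing determinant are rejected as degenerate.
* The pseudo-inverse fit rejects rank-deficient source matrices
  (e.g. all patches the same color) as ill-conditioned rather than
  returning an arbitrary minimum-norm solution.
* Softmax is computed with max-subtraction; cross entropy clamps
  probabilities at 10⁻¹².
* Argmax ties resolve to the lowest class index (background wins exact
  ties), documented and deterministic.
* Pixel rounding: rendering paints a pixel when its centre falls inside
  a shape; scene images are quantized to 8-bit integers so PNG
  round-trips are lossless and byte-identical under a fixed seed.

## Known limitations

* Planar measurement only; curved or deep wounds are underestimated.
* The linear color model cannot undo gamut clipping or spatially varying
  illumination (shading fields).
* Marker detection assumes the chart is fully visible and roughly
  frontal (obliques are handled geometrically, but heavily foreshortened
  bit cells will fail to decode).
* The paper-scale encoder presets are structural implementations; no
  pretrained weights exist, so their clinical-scale accuracy is not
  reproduced here.
* Synthetic colors separate tissue classes more cleanly than real
  tissue; absolute IoU values on synthetic cohorts are upper bounds,
  not forecasts, for clinical data.
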