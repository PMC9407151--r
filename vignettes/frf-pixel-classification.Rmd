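---
title: "Fast-random-forest pixel classification: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-random-forest pixel classification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frfseg)
```

# The problem

In dermatopathology the diagnostic "gray zone" between dysplastic nevi and
malignant melanoma shows substantial inter- and intra-observer
disagreement. A pragmatic machine-assist is *same-image* supervised
segmentation: the pathologist circles a few clusters of pixels on the image
under review — one class per kind of anomaly ("defect"), plus unremarkable
tissue — and a classifier extends those sparse annotations to every pixel,
returning per-class probability maps and physical coverage estimates. No
historical training corpus or transfer across stains is involved; each
image carries its own model. `frfseg` implements this protocol end to end:
feature extraction, forest training, probability-map thresholding, coverage
quantification, and performance indicators.

# The model

## Feature stack

Each pixel is represented by a feature vector computed from the grayscale
image (BT.601 luma for RGB input; the conversion weighting is a convention
choice — the method only needs a single intensity channel).

The default bank follows the hyperparameters that work well for H&E
photomicrographs at this scale: **Gaussian blur**, **Hessian features**,
and **membrane projections**, with membrane thickness 1 px, membrane patch
size 19 px, minimum σ 1 and maximum σ 16. Scales form a powers-of-two
ladder σ ∈ {1, 2, 4, 8, 16}: given only a minimum and maximum, octave
spacing is the standard multiscale convention and keeps the stack compact
(47 planes) while spanning nuclear to architectural scales at 10×
magnification (1 px ≈ 1 µm at the default 1000 px/mm calibration).

For the Hessian of the σ-smoothed intensity with entries h1 = Ixx,
h2 = h3 = Ixy, h4 = Iyy, the stack carries the trace, a determinant, the
eigenvalues Fe ≥ Se, the orientation, and two ridge-strength measures
(Gamma, Square Gamma) controlled by a constant t = 13/4. Three of these
quantities admit more than one printed convention in the literature this
implementation follows, so both are kept:

* **Determinant.** The algebraic determinant `det_standard = h1·h4 − h2·h3`
  satisfies the eigenvalue identities (Fe·Se = det, Fe+Se = trace) and
  backs every internal invariant. The quadratic form
  `det_printed = h1² + h2·h3 + h4²` is also computed and is the default
  *stack feature*; it is a legitimate (positive-semidefinite-leaning)
  texture energy even though it is not the determinant. Selectable via
  `filter_config(hessian_det =)`.
* **Orientation.** The default is ½·atan2(2·h2, h1 − h4), the angle of the
  maximal second derivative. An arccos form
  ½·arccos(4h2² + (h1 − h4)²) exists in print but its argument is
  unbounded; it is available behind
  `filter_config(orientation_form = "arccos")` with the argument clamped
  to [−1, 1]. It contributes no directional information where clamping
  saturates, which is why it is not the default.
* **t = 13/4.** The notation for the Gamma measures is ambiguous between a
  constant t = 13/4 = 3.25 and a γ-normalization exponent 3/4. The
  constant reading is used (it only rescales the planes, which is
  irrelevant to threshold-based tree splits); it is configurable via
  `filter_config(hessian_t =)`.

**Membrane projections** rotate a normalized line kernel (length =
patch size, width = thickness) through 30 orientations in 6° steps and
aggregate the 30 responses per pixel by sum, mean, sd, median, max and
min. The max plane is an isotropic ridge detector — it responds to
elongated structures (membranes, fibrous septa, nests' borders) regardless
of direction.

Beyond the default bank, `apply_filter()` exposes difference of Gaussians,
Sobel gradient magnitude, local disc statistics, Perona–Malik anisotropic
diffusion (20 iterations, conduction 20/255, step 0.2 — classic
edge-preserving defaults), bilateral filtering, Lipschitz covers
(chamfer-sweep top-hats with default slope 5/255 per px), Gabor magnitude
banks (4 orientations × 2 wavelengths per scale), Gaussian derivatives of
orders 2–4, structure-tensor eigenvalues, and ±σ shifts. All convolution
uses reflect padding (edge duplicated), so every filter is deterministic
and translation-equivariant away from borders; separable kernels run
through C-backed `stats::filter`, general 2-D kernels through FFT products.
Sampled derivative kernels are moment-normalized at orders 1–2 so
polynomial images give exact derivatives — this is what makes the
analytic unit tests tight rather than approximate.

## The forest

`frf_train()` grows `n_trees` (default 200) CART-style trees on bootstrap
resamples of the labeled pixels. At each node `mtry` features (default
⌊√p⌋) are drawn uniformly without replacement and the best Gini split is
taken; trees grow to purity (minimum leaf 1). These defaults are the
standard random-forest choices; the method's published description fixes
none of them, and on the fixtures all results are insensitive to
`n_trees` beyond ~50.

Determinism is treated as a feature contract, not an accident:

* Per-tree sub-seeds are drawn once from the master seed, so the K-tree
  probability map is *exactly* the mean of the K single-tree maps built
  with those sub-seeds (tested to 1e−12).
* Ties — equal split gains, equal argmax probabilities — break toward the
  lowest feature/class index and the lowest threshold. Arbitrary but
  reproducible beats unstable.
* If every sampled feature is constant on a node, the split search falls
  back to the full feature set; only genuinely duplicated feature vectors
  with mixed labels produce an impure leaf.

A single-tree, no-bootstrap, depth-1 configuration exposes the raw split
choice, which the test suite compares against an exhaustive enumeration
over every feature/threshold pair on small instances.

Evaluation is on the training labels themselves: by design the protocol
trains and tests on the same image, so there is no held-out set, and
"precision" here means training-set precision (micro-averaged — for
single-label multiclass data this equals accuracy). The learning curve
operationalizes "instances" as bootstrap-ordered training-sample counts:
one bootstrap ordering is drawn, and for each scheduled count n a forest
is trained on the first n samples and scored on them. Classes unseen at
small n are flagged `degenerate` and contribute 0, rather than being
silently dropped.

## Quantification

`threshold_probability()` uses ≥ (inclusive) comparison — documented so
that coverage at a threshold equal to a realized probability is
bit-reproducible. Coverage percent is `100 · covered / total`; extension
is `coverage × physical area`, with physical area `h·w / (px/mm)²`. The
default calibration of 1000 px/mm mirrors the standard 1000 × 2000 px ≙
1 mm × 2 mm analysis field; the default threshold 0.5 is the natural
majority-vote point and is configurable per class, since in practice the
threshold is a reviewing pathologist's sensitivity dial. Human-readable
output rounds percentages to one decimal; CSV/JSON keep full precision.
Morphological post-processing (opening, component filtering) is
deliberately out of scope — reported areas are exactly what the
thresholded map says.

# The synthetic scenes

`generate_scene()` emulates just enough of a photomicrograph to exercise
every stage: a stationary correlated Gaussian background (smoothed white
noise; default mean 0.62, sd 0.05, correlation length 2 px) and elliptical
defect blobs with distinct texture statistics (defaults: a dark class at
mean 0.30 and a bright, coarser, obliquely anisotropic class at mean 0.85,
both sd 0.05). The defaults keep |Δmean| ≥ 4·sd, the separability regime
in which a perfect classifier is the expected outcome; truth masks are
recorded exactly as rasterized, so coverage ground truth is known to the
pixel. Blobs that would overlap an earlier class keep only their unclaimed
pixels (masks stay disjoint), and blobs are clamped to fit the frame.

What the scenes do **not** model: nuclei and cellular micro-structure,
stain variation and chromatic information, uneven illumination,
non-elliptical lesion geometry, and annotation noise (sampled labels are
always inside the true mask). Passing the end-to-end tests therefore
demonstrates that the pipeline is *correct* — features computed as
specified, forest consistent, calculus exact — not that the default
configuration is *sufficient* for any particular real-world stain or
magnification.

# Numerical and design choices

* **Problem sizes.** Unit fixtures are 20–50 px across; end-to-end scenes
  are 100 × 160 px with 150 labels/class; the acceptance computation uses
  a 512 × 512 scene with 100 labels/class. These sizes are the smallest at
  which each claim is meaningfully exercised (e.g. blobs several blur
  radii wide), and everything runs in seconds on one core.
* **Annotation density matters.** With sparse labels (≈50/class) the
  recovered coverage acquires a systematic positive halo of up to ~1.5
  percentage points: pixels at blob boundaries have blur-mixed features,
  and the labeled defect pixels near edges pull that ambiguous band into
  the defect class. At ≈150 labels/class (still ~1% of pixels) the
  boundary is resolved and recovery is within ±0.5 pp across seeds. This
  mirrors practice: circling a few *clusters* yields hundreds of labeled
  pixels per class, not dozens.
* **Float TIFF maps.** Probability maps serialize as 32-bit float
  multi-page TIFF (one page per class, in class order) — lossless at
  float32, readable by any scientific viewer. PNG previews render
  probability 1 as white, the "high probability highlighted with white"
  display convention.
* **Annotation dialect.** Sparse labels travel as an 8-bit indexed PNG
  mask (0 = unlabeled) plus a JSON class table; coordinates are 0-based,
  row-major, origin top-left throughout.
* **Provenance.** Every protocol artifact embeds the seed and the md5 of
  the canonical config JSON; reruns with the same config are byte-identical.

# Known limitations

* Luma-only: color (eosin/hematoxylin balance) is discarded; stain
  deconvolution would be the natural extension.
* The O(σ²) disc filters (local statistics, bilateral) are exact but slow
  at the largest scales; they are off by default.
* Same-image training cannot detect what the annotator did not mark, and
  training-set precision says nothing about generalization beyond the
  annotated image — it is a consistency indicator, as in the protocol this
  package implements.
* Whole-slide formats, pyramidal tiling and 3-D stacks are out of scope.
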