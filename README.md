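# frfseg

Trainable pixel classification for histopathology photomicrographs, in the
fast-random-forest (FRF) style: a pathologist circles a handful of pixel
clusters on a single image — anomalous regions ("defects": architectural or
cytological atypia, pagetoid spread, and so on) plus unremarkable tissue —
and the classifier segments the *same* image into those classes, producing
per-class probability maps and physical defect-coverage estimates. No
historical training corpus is needed: training and testing happen on the
image under review.

The package is aimed at image-analysis work in digital dermatopathology
(e.g. supporting melanoma review), but nothing in it is specific to a stain
or magnification — it applies to any calibrated 2-D grayscale image with
sparse class annotations.

## Method

1. **Feature stack.** The image is converted to grayscale (BT.601 luma) and
   expanded into per-pixel features: the raw intensity, Gaussian blurs,
   Hessian features, and membrane projections (a normalized line kernel of
   patch size 19 and thickness 1 rotated through 30 orientations in 6°
   steps, aggregated per pixel by sum/mean/sd/median/max/min), across the
   scale ladder σ ∈ {1, 2, 4, 8, 16} px. For the Hessian of the σ-smoothed
   intensity, H = [[h1, h2], [h3, h4]], the stack carries

   - Trace = h1 + h4
   - Det (two conventions: the algebraic h1·h4 − h2·h3 and a quadratic
     form h1² + h2·h3 + h4², see the vignette)
   - eigenvalues Fe, Se = (h1+h4)/2 ± √(4h2² + (h1−h4)²)/2
   - orientation ½·atan2(2h2, h1 − h4)
   - Gamma = t⁴ (h1−h4)² ((h1−h4)² + 4h2²) and
     Square Gamma = t² ((h1−h4)² + 4h2²), with t = 13/4.

   Further filter kinds (difference of Gaussians, Sobel, local statistics,
   anisotropic diffusion, bilateral, Lipschitz, Gabor, higher derivatives,
   structure tensor, shifts) are available via `apply_filter()` /
   `filter_config()`.

2. **Forest.** `frf_train()` grows an ensemble of Gini decision trees on
   bootstrap resamples of the labeled pixels (`mtry = ⌊√p⌋` features per
   node, trees to purity). Per-pixel class probabilities are the average of
   the leaf class-frequency vectors across trees; the class map is the
   argmax. Everything is seed-deterministic and the trees are plain,
   JSON-serializable structures.

3. **Quantification.** A per-class threshold (default 0.5) turns a
   probability plane into a defect mask; with the px/mm calibration
   (default 1000 px/mm, so a 1000 × 2000 px field is 1 mm × 2 mm) coverage
   is reported both as percent of the field and as extension in mm².

4. **Performance indicators.** Training-set precision/recall learning
   curves over bootstrap-ordered instance counts, and ROC/AUC against
   annotated truth.

## Worked example

Synthetic scenes stand in for photomicrographs: correlated-noise background
with elliptical defect blobs of distinct texture, and exact ground-truth
masks.

```r
library(frfseg)

scene  <- generate_scene(scene_params(height = 100, width = 160), seed = 19)
labels <- sample_labels(scene, n_per_class = 150, seed = 19)
stack  <- build_stack(scene$image)         # 47 features, scales 1..16
model  <- frf_train(stack, labels, n_trees = 40, seed = 19)
summary(model)
pred   <- predict(model, stack)
defect_report(pred$prob, scene$image, thresholds = 0.5, image_id = "scene_19")
truth_coverage(scene)
```

```
<synthetic_scene> 100 x 160 px (seed 19); truth coverage: C1 21.67%, C2 9.14%
Fast-random-forest pixel classifier (40 trees, mtry = 6, seed = 19)
  classes:  background, C1, C2
  features: 47
  training accuracy: 1.0000
  tree depth: median 6 (range 4-8); leaves: median 10
  top features by Gini importance:
    gaussian_s2                  0.10891
    raw                          0.08917
    gaussian_s1                  0.07487
Defect coverage report for scene_19
  background thr 0.50:  68.6% of field, 0.011 mm^2
  C1         thr 0.50:  21.9% of field, 0.003 mm^2
  C2         thr 0.50:   9.6% of field, 0.002 mm^2
```

The thresholded maps recover the known blob coverage (21.67% and 9.14%)
within a fraction of a percentage point; training accuracy 1.0 reflects the
maximum-precision behaviour expected of the method on cleanly separable
classes. On a real 1 mm × 2 mm field the same report reads directly in mm²
— e.g. a class covering 5.3% of the field is 0.106 mm² of tissue.

A thin command-line runner wraps the same pipeline:

```sh
Rscript inst/scripts/frfseg.R simulate --out demo --seed 19
Rscript inst/scripts/frfseg.R run --image demo/scene.png \
    --labels demo/scene_labels.png --classes demo/scene_label_classes.json \
    --out demo/out --n-trees 40 --seed 19
```

Exit codes distinguish I/O (2), configuration/annotation (3), training (4)
and evaluation (5) failures; every artifact embeds the seed and a config
hash.

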