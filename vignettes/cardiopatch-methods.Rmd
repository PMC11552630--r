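---
title: "Methods: nucleus segmentation, patch classification and patient-level voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus segmentation, patch classification and patient-level voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiopatch)
```

## The problem

Endomyocardial biopsies from patients with dilated cardiomyopathy are
scarce: typically a single stained whole-slide image exists per patient,
while the clinically interesting labels — heart failure (HF) versus
non-failing control, and whether the left ventricle will recover under
therapy (left ventricular reverse remodeling, LVRR) — are per-patient.
Two biological premises make imaging-based prediction plausible: failing
cardiomyocytes show altered nuclear morphology (visible in DAPI staining),
and DNA-damage signaling is activated in myocardium that will not recover
(visible as punctate gamma-H2A.X foci).

`cardiopatch` implements the full analysis chain around these premises:
nucleus isolation from DAPI slides, dual-stain composite construction and
fixed-size tiling, patient-exclusive dataset assembly with rotation
augmentation, a pluggable patch classifier, and patch-to-patient
aggregation by majority vote, evaluated with confusion matrices, ROC/AUC
and PR/AUPR. A seeded synthetic-slide generator with ground truth makes
every stage testable without clinical data.

## Nucleus segmentation

`segment_nuclei()` applies five steps in order:

1. grayscale conversion (BT.601 luminance for 3-channel input);
2. bicubic enlargement by an integer per-axis factor, default 4 — a
   16-fold area enlargement. Cardiac nuclei are only a few pixels across
   at acquisition resolution, too small to segment directly;
3. Otsu thresholding (exhaustive maximization of between-class histogram
   variance) and binarization, with foreground defined strictly above the
   threshold;
4. a morphological gradient (dilation minus erosion, 3x3 box element,
   reflect border padding) outlining nucleus contours;
5. connected-component labeling (8-connected), measurement of pixel-count
   areas and tight bounding rectangles, retention of objects of at most
   512 upscaled pixels, and bounding-box cropping from the upscaled
   grayscale image.

Several conventions here are genuinely open and were fixed once:

* **Enlargement factor.** "16-fold" can mean per-axis or by area. We use
  per-axis factor 4 (16-fold area), configurable via
  `segmentation_config(upscale_factor=)`. With nuclei of radius 2–3 px at
  acquisition scale this keeps the 512-px cap in a plausible
  nucleus-size regime; per-axis 16 would make every nucleus thousands of
  pixels and the cap would reject everything.
* **Bicubic convention.** Keys kernel with a = -0.5 (the common library
  default), corner-aligned coordinate mapping (image corners are
  preserved exactly), replicated borders, rounding to integers at the
  end. The test suite validates the separable implementation against
  direct scalar kernel evaluation.
* **Areas.** The area of an object is the pixel count of its filled
  component on the binarized image, measured after enlargement (the frame
  in which the 512-px cap is applied); the gradient contour is retained
  for visualization (`keep_contour = TRUE`) but not used for measurement.
  Contour-pixel counting would conflate perimeter with area.
* **Thresholding order.** Otsu runs on the enlarged image, following the
  printed step order of the procedure the package reimplements.
* **Degenerate slides.** A constant slide has no Otsu threshold; the
  function warns and returns an empty crop set rather than erroring,
  because empty fields of view occur in practice.
* Objects touching the slide border are kept; no minimum-area floor is
  applied by default (`min_area_px = 1`).

## Dual-stain composites and tiling

`overlay_channels()` auto-contrasts each channel (histogram-tail
saturation, default 0.35% per tail, mirroring the familiar "Auto"
brightness/contrast behavior) and places DAPI in blue and gamma-H2A.X in
red — the conventional fluorophore display; classifiers only need
consistency, so the mapping is configurable.

`tile_patches()` uses a non-overlapping grid with stride equal to the
patch size (default 128), row-major order, partial edge tiles dropped:
`floor(H/s) * floor(W/s)` patches. A stitched slide of 8064 x 10240
pixels therefore yields exactly 5040 patches; identical per-patient patch
counts across a cohort imply exactly this kind of deterministic grid,
which is why no overlap or random cropping is used. Patches inherit the
patient's outcome label (weak labeling): every patch of an LVRR-positive
patient is labeled positive even though individual patches may carry no
signal.

## Dataset construction

`patient_split()` assigns whole patients to train/test by seeded sampling
stratified on the class label; all items of a patient inherit its split.
Patient exclusivity — no patient contributing images to both sides — is
asserted on every constructed manifest and is a hard failure, since
identity leakage is the canonical way slide-level classifiers cheat.

`rotate_augment()` replaces every training item with four items tagged
with quarter-turn rotations. Rotations are exact pixel permutations
(never interpolated) applied lazily at image-load time, so the manifest
stays a light-weight CSV; the training set size exactly quadruples and
the test split is never augmented. Manifests carry their split seed in a
JSON sidecar for provenance.

## Patch classifiers

`fit_classifier()` / `predict_proba()` define a uniform contract: scores
in [0, 1], higher meaning positive class, bit-identical outputs for a
fixed seed and manifest. Model comparisons are therefore configuration
sweeps; the aggregation and evaluation stages never change.

Two backends ship:

* **`transformer_small`** — a compact vision transformer implemented in
  base R with hand-derived backpropagation: patch-token embedding with a
  learned positional embedding, pre-LayerNorm blocks of multi-head
  self-attention and a ReLU MLP (both residual), mean pooling and a
  2-logit softmax head, trained with Adam under cross-entropy. The
  default desk-scale geometry is input 32, token patch 8 (16 tokens),
  width 32, 2 layers, 2 heads, MLP width 64, 12 epochs, batch 32,
  learning rate 1e-3. This geometry was chosen so that from-scratch CPU
  training takes seconds at the cohort sizes used in the examples while
  still exercising a genuine attention architecture; no deep-learning
  framework is a dependency. Gradients are verified against finite
  differences in the test suite. Loading externally published pretrained
  weights is out of scope: large-scale pre-training is consumed, never
  reproduced, and at desk scale the synthetic tasks are learnable from
  scratch.
* **`intensity_baseline`** — a logistic model on per-channel mean and
  standard deviation features. It is deliberately oracle-adjacent: on
  data whose classes differ in channel intensity statistics it recovers
  the generating rule almost exactly, making it a fast sanity check and
  the reference point any representation-learning backend must beat.

`preprocess_for_model()` resizes the longer side to the model input size
preserving aspect ratio, zero-pads to a square (top-left anchored),
scales to [0, 1] and replicates single-channel inputs to 3 channels —
one deterministic geometry rule for both arbitrary nucleus crops and
fixed-size patches.

## Patient-level aggregation and evaluation

`vote_patient()` hard-labels each patch at the decision threshold
(default 0.5, exposed because behavior across threshold regions is of
interest) and takes the majority. With an even patch count an exact tie
is possible; it is broken by comparing the patient's mean score to the
threshold and flagged via `tie_broken`, so downstream analysis can see it
happened.

`roc_auc()` sweeps thresholds over distinct scores, grouping ties into
single operating points; the trapezoidal area then equals the
pair-counting probability `P(s_pos > s_neg) + 0.5 P(equal)` exactly, and
the suite asserts that identity on every random table. `pr_aupr()` uses
step-wise (right-continuous precision) interpolation, the conservative PR
convention; with all scores tied the curve collapses to a single point
and the area equals the positive prevalence.

## The synthetic-slide generator

`generate_slide()` renders, per class phenotype:

* a DAPI channel: filled ellipses (intensity ~200 on the 8-bit scale,
  per-nucleus jitter sd 10) on a dark background (level 12) with
  pixelwise Gaussian noise (sd 8, drawn as the exact discretized,
  range-clipped distribution);
* a damage channel: per-nucleus focus counts drawn from a Poisson with
  the class's `foci_rate`, rendered as small bright disks (radius 1.2 px,
  intensity 200) placed uniformly inside the parent ellipse, over a
  dimmer noisy background (level 8, sd 5).

The nominal radius `r` fixes the ellipse area (`pi r^2`) independently of
eccentricity, so size and shape effects are orthogonal dials. Class
encodings mirror the biological premises without claiming unpublished
effect sizes: diagnosis-track classes differ in nuclear morphology
(control radius 2.4 px, eccentricity 0.3; HF radius 2.9 px, eccentricity
0.7), prognosis-track classes in foci rate (responders 0.5, non-responders
5 foci per nucleus) — a deliberately large, desk-scale effect chosen so
that a mean-intensity threshold classifier reaches at least 0.9 patch
accuracy, the contract the classifier tests build on. Default prognosis
slides are 8064 x 10240 (exactly 5040 patches) with 4 nuclei per patch
area so that essentially every patch carries signal.

Non-overlapping placement uses a jittered occupancy grid (at most one
nucleus per cell, cell size derived from the maximal semi-axis): it is
O(n), guaranteed overlap-free, and fails loudly when the requested count
cannot fit, at the cost of a slight regularity in nucleus spacing that
real tissue does not have. Everything is reproducible bit-for-bit from
`(params, seed)`; cohort generation derives per-patient seeds from the
master seed, and `per_patient_fn` streaming keeps full-size cohorts
within memory.

What the generator does **not** emulate: touching or clumped nuclei (no
watershed splitting exists downstream), out-of-focus blur and
point-spread optics, stitching artifacts, intensity gradients across the
slide, autofluorescence, or inter-patient variability beyond the seed.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that it recovers known planted effects; they say nothing
about accuracy on real biopsy images, which depends on effect sizes the
synthetic data does not model.

## Problem sizes in the examples and tests

The deterministic dataset-construction checks run at the published
cohort scale (46 patients, 8064 x 10240 slides, 231 840 patches) because
they are cheap per pixel. The learning checks run on micro-cohorts
(256 x 384 slides, 6 patches per patient, 4 + 4 training and 2 + 2 test
patients, 3 seeds) — sizes chosen so a from-scratch CPU training run
takes well under a minute while the planted foci-rate effect remains
clearly recoverable; the end-to-end expectation there is at least 0.9
patch accuracy and an error-free patient majority vote.

## Known limitations

* The transformer is desk-scale by design; it makes no claim to the
  capacity of published large vision models, and `pretrained = TRUE` is
  a reserved switch rather than a working weight loader.
* Touching nuclei merge into one component (no watershed), and the
  512-px cap silently removes merged blobs — on dense real tissue this
  biases the crop set toward isolated nuclei.
* `roc_auc()`/`pr_aupr()` are binary-only; no confidence intervals are
  computed.
* The clinical outcome definitions (e.g. the LVEF-based LVRR rule) are
  consumed as given metadata (`label_provenance`) and never computed.
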