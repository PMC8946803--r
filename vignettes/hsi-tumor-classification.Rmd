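---
title: "Methods: hyperspectral classification of ovarian tumor tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral classification of ovarian tumor tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiclass)
```

## The problem

Complete cytoreductive surgery is the strongest predictor of survival in
advanced epithelial ovarian cancer, and residual microscopic tumor drives
recurrence. Near-infrared hyperspectral imaging (HSI) offers a label-free,
non-contact way to discriminate tumorous from healthy tissue by its
reflectance spectrum. `hsiclass` implements the full ex vivo analysis chain
for a snapshot-mosaic NIR camera: 25 spectral bands (665–975 nm) interleaved
on the sensor in a repeating 5×5 mosaic, imaged against histopathology
ground truth, and classified per 20×20-pixel patch with a class-weighted
linear SVM under leave-one-patient-out cross-validation (LOPO-CV).

Because the underlying patient data are not public, the package ships a
synthetic cohort generator that emulates the camera and the annotation
workflow, so that every stage is testable end to end.

## Pipeline and model

1. **Demosaic.** Band $b$ at demosaiced pixel $(i,j)$ is the mosaic value at
   $(5i + r_b,\, 5j + c_b)$; no interpolation. A $H\times W$ frame becomes a
   $\lfloor H/5\rfloor \times \lfloor W/5\rfloor \times 25$ cube (the sensor's
   advertised $409\times218$ differs from $\lfloor 2050/5\rfloor \times
   \lfloor 1080/5\rfloor = 410\times216$; we use floor division and do not
   attempt to reproduce the advertised figure).
2. **Reflectance calibration.** With white and dark reference frames,
   $I_{\mathrm{ref}} = (I_{\mathrm{raw}} - I_{\mathrm{dark}})\,/\,
   (I_{\mathrm{white}} - I_{\mathrm{dark}})$ per pixel and band. This cancels
   the illumination field and dark current exactly; pixels whose denominator
   falls below $\varepsilon = 10^{-6}$ are flagged `invalid_reference`.
3. **Min–max normalization.** Each spectrum is rescaled across its 25 bands
   to $[0,1]$: $\hat x = (x - \min x)/(\max x - \min x)$. This keeps only the
   *shape* of the signature and is invariant under positive affine transforms
   of the input. We apply it per spectrum (not per band across the image);
   the alternative is not implemented because per-band scaling would retain
   amplitude structure the classifier should not use.
4. **Pixel selection.** Glare pixels (max reflectance over bands
   $> 0.95$) and background pixels (mean reflectance $< 0.10$; samples sit on
   near-black paper) are removed. Tissue edges of 20 px are then eroded away
   (mixed spectra live there). Thresholds are config fields, not constants.
5. **Patching.** The image is divided into a fixed grid of 20×20-pixel
   blocks anchored at the origin; spectra of valid pixels are averaged per
   block. A block is kept when ≥ 80% of its pixels are valid and all its
   annotated pixels agree on one of tumor / non-tumor; any contact with a
   "mixed" annotation (1–50% tumor cells) excludes the block.
6. **Annotation registration.** Histology annotations (tumor bordeaux,
   non-tumor blue, mixed green) are segmented by HSV windows and registered
   into camera coordinates by an interpolating thin-plate spline on ~20
   control points (nearest-neighbor resampling for label masks).
7. **Features.** 19 features per patch: 9 band intensities (697, 775, 799,
   823, 863, 872, 901, 910, 923 nm), 4 intensity differences (684–697,
   882–892, 923–930, 943–954 nm) and 6 intensity ratios (676/910, 697/910,
   762/910, 872/910, 923/910, 930/910 nm).
8. **Classifier.** A linear SVM minimizing
   $\tfrac12\lVert w\rVert^2 + C\sum_i w_{c(i)}\,\max(0, 1 - y_i(w\cdot x_i + b))$
   with inverse-frequency class weights $w_c = N/(2 n_c)$ and $C = 1$ (no
   hyperparameter search). Features are z-scored with training-fold
   statistics. The solver is a deterministic maximal-violating-pair SMO
   implemented in C++.
9. **Evaluation.** LOPO-CV: all patches of one patient held out per fold.
   Per patient we report sensitivity, specificity, PPV, NPV, AUC
   (trapezoidal, equal to the tie-corrected Mann–Whitney statistic) and MCC
   at the Youden-index threshold $\arg\max(\mathrm{TPR}-\mathrm{FPR})$ of the
   held-out patient's own ROC. The cohort mean averages each metric over the
   patients where it is defined; tumor-free patients contribute only to
   specificity.

## Design choices that were genuinely open

* **Normalization vs. ratios.** Min–max normalization forces a zero into
  every spectrum, which makes band ratios unstable. Default (`mode =
  "mixed"`): intensities are read from the normalized spectrum, derivatives
  and ratios from calibrated reflectance. Both all-reflectance and
  all-normalized modes are selectable.
* **Normalize after patch averaging.** Averaging normalized spectra would
  break the min/max range guarantee, so patch means are computed on
  reflectance and normalized afterwards; the opposite order is available via
  `normalize_before_patching`.
* **Leave-one-*patient*-out.** Per-patient report rows imply patient-level
  folds; pooling a patient's patches across folds would leak within-patient
  structure.
* **Threshold on the held-out ROC.** Metrics are reported "at the optimal
  threshold point" of each patient's ROC. For tumor-free patients no ROC
  exists; their specificity is computed at the SVM's own decision boundary
  (score 0). A training-fold-threshold mode is selectable.
* **Edge erosion support.** Eroding the *valid* mask would delete a
  41×41 window around every isolated glare pixel — with 1–2% glare this
  empties every image (the chance of a clean window is about
  $0.99^{1681}\approx 5\times10^{-8}$). The default therefore erodes the
  tissue support (everything except background) while glare pixels remain
  individually excluded; strict mask erosion is available as
  `support = "valid"`.
* **Block purity.** How annotation labels were reconciled within a block is
  not specified anywhere; we use all-annotated-pixels-agree, else excluded.
* **Half-up display rounding.** Three of the six published cohort means are
  exact decimal halves at 2 dp (0.805, 0.815, 0.825); reproducing the
  printed table requires round-half-up, not banker's rounding, so
  `round_half_up()` is used for display aggregation.

## The synthetic world

The generator states one concrete world and keeps it fixed:

* **Endmembers** are smooth synthetic curves (linear continuum plus Gaussian
  dips at plausible NIR chromophore wavelengths: ~760 nm deoxyhemoglobin,
  ~930 nm lipid, ~970 nm water) — controllable stand-ins, *not* digitized
  tissue spectra. The tumor endmember is `connective + separation × delta`;
  `separation = 0` is a true null only against a single non-tumor class,
  which is why the null-calibration cohorts disable the heterogeneous
  classes.
* **Per-spectrum amplitude** is log-normal (σ = 0.15) and multiplies the
  whole spectrum, so same-class spectra "run in parallel" — precisely the
  structure that makes ratio features informative. Additive per-band noise
  has σ = 0.01 reflectance. Both are per pixel and independent, so patch
  averaging suppresses them faster than spatially correlated real noise
  would; a green recovery test therefore establishes correctness of the
  chain, not clinical-level difficulty.
* **Camera.** 10-bit sensor (saturation 1023), dark current 64, white level
  900 counts, read noise 2 counts, smooth radial illumination fall-off,
  1% i.i.d. glare pixels saturating whole 5×5 cells, black paper background
  at 0.02 reflectance.
* **Cohort.** 10 patients, 26 samples with the per-patient sample counts of
  the emulated pilot cohort; patients 2, 3, 4, 8 are tumor-free, exercising
  the "-" row semantics. Scenes are 400×400 with four blob regions (one per
  quadrant; occasional regions carry 5–45% tumor fractions and must end up
  excluded). This yields roughly 1–2 thousand retained patches; the
  annotation image is misaligned by a small random affine map that the
  control-point registration recovers exactly.

What the generator does **not** emulate: spatially correlated noise,
specular gradients, real filter response curves, registration error beyond
an affine map, depth mismatch between surface histology and volumetric
reflectance. Green tests certify the computational chain, not clinical
performance.

## Numerical notes

* SMO stops at duality gap `1e-5` (far below the O(1) scale of standardized decision values) (tests tighten to `1e-12` when comparing
  objectives with a grid oracle); ties in working-set selection resolve to
  the lowest index, making fits bit-reproducible.
* ROC thresholds sit at distinct score values, ties collapse to one point,
  AUC uses trapezoids (= half-credit for ties); Youden ties break toward
  lower FPR, then higher threshold.
* Flat spectra cannot be min–max normalized; they return zeros and a
  `degenerate` flag. Ratio features with |denominator| < 1e-8 return `NA`.
* TPS uses the $r^2\log r$ kernel with zero regularization; collinear
  control points raise an informative error.
* All RNG flows through explicit seeds; a cohort is a pure function of
  (config, seed), and generated files are byte-stable.

## Test-budget scaling

The acceptance-style parameter-recovery checks run the full 26-sample
separable cohort once, but the 20-seed null calibration and the
separation sweep use reduced cohorts (10 patients × 1 sample, 200×200
scenes, two rectangular regions) so the suite stays within its time budget.
The reduction changes problem *size*, not any model parameter.

## Known limitations

* The published per-patient metrics cannot be reproduced from raw data (the
  patient images are not public); they are verified at the aggregation level
  from the printed per-patient table only.
* Raster I/O is plain-text NetPBM (PGM/PPM) rather than TIFF/PNG, because no
  image codec is available in the supported dependency set; the formats are
  lossless for integer frames and readable by standard tools.
* The non-rigid registration of the original MATLAB workflow is replaced by
  an interpolating thin-plate spline on explicit control points; elastic
  intensity-based registration is out of scope.
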