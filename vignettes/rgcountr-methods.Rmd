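---
title: "Counting retinal ganglion cells on flatmounts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting retinal ganglion cells on flatmounts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Survival of retinal ganglion cells (RGCs) is the primary outcome measure in
preclinical glaucoma research. RGCs are visualised on whole flatmounted
retinas with a pan-RGC cytoplasmic immunostain (RBPMS) or a retrograde
tracer (FluoroGold), and counted. Manual counting of preselected frames is
slow and introduces selection and counting bias; automated counting of
cytoplasmic labels is hard because somata span 10–35 µm, overlap, and stain
heterogeneously. `rgcountr` implements a fully automated pipeline: a U-Net
counting model detects somata on overlapping tiles of the full mosaic, a
second U-Net segments the retinal outline, detections outside the retina are
discarded, and the deliverable per retina is the RGC count, the retinal area
(mm²) and their ratio, the mean density (cells/mm²), optionally with
isodensity maps and overlay images.

Because no annotated retinal mosaics ship with the package, a synthetic
flatmount generator provides images with exact ground truth (every soma
centre, the silhouette mask, the true area). All training, testing and
validation in the package run against this generator.

## Pipeline overview

1. **Training data** (`apply_counting_rules`, `points_to_mask`,
   `crop_subframes`, `augment_pair`, `split_train_val`): 768 × 768 px
   annotation frames (354 × 354 µm at the calibrated 2.17 px/µm) are cropped
   into nine 256-px sub-frames and rescaled to half size; point annotations
   become binary disc targets. The counting split is 50/50 (edge cases
   represented equally in training and validation), the segmentation split
   75/25.
2. **Models** (`build_unet`, `train_unet`, `transfer_learn`): an adapted
   U-Net per task, trained with a combined binary cross-entropy + Dice loss
   and Adam.
3. **Inference** (`plan_tiles`, `predict_tiled`, `stitch`, `binarize`):
   overlapping tiles (256 px / 12.5 % overlap for counting, 512 px / 25 %
   for segmentation on a 2048-px working image) are predicted independently
   and merged; overlap suppresses tile-edge artefacts.
4. **Quantification** (`detect_cells`, `segment_retina`, `filter_by_retina`,
   `quantify_retina`, `isodensity_map`, `render_overlay`): connected
   components of the binarized counting map are the detected cells; the
   segmentation mask is cleaned (largest component, holes filled); density
   is count/area; isodensity maps come from a Gaussian kernel density
   estimate scaled by the total count.
5. **Validation statistics** (`icc`, `bland_altman`, `linregress`,
   `jaccard`): the agreement toolbox used to compare automated with manual
   counts and masks.

## The U-Net and its training

Each contraction block is two convolutional sub-blocks (3 × 3 convolution,
batch normalisation, ReLU) followed by 2 × 2 max-pooling and dropout
(rate 0.5 in the full-scale configuration); the filter count starts at 32
and doubles per level. Expansion blocks are a stride-2 3 × 3 transposed
convolution, concatenation with the matching encoder activation, dropout and
two convolutional sub-blocks; the head is a 1 × 1 convolution with sigmoid
activation, so the network maps a tile to a per-pixel probability map of the
same size.

Reference full-scale settings are kept as presets:
`unet_config_counting()` (128-px input, batch 32, 256 steps/epoch, up to 183
epochs) and `unet_config_segmentation()` (512-px input, batch 16, 35
epochs), both with Adam at 1e-4 and early stopping on the validation loss.

The loss is the unweighted sum `BCE + (1 − Dice)` with
`Dice = (2Σpt + ε)/(Σp + Σt + ε)`; the two coefficients are exposed in the
configuration (`bce_weight`, `dice_weight`) because any fixed combination is
a defensible reading of "a combination of binary cross-entropy loss and Dice
coefficient". Gradients are taken on the logits for numerical stability.

Design points that were genuinely open, and the choices made:

* **"5 contraction and up-sampling blocks"** is read as five resolution
  levels, i.e. four pooling steps plus a bottleneck. The alternative (five
  poolings) is also viable for 128-px inputs, but the chosen reading keeps
  the parameter count close to the original U-Net and pairs naturally with
  five up-sampling blocks.
* **Transposed convolution** uses stride 2 (required to invert 2 × 2
  pooling). Internally it is computed as zero-stuffed upsampling followed by
  an ordinary 3 × 3 convolution, which is mathematically identical and lets
  the forward/backward kernels be shared.
* **Batch normalisation** precedes ReLU, and dropout sits after pooling and
  after concatenation, following the stated block order. Population
  statistics for inference are tracked by exponential smoothing
  (momentum 0.9).
* **Early stopping** monitors the validation loss with a patience of 10
  epochs in the full-scale presets (the stopping rule is stated only as
  "when the validation loss stopped improving"); the best-validation weights
  are returned.
* **Training masks**: the geometry of the point-derived targets is not
  published. The package uses discs of radius 4 px at the half-rescaled
  128-px resolution (≈ 3.7 µm at 2.17 px/µm) — smaller than the smallest
  soma radius, so targets of adjacent cells rarely merge. The radius is a
  parameter (`make_training_pairs(radius_px = )`).
* **Weak-stain rule**: counters excluded "very weakly stained" cells without
  a published threshold; `apply_counting_rules` uses intensity < 10 % of the
  99th-percentile candidate intensity, exposed as a parameter.
* **Intensity normalisation**: frames are min–max normalised to [0, 1]
  before training and inference (the source is silent on this; a fixed
  normalisation makes the synthetic and real intensity scales commensurate).

The network engine itself is written in the package (R with compiled C++
kernels for convolution, batch-norm and pooling; all heavy arithmetic is
BLAS matrix products). It is a compact, fully tested CNN engine: gradients
are verified against finite differences, and the convolution against an
independent pure-R im2col implementation.

## Tiled inference choices

* **Merge rule** in overlaps is the per-pixel mean (maximum available via
  `merge = "max"`); the published description stops at "merged in the
  stitching phase".
* **Edge handling**: the final tile in each dimension is clamped flush to
  the image edge; no padding is fabricated. This guarantees full coverage,
  and the coverage property is tested over random geometries.
* **Interpolation**: bilinear for images and probability maps,
  nearest-neighbour for binary masks.
* **Counting resolution**: 256-px tiles are rescaled to the 128-px model
  input, the stitched half-resolution map is up-scaled ×2 to the source
  grid, then binarized at 0.5 (the sigmoid midpoint; configurable).
* **Minimum component area**: binarization specks below the area of a
  4-µm-diameter disc are removed. This is a numerical cleanup, not a
  biological size rule (the published 9-µm rule was a manual annotation
  rule); it is exposed and can be disabled.
* **Touching cells** merged by the probability map are counted once; no
  watershed splitting is applied — separating overlapping cells is the
  counting model's job.

## Isodensity maps

The map is a bivariate Gaussian KDE over detected centroids with a 150-µm
bandwidth, evaluated on a regular grid (default spacing 50 µm, exposed),
multiplied by the total count and expressed in cells/mm². Two exact
properties pin the implementation: the unmasked map integrates to the cell
count (to 0.1 %; the default grid margin of four bandwidths makes the
truncation negligible), and a single cell yields a peak of
`(2πh²)⁻¹ × 10⁶` cells/mm². The KDE is also cross-checked against an
independent bivariate implementation (`MASS::kde2d`) in the tests.

## Agreement statistics

`icc()` computes ICC(2,1) — two-way random effects, absolute agreement,
single rater — from the two-way ANOVA mean squares, with the standard
F-based 95 % CI; this is the common default for method comparison, and the
one-way and consistency variants are selectable because the published
analysis does not name its variant. `bland_altman()` uses the pairwise mean
as the denominator for percent differences (standard ratio practice; again
the denominator is not published) and exact 1.96 limits.
`linregress()` is ordinary least squares with R² the squared Pearson
correlation. `jaccard()` is |A∩B|/|A∪B|.

## The synthetic generator

`synthetic_spec()` defaults encode the study conditions the generator
emulates:

| parameter | default | rationale |
|---|---|---|
| `mean_density` | 3000 cells/mm² | naive RBPMS⁺ density in mouse |
| `soma_diameter_range` | 10–35 µm | published soma size span |
| `pixel_scale` | 2.17 px/µm | epifluorescence mosaic resolution |
| `retina_radius` | 2060 µm | with 4 lobes ≈ 14 mm² retina |
| `gradient_ratio` | 2 | central-to-peripheral density gradient (no published magnitude; exposed) |
| `injury_factor` | 1 | survival fraction; 0.4 emulates severe crush-like loss |
| `background_level`, `tissue_level` | 0.05 / 0.06 | off-tissue glass background; tissue autofluorescence above it (the flatmount is visibly brighter than the glass even between cells) |
| `noise_sd`, `brightness_field_amplitude` | 0.02 / 0.15 | sensor noise and staining heterogeneity |

The silhouette is a disc perturbed by a low-order cosine into four lobes
(the clover outline produced by relief cuts). Cells follow an inhomogeneous
point process: the target count is Poisson with mean
`density × area × injury`, positions are drawn by rejection from a linear
radial falloff normalised so its spatial mean is 1, and a hard core of half
the mean soma diameter keeps centres apart (somata may still overlap
visually, exercising the model's ability to separate touching cells). Each
soma lies entirely inside the silhouette — the tissue contains its cells, so
the ground-truth mask coincides with the visually bright tissue extent, as
a manual outline of a real flatmount would. Somata are rendered as
anisotropic Gaussian blobs clipped at 2σ with per-cell intensity jitter
(`soma_intensity_range`; widening it down to very faint values emulates
heterogeneous retrograde-tracer labelling), then modulated by a smooth
multiplicative brightness field plus Gaussian noise.

What the generator does **not** emulate: real staining artefacts (vessels,
bubbles, debris), microglial tracer uptake, the visual streak (optional
elongation was considered and left out of scope), focus gradients in mosaic
stitching, and realistic soma morphology beyond elliptical blobs. Passing
the synthetic recovery checks therefore demonstrates that the pipeline's
machinery — data path, optimisation, tiling, detection, quantification — is
correct and self-consistent; it does not certify accuracy on real
microscopy, which requires the published kind of manual-count validation.

## Desk-scale problem sizes

The package's own validation runs a reduced experiment end to end
(`desk_models()`): a synthetic training retina of 520 µm nominal radius
(≈ 0.86 mm², ≈ 2500 cells), 5 regional frames → 45 training pairs for the
counting model; a reduced U-Net (3 levels, 16 base filters for counting,
8 for segmentation, no dropout, Adam at 1e-3, flip/rotation augmentation,
12 / 14 epochs); segmentation trained on three whole retinas (naive and
injured) at a 512-px working resolution. Held-out evaluation uses separately
seeded retinas: 20
frames for the counting error, a whole retina for the segmentation IoU, and
naive-vs-injured pairs for end-to-end density recovery. These sizes are the
package's choice of a minimal configuration that still demonstrates
convergence and recovery; the full-scale presets remain available for real
data.

## Known limitations

* The counting model counts merged probability blobs once; at densities far
  above the emulated 3000 cells/mm² undercounting will grow.
* Batch-norm inference statistics come from exponential smoothing over
  training batches; very short runs (a few dozen updates) may leave them
  noisy.
* `run_batch` writes CSV results (no spreadsheet writer is declared as a
  dependency).
* The CLI is a thin `Rscript` front end (`inst/scripts/rgcountr.R`); it is
  not installed on `PATH`.
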