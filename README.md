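# rgcountr

Fully automated quantification of retinal ganglion cells (RGCs) on whole
retinal flatmount images.

RGC survival is the primary outcome measure in preclinical glaucoma
research: retinas are flatmounted, RGCs are labelled with a pan-RGC
cytoplasmic immunostain (RBPMS) or a retrograde tracer (FluoroGold), and the
surviving cells are counted. Manual counting of preselected frames is slow
and bias-prone, and cytoplasmic labels defeat classical threshold-based
counters because somata span 10–35 µm, overlap, and stain unevenly.
`rgcountr` implements a deep-learning pipeline for this task, together with
a synthetic flatmount generator with exact ground truth that makes the whole
pipeline trainable and testable without microscopy data.

## What the pipeline computes

Two U-Nets — encoder–decoder convolutional networks with skip connections —
are trained with the combined loss

    L(p, t) = BCE(p, t) + (1 − Dice(p, t)),
    Dice(p, t) = (2 Σ p·t + ε) / (Σ p + Σ t + ε)

where `p` is the per-pixel sigmoid output and `t` the binary target. The
**counting model** maps image tiles to soma probability maps; the
**segmentation model** maps a downscaled whole retina to a silhouette mask.
A whole mosaic is processed by overlapping tiles (256 px at 12.5 % overlap
for counting, 512 px at 25 % on a 2048-px working image for segmentation);
overlapping predictions are stitched by per-pixel averaging, which
suppresses tile-edge artefacts. The binarized counting map is labelled into
8-connected components (the detected cells), detections outside the
segmented retina are discarded, and the per-retina deliverable is

* `count` — number of detected RGCs,
* `area_mm2` — retinal area from the mask pixel count and the pixel scale
  (default 2.17 px/µm),
* `density = count / area_mm2` (cells/mm²),

plus optional isodensity maps (Gaussian kernel density estimate of the
centroids, bandwidth 150 µm, scaled by the total count to cells/mm²),
overlay images and centroid coordinates. Agreement statistics used to
validate automated against manual counts are included: ICC(2,1) from the
two-way ANOVA mean squares, Bland–Altman percent bias with 95 % limits of
agreement, ordinary least squares, and the Jaccard index for masks.

The CNN engine (convolutions, batch normalisation, pooling, transposed
convolutions, Adam, the BCE+Dice loss and its gradients) is implemented in
the package in R with compiled BLAS-backed kernels, and is verified against
finite-difference gradients and an independent pure-R convolution oracle in
the test suite.

## Worked example

Generate a synthetic retina, train the desk-scale model pair, and quantify:

```r
library(rgcountr)

models <- desk_models(seed = 1)        # trains counting + segmentation (~9 min)

ret <- generate_retina(synthetic_spec(retina_radius = 470, seed = 550))
fm  <- flatmount(ret$image, ret$pixel_scale, "demo")
q   <- quantify_retina(fm, models$counting, models$segmentation,
                       working_px = 512, tile_px = 128)
print(q)
#> Retina 'demo': 2077 cells, 0.706 mm2, 2943 cells/mm2
c(truth_cells = nrow(ret$centres), truth_area = round(ret$area_mm2, 3))
#> truth_cells  truth_area
#>        2127       0.699
```

The printed line is the pipeline's deliverable: the detected cell count, the
segmented area in mm², and their ratio, the mean RGC density. Here the
ground truth is known exactly (2,127 cells on 0.699 mm², i.e. 3,043
cells/mm²), so the desk-scale models recover the density within about 3 %.
Held-out accuracy can be summarised with:

```r
ce <- desk_counting_error(models$counting, seed = 1)   # 20 held-out frames
ce$mape
#> [1] 1.801091
desk_segmentation_iou(models$segmentation, seed = 1)$iou
#> [1] 0.9846229
```

A batch folder of TIFFs is processed with `run_batch()` (or the
`inst/scripts/rgcountr.R` command line: subcommands `quantify`, `train`,
`transfer`, `simulate`, `evaluate`), producing `results.csv` with one row
per retina.

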