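---
title: "Methods: weakly-supervised grading of cervical dysplasia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weakly-supervised grading of cervical dysplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cervical squamous intraepithelial lesions are graded on an ordered
two-tier scale — non-neoplastic (NNeo), low grade (LSIL), high grade
(HSIL) — from H&E sections of LEEP samples and surgical specimens. The
diagnostic signal sits in the squamous epithelium, a thin ribbon that
occupies a small fraction of the tissue, and the grade depends on how far
immature basal-type cells extend through the ribbon's thickness: the
lower third for LSIL, the middle and upper thirds for HSIL. Slides with
no exocervical squamous epithelium are non-representative ("others").

`cervigrade` casts slide grading as a two-stage problem.

**Stage 1 — find the epithelium.** Tissue fragments are located on a
slide overview with an Otsu threshold and connected components; each
fragment crop is resized to a square network input and segmented by a
U-Net (double 3×3 convolution blocks, max-pool encoder, transposed-conv
decoder with skip connections, sigmoid head). The loss is the sum of the
pixel-mean binary cross-entropy and the soft Dice loss with smoothing
term $\lambda$:

$$L_s = \mathrm{BCE}(y,\hat y) + 1 -
  \frac{2\sum y\hat y + \lambda}{\sum y + \sum\hat y + \lambda},
  \qquad \lambda = 1 .$$

The BCE term is averaged over pixels and the Dice term uses whole-image
sums; $\lambda$ makes an empty prediction on an empty target a perfect
score, which matters because negative fragments (no epithelium) are part
of training.

**Stage 2 — grade the epithelium.** The merged level-0 epithelium mask
is reduced to one centerline per connected component and 512×512 tiles
are sampled at 20× along it. A CNN outputs a probability vector over the
three ordered grades per tile. Supervision is multiple-instance: a *bag*
is the tile set of a slide (LS, labelled slides), of one annotated
epithelium (AE), or a single fully-annotated tile (AT). Under the MIL
assumption the bag's label is carried by its *worst* tile, found by
ranking tiles on the expected severity

$$\mathbb{E}(\hat C) = \sum_{i=1}^{n} i\, p(\hat C = C^{(i)}),$$

which is monotone under shifts of probability mass toward more severe
classes. Training alternates, each epoch, an inference pass that
re-selects each multi-tile bag's worst tile (labelled with the bag
label) and a gradient pass over the selected tiles plus all AT tiles.
The loss is the ordinal quadratic-weighted-kappa loss

$$L_c = 1 - \kappa, \qquad
  \kappa = 1 - \frac{\sum_{y,\hat y} w_{y\hat y}\, x_{y\hat y}}
                     {\sum_{y,\hat y} w_{y\hat y}\, m_{y\hat y}},
  \qquad w_{y\hat y} = \frac{(y-\hat y)^2}{(n-1)^2},$$

with $x$ the observed matrix, and $m$ the expected matrix — the outer
product of the actual and predicted marginals normalised to the batch
size. At inference the slide label is the argmax class of the worst
tile; if the segmentation is empty the slide is "others" and no tile is
ever classified (the two code paths are mutually exclusive).

## Design choices where the design was open

Several steps admit more than one reasonable reading; the package fixes
them as follows.

* **Otsu input and polarity.** The threshold is computed on the luma
  channel of an overview capped at 2048 px; tissue is the class *below*
  the threshold (darker than glass). A 5-px disc closing bridges small
  gaps before labelling, and components below 0.05 % of the overview
  area are dropped as debris.
* **Fragment resizing.** Non-square fragments are padded with white to a
  square before resizing. Direct anisotropic resizing would distort the
  thin ribbon differently in x and y; padding preserves aspect ratio at
  the cost of some empty input area. The pad-then-scale transform is
  recorded exactly so crop-space masks map back to level-0 within 1 px.
* **Centerline.** "Refining the skeleton by repeated erosion and
  dilation" is implemented as iterative morphological thinning
  (Zhang–Suen), which is the well-defined object that procedure
  approximates, followed by the longest simple path over the skeleton's
  breadth-first spanning tree (exact on tree-shaped skeletons; loops are
  broken by the spanning tree). Thinning retracts ribbon ends by about
  half a thickness, so path ends are extended along their local
  direction to the mask boundary; without this the emission rule would
  undercount tiles on short ribbons.
* **Tile sampling.** Centers are emitted at the path start and then each
  time the cumulative x-advance reaches the interval (256 px at 20×,
  i.e. 50 % overlap of 512-px tiles). The x-axis rule is ill-posed for
  vertical ribbons, so when a path's overall extent is larger in y the
  same rule is applied to the y-advance and the output is flagged.
  Points are tile *centers*, tiles are axis-aligned, and the interval is
  interpreted in 20× pixel units.
* **Kappa-loss batching.** The observed matrix collects soft
  probabilities (differentiable); on hard one-hot predictions it reduces
  exactly to the integer confusion matrix, and this equivalence is
  enforced by a test. The loss is computed per minibatch; a single-class
  batch with all mass on that class has no defined chance correction and
  is flagged degenerate (κ := 0), contributing no gradient.
* **Worst-tile ties** break toward the higher HSIL probability, then
  stable tile order, making inference deterministic.
* **"Others" gating** defaults to strictly-zero epithelium pixels, with
  a configurable minimum area because real segmentations have speckle.
  Over-segmented non-representative slides are pushed through the
  classifier rather than special-cased.
* **Classifier class set** is strictly {NNeo, LSIL, HSIL}; "others" is
  produced only by the empty-segmentation rule, never trained on.
* **Initialisation.** Both networks train from random weights.
  ImageNet initialisation of the tile classifier is a known accelerator
  on real H&E but is an external artefact; the phantom tasks do not need
  it and random init keeps runs fully seeded.

## Evaluation conventions

The metrics module fixes the conventions that reproduce the reported
numbers for this family of pipelines: *balanced accuracy* is the
unweighted mean of per-class recall; *precision*, *sensitivity* and *F1*
are support-weighted averages of the per-class values (weighted
sensitivity is algebraically the micro accuracy, used as a self-test);
the quadratic weighted kappa is computed on integer counts with the
expected matrix normalised to the observed total; and *excluding* the
non-ordinal "others" class removes both its predicted row and its actual
column, so slides of other classes predicted "others" leave the
evaluation. Confusion matrices are oriented rows = predicted,
columns = actual. Epithelium detection is scored separately as the mean
of positive and negative recall over the binary question "was any
epithelium found". A rank-based one-vs-rest macro AUC is provided for
completeness but is not part of any validated surface.

## The phantom generator

Real cervical WSI cohorts are rarely redistributable, so the package
generates phantom slides that preserve exactly the structure the
pipeline exploits:

* 1–4 elliptical tissue fragments of low-frequency pink "stroma" on a
  white background, clearly darker than glass so Otsu separates them;
* per graded fragment, one epithelium ribbon following a smooth random
  arc near the fragment edge, nominal thickness drawn from a configured
  range and varying ±25 % along the length — curved, variable-width
  shapes exercise the centerline machinery;
* grade-dependent nuclear texture as a visual proxy for basal-cell
  proliferation depth: NNeo carries sparse dark nuclei in a thin basal
  band, LSIL dense nuclei in the basal third plus lighter
  koilocyte-like vacuole rings above, HSIL dense nuclei across the full
  thickness;
* "others" slides contain fragments but zero ribbon pixels;
* ground truth per slide: the binary mask, a thickness-band map
  (basal/middle/upper third), a nucleus map, a per-pixel region-label
  map, the generating spline of each ribbon, the epithelium outline
  polygons and small fully-labelled ROI polygons (GeoJSON).

The slide label of a graded phantom is the worst region label present —
one fragment always carries it — matching the MIL assumption by
construction. Class counts in generated datasets follow largest-remainder
apportionment of the configured mix, so manifests are reproducible;
all per-slide randomness flows through one seeded generator.

What phantoms deliberately do **not** model: stain variability and
scanner colour profiles, nuclear pleomorphism and mitoses, tissue folds,
blur, pen marks, or annotation noise. Passing the phantom-scale tests
therefore shows the machinery is correct and the learning tasks are
solvable end to end; it does not certify performance on real H&E.

## Problem sizes, schedules and numerics

The full-scale recipe kept in the defaults: U-Net depth 4 with 64 base
filters on 1024×1024 crops, Adam at 1e-4, batches of 4, 250 epochs,
best checkpoint by validation loss; classifier at 1e-5, batch 16,
300 epochs, best checkpoint by validation (bag-level balanced) accuracy;
512×512 tiles at 20× every 256 px.

The reduced configurations used by the tests and the acceptance script
are the package's own desk-scale choices: a depth-2, 8-filter U-Net on
256×256 single-fragment phantom crops (40 train / 4 validation /
10 held-out, 8 epochs, Adam 1e-3) and a 4-block, 8-filter classifier on
64×64 inputs resized from 96-px tiles of 768×576 phantoms (AT bags from
24 training slides, 6 validation slides, 35 epochs, Adam 1e-3, two
random restarts). The restarts exist because the kappa loss has a rare
degenerate optimum that collapses the most severe class — ordinally
correlated but compressed predictions still score a decent kappa since
the expected matrix adapts to the predicted marginals; validation
balanced accuracy picks the restart that escaped it. These sizes were chosen so
each training run finishes in minutes on one CPU while leaving a wide
margin over the tested floors (held-out Dice ≥ 0.70, held-out tile
balanced accuracy ≥ 0.80).

Numerical details: predictions are clamped to $[10^{-7}, 1-10^{-7}]$
before the BCE logs (the loss is unbounded at 0/1); the Dice smoothing
term rescues empty-vs-empty; network inputs live in $[0,1]$; He
initialisation throughout; Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$; the prediction threshold defaults to 0.5 (not part
of any stated recipe); polygon rasterization uses even-odd fill with
pixel-center inclusion, and all coordinates are 0-based, x = column,
half-open boxes. Both training loops are exactly reproducible given
their seed: same seed, bit-identical checkpoints.

## Known limitations

* The CNN engine is sized for the reduced configurations; the full-scale
  recipe (depth-4 U-Net at 1024², 250 epochs; a ResNet-scale tile
  classifier) is expressible but not practical on one CPU, and
  benchmark results on proprietary cohorts are out of scope.
* AUC against per-slide scores is provided but has no validated
  reference surface.
* The pyramid abstraction covers plain PNG-backed images with factor-2
  levels; vendor WSI containers are not parsed.
* Phantom realism is structural, not photometric (see above), so
  learned phantom models do not transfer to real slides.
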