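---
title: "Segmentation-free immune phenotyping: models and methods"
author: "immunopoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmentation-free immune phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiplex immunohistochemistry (mIHC) produces multichannel images — a
nuclear stain (DAPI), several immune markers (here CD3, FOXP3, CD20,
CD45RO, CD8) and a tumor marker — from which researchers want the
positions and phenotypes of lymphocytes, typically to quantify
tumor-infiltrating lymphocytes and their spatial organization. The
standard route segments every cell first and reads marker intensities per
mask. In dense lymphoid tissue this segmentation-first approach fails
*even when the segmentation is perfect*: 4 µm physical sections are
thicker than the lateral spacing of packed lymphocytes, so cells overlap
along the optical axis and spill signal into each other's footprints.
`immunopoint` takes the alternative route: it never segments, but directly
regresses (1) the proximity of every pixel to the nearest cell center and
(2) the expression of each marker on that nearest cell, from sparse
"click" annotations. Cell calling is then blob detection on the proximity
map, and phenotyping is thresholding of per-cell "pseudomarker" readouts.

## Training labels from point annotations

An annotator clicks a cell center and scores each marker on a 1–5 Likert
scale expressing certainty of positivity (1 certainly negative, 3
undecided, 5 certainly positive); background annotations mark
non-lymphocyte structures or empty sites. `build_proximity_map()` turns
these into a dense regression target on a 0.5 µm/px grid:

* value $5 - d$ inside the disk of radius 5 px (2.5 µm) around each cell
  annotation, where $d$ is the distance to the nearest annotated center —
  5 at the click, 0 at the disk boundary;
* $-2$ inside background-annotation disks;
* $-1$ everywhere else ("unknown status" — never sampled for training).

The ramp between the fixed endpoints (5 at the center, 0 at the boundary)
is linear; it is the simplest monotone interpolation and makes the
target's local maxima coincide exactly with annotation coordinates.
Where a cell disk and a background disk overlap, the cell wins (a
background click near a true cell should not erase the cell's evidence);
between overlapping cell disks, the maximum (equivalently: the nearest
center) wins. Phenotype maps are 0 outside disks and
$(\ell - 1)/4 \in [0,1]$ inside, with the nearest annotation taking
precedence; the affine map treats the Likert scale as evenly spaced,
which also motivates squared-error training losses below.

Training patches (63×63×7 inputs, 3×3×6 labels) are sampled uniformly
without replacement from one-eighth of the known-status pixels, capped at
1000 per tile, so each annotation is covered by many overlapping patches.
Inputs near the tile border are completed by mirror reflection; the label
maps are reflected the same way.

## The network

`build_model()` constructs a multi-task fully convolutional network:
nine 5×5 valid convolutions in three blocks with ResNet-like skip
connections (the block input, center-cropped by 6 px per side, is added
to the block's last pre-activation; block 1 projects its 7 input channels
through a 1×1 convolution), a 25×25 valid reduction convolution that
brings a 63×63 receptive field to a 3×3 feature map, one shared fully
connected stage, and two branches of two fully connected stages each —
proximity (1 channel) and pseudomarkers (5 channels). All "fully
connected" stages are 1×1 convolutions, and every convolution is valid
with stride 1, so the same weights run densely over arbitrarily sized
tiles. Batch normalization follows each convolution except the skip
projection; the fully connected stages use dropout (rate 0.2) instead.
No deep-learning framework is available in this R environment, so the
forward and backward passes (im2col + GEMM convolutions, batch-norm
statistics and gradients, dropout, Adam) are implemented directly in
RcppArmadillo; all randomness draws from R's RNG, so training is exactly
reproducible under a seed.

The exact kernel plan (nine 5×5 convolutions shrinking 63→27, one 25×25
reduction) is one of several that satisfy the three-block / 63×63→3×3
contract; it was chosen because it keeps every layer a plain valid
convolution with output stride 1, which makes dense inference exact
rather than approximate.

Training minimizes
$1\cdot\mathrm{MSE}(\text{proximity}) + 20\cdot\mathrm{MSE}(\text{pseudomarkers})$
with Adam at learning rate $10^{-3}$ (defaults in `train_config()`:
100 epochs). Augmentation applies flips and 90° rotations jointly to
input and label, then input-only intensity jitter
($s_1 \sim U(0.6, 2)$ multiplicative, $s_2 \sim U(-0.2, 0.2)$ additive)
and Gaussian input noise of sd 0.1. Batch size (128 by default) and
batch-norm momentum (0.9) are package choices. Inputs are normalized per
tile and channel to the 3rd–99.8th percentile range.

### Dense inference and the 3×3 window

During dense inference each output-map position *is* one unit of some
window's 3×3 output; mirror-padding the tile by 30 px (half the 61 px
receptive field) aligns the map exactly with the input pixels, which
realizes the "center element per location" readout. The alternative
`aggregate = "mean"` averages the overlapping window estimates, which for
a stride-1 fully convolutional network reduces to a 3×3 box filter of the
dense map; it is off by default.

The network is only approximately flip-equivariant — equivariance is
encouraged by augmentation, not enforced architecturally — so tests check
strong correlation between flipped and direct predictions rather than
exact equality.

## Cell calling and phenotyping

`detect_cells()` runs multiscale Laplacian-of-Gaussian blob detection on
the predicted proximity map with `min_sigma = 3`, `max_sigma = 5`,
`threshold = 0.07` (10 scales, overlap pruning at 0.5, stronger response
kept). Negative map values are clipped to 0 first: the −1/−2 sentinels
are training codes, not physical proximities. The detector is implemented
on analytic LoG kernels (truncated at 4σ) with scale-normalized responses
and strict 26-neighborhood maxima in (x, y, σ) space; tests verify it
against an independent exhaustive maxima scan.

Per detected center, `extract_pseudomarkers()` averages each phenotype
map over the 13-pixel disk of radius 2 px and clips to [0, 1].
`call_phenotype()` binarizes ψCD3, ψCD8, ψFOXP3, ψCD20 at 0.4 (ties count
positive) and maps: B = CD20⁺CD3⁻CD8⁻FOXP3⁻, Th = CD3⁺ only,
CTL = CD3⁺CD8⁺, Treg = CD3⁺FOXP3⁺, other = all negative, anything else =
invalid. ψCD45RO is never binarized — memory phenotype is a continuum and
is analyzed via polyserial correlation instead. Invalid detections are
excluded from density analyses (and logged); they indicate contradictory
marker evidence rather than a usable phenotype.

## The tissue simulator

Because fully annotated mIHC data cannot ship with the package, a 3D
Cellular Potts model (CPM) generates lymphocyte-dense tissue with exact
ground truth. Cells are two-compartment (cytoplasm + nucleus) spin
domains on a 0.5 µm lattice evolving by Metropolis-accepted copy attempts
(Moore-neighborhood candidates, 6-connectivity adhesion energy,
temperature T = 20) under

$$H = \sum_{\langle i,j\rangle} J(\tau_i, \tau_j)\,(1-\delta_{s_i s_j})
    + \lambda_V \sum_s (v_s - V_s)^2 .$$

Defaults: J(cytoplasm, medium) = 20, J(cytoplasm, cytoplasm′) = 40,
J(nucleus, own cytoplasm) = 10, J(nucleus, anything else) = 200 (this
keeps nuclei strictly enclosed), λ_V = 50. Simulation protocol: place
single-voxel seeds, relax 25 Monte Carlo steps so they circularize, place
one nucleus seed voxel at each cell's interior voxel nearest its
centroid, relax 50 more MCS (75 total). An 8-voxel slab (4 µm, matching
physical sections) is cut; membrane markers paint the outer cytoplasm
layer, nuclear markers the nucleus voxels, per-cell log-normal brightness
(σ_log = 0.3) and per-pixel additive Gaussian noise (5% of paint
intensity, clipped at 0) are applied, and intensities are summed along z.
Ground truth (exact mask and centroids) is read from the slab mid-plane.

Cell diameters are drawn uniformly from 7–10 µm; the total target volume
is the sphere volume at the drawn diameter, split 60% cytoplasm / 40%
nucleus. The diameter range was calibrated so that the mid-plane density
at full confluence is ≈ 30 000 cells/mm² and at 10% seeding ≈ 3000
cells/mm² — the regime in which segmentation-first phenotyping visibly
breaks down — with `N_confluent = lattice volume / mean cell volume`
(the lower end of the nominal small-lymphocyte range 5–10 µm produced too
many mid-plane crossings per volume once packing deformation is taken
into account). Simulated phenotype frequencies default to a
lymphoid-tissue-like mixture (`default_phenotype_freqs()`): 20% B, 25%
Th, 15% CTL, 10% Treg, 10% memory-T, 20% unlabeled background cells.

What the simulator deliberately does **not** emulate: channel crosstalk,
steric hindrance between antibodies, autofluorescence, and realistic
tissue architecture (follicles, vessels). Green tests on simulated data
therefore show that the pipeline solves the geometric overlap problem —
not that it is robust to real staining artifacts, which require real
annotated tissue to assess.

## Evaluation machinery

* **Sparse protocol** (`sparse_error_rates()`): an annotated lymphocyte
  is an error unless the nearest detected lymphocyte within 3.5 µm (7 px)
  has the same phenotype; a background annotation is an error if any
  detected lymphocyte falls within 3.5 µm. Exact Clopper–Pearson 95%
  intervals per category.
* **ROI protocol** (`match_roi()`): maximum-cardinality bipartite
  matching under the 3.5 µm cutoff; among maximum matchings the total
  matched distance is minimized (implemented as a Hungarian assignment
  with a large infeasible-pair penalty — the secondary objective makes
  the matching unique and stable under permutation). TP = matched same
  phenotype; unmatched or phenotype-mismatched detections are FP,
  annotations FN. `prf()` pools counts across ROIs and bootstraps ROIs
  (B = 1000, percentile intervals).
* **Count agreement** (`count_agreement()`): ICC in the one-way
  random-effects, single-measurement form — it ranges over [−1, 1] as
  required for an agreement statistic — plus RMSE, both bootstrapped
  over ROIs.
* **Ordinal agreement**: two-step polyserial / polychoric estimators
  (thresholds fixed at normal quantiles of the marginals, correlation
  maximizing the latent bivariate-normal likelihood; tetrachoric as the
  2×2 special case). Tests verify grid-search agreement to 10⁻³ and
  parameter recovery within ±0.05, and the Pearson limit at many levels.
* **Density profiles**: equal-width bins on log10 annotated-lymphocyte
  density; 4 bins by default (the bin count is a package choice; it is
  exposed in the API). Zero-density ROIs floor into the lowest bin.

## Spatial analyses

Tissue masks come from Gaussian-weighted adaptive thresholding (window
255 px, offset per staining) of the tumor channel (tumor) and of the sum
of all channels (tissue), with morphological closing (radius 5 px),
hole-filling and small-object removal (10⁴ px); stroma = tissue − tumor.
Hole-filling is needed because purely local thresholds detect only the
rims of large uniform regions. The signed Euclidean distance to the
tumor border (boundary pixels exactly 0, negative inside) defines the
invasive margin: the stromal band within 100 µm. "Inside tumor" counts
the whole tumor mask; the 100 µm limit applies to the stroma side only.
Neighbor preference uses pairs of lymphocytes within 14 µm center
distance: entry (A, B) is the mean number of type-B neighbors per type-A
cell divided by the mean number of type-B neighbors per lymphocyte — 1
under exchangeable labels (verified by a permutation null in the tests).
Compartment comparisons across slides use Welch's t-test (unequal
variances is the safer default when only "t-test" is specified).

## Problem sizes in tests and the self-contained validation

The test suite validates everything on simulated data at sizes chosen for
a single-CPU workstation: 64³ µm³ volumes (128³ voxels) for density
calibration and the density sweep; a reduced network (width 8, fully
connected width 24) trained for 14 epochs on 1400 patches from six
simulated tiles at 25% confluence for the end-to-end check, evaluated on
four held-out slices as matched F-scores for B versus T (pooled Th, CTL,
Treg) against a label-permutation baseline. These sizes are package
choices that keep the full suite reproducible in minutes while leaving
the default (width 16 / 100 epochs) configuration available for real
training runs. The headline numbers reported on real tumor cohorts
(error rates, ICC against counts, polyserial agreement, flow-cytometry
concordance) require the externally deposited annotated images and are
out of scope for the self-contained suite: the machinery that computes
them is validated here on synthetic fixtures and oracles instead.

## Numerical details and edge cases

* Coordinates are 0-based, x = column, y = row, origin top-left; user
  outputs in µm, internal arithmetic in px (0.5 µm/px).
* Constant image channels normalize to all-zero with a warning (an ε
  guards the percentile denominator).
* Energy bookkeeping in the CPM is incremental; `potts_energy()`
  recomputes from scratch and the two agree exactly (a test asserts it).
  Lattice boundaries pair with medium in the adhesion sum.
* Cells annihilated during relaxation (volume 0) are dropped with a
  warning; at high confluence a handful of the smallest seeds lose out.
* FCS export writes minimal FCS 3.1 (list mode, float32, little-endian)
  with fixed-width offsets; a matching reader round-trips it and any
  flow-cytometry tool can open it.
* Float TIFF output is written by a small built-in writer (sample format
  3) because the available TIFF binding stores only scaled integers;
  standard readers, including `tiff::readTIFF()`, read it losslessly.
* `polychoric_cor()` warns at boundary estimates (|ρ| > 0.99), which
  arise from tables with empty discordant cells.

## Known limitations

* The simulator's marker model is binary (a phenotype expresses a marker
  or not); real expression distributions are graded. CD45RO continuity is
  represented only through the Likert machinery, not the image model.
* Exact flip equivariance of the trained network is not guaranteed (see
  above).
* The adaptive-threshold tissue segmentation is a transparent baseline,
  not a learned segmenter; its parameters must be tuned per staining.
* The reduced training recipe in the tests trades accuracy for runtime;
  production use should train the default-width model for the default
  epoch count on real annotations.
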