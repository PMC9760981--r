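---
title: "Methods: gland segmentation, histogram harmonization, and the cross-device protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gland segmentation, histogram harmonization, and the cross-device protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Meibomian glands (MG) secrete the lipid layer of the tear film; their
atrophy — visible as gland dropout on infrared meibography — is a leading
cause of evaporative dry eye. Quantifying dropout requires segmenting two
regions in a meibography image: the tarsal eyelid area and the gland area
inside it. From a 3-class label map (0 background, 1 eyelid, 2 MG) the
clinically used quantities follow directly:

* **MG loss rate** = `1 - MG area / eyelid area`, a number in [0, 1];
* **meiboscore**, the 0–3 clinical grade that increments for every third
  of the eyelid lost (0 for no loss, 1 up to 1/3, 2 up to 2/3, 3 above).

A segmentation model is typically trained on images from a single device.
Deployed on a second device with a different grayscale response, it sees a
systematically shifted intensity distribution ("domain shift") and can
degrade badly. `meibseg` implements the full pipeline for studying that
question: segmentation network, the two intensity-harmonization operators
usually proposed as remedies (histogram specification and CLAHE), the
atrophy quantification, the statistical comparison machinery, and a
synthetic phantom generator that emulates two devices so everything can be
validated end to end without clinical data.

## Synthetic phantoms: what they emulate and what they do not

No public meibography dataset with 3-class masks exists, so the package
generates its own study material. A phantom is built from:

* an **eyelid band** bounded by two parabolic margins (curvature
  parameter, default 0.12 of the image height);
* **gland stripes**: a periodic tiling of parallel, slightly tortuous
  vertical stripes (a shared sinusoidal offset; amplitude 10–25% of the
  stripe spacing). Healthy lids are almost fully tiled by glands, so
  stripes occupy `gland_width_frac = 0.985` of each period by default and
  the thin residue forms the inter-gland septa labelled eyelid;
* **atrophy** by proximal truncation: each stripe keeps only the fraction
  of its length nearest the lid margin. The keep fraction is calibrated
  against the rasterized full-stripe coverage so that the realized mask
  loss rate tracks `atrophy_frac` (within about ±0.03 over random
  geometries; the package's tests require ±0.05). Per-gland jitter (±0.04)
  keeps the truncation front irregular. At `atrophy_frac = 1` all stripes
  are removed.
* a **device style**: a monotone 256-level tone curve, global
  brightness/contrast, radial vignetting and Gaussian sensor noise applied
  to the ideal rendering (background 35, lid 110, glands 185 with mild
  longitudinal shading, 8-bit). The two built-in styles are deliberately
  far apart — `style_internal()` is bright with an S-curve, and
  `style_external()` is dark and gamma-compressed — producing an average
  histogram gap of about 1.7 (out of a maximum 2) between populations,
  a much stronger shift than between typical real devices. Styles change
  intensities only; masks are shared by construction.

Phantoms reproduce the features downstream stages depend on — parallel
elongated glands inside a band, controllable loss rate, two populations
with very different histograms — and none of the photographic nuisances of
real meibography (eyelashes, specular reflections, defocus, partially
everted lids, annotation noise). Passing tests on phantoms therefore
validates the machinery (losses, metrics, preprocessing, training
dynamics, the direction of the domain-shift effect), not clinical accuracy
on patient images.

Reproducibility: every phantom is generated under its own integer seed;
dataset seeds derive from a master seed by a counter hash, so collections
are identical regardless of generation order.

## Preprocessing operators

**Histogram specification (HS).** The target is the average histogram of
the training-device population: each image's 256-bin histogram is
normalized to sum 1, then averaged bin-wise. An image is remapped through
the look-up table `lut[v] = min { t : templateCDF(t) ≥ imageCDF(v) }` —
the composition of its empirical CDF with the generalized inverse of the
template CDF, with ties broken toward the smallest level. The LUT is
monotone, so intensity order is preserved; the output CDF matches the
template CDF within the largest template bin mass (the quantization
bound), and self-specification is the identity up to one gray level. A
degenerate template with all mass in one bin maps every pixel to that
level, by design not an error. The template is built from whatever
internal-role image pool is available at call time.

**CLAHE.** Tile-wise histogram equalization with a clip limit expressed as
a multiple of the mean bin height; clipped excess is redistributed
uniformly, and per-pixel mappings are bilinearly interpolated between the
four surrounding tile mappings. Defaults: 64-pixel tiles (the
neighbourhood-block size commonly quoted for meibography enhancement) and
clip limit 2.0; neither an interpolation scheme nor a clip limit is fixed
by prior art, so both are configurable. Two deliberate conventions: a
single tile with a clip limit too high to bite reduces exactly to global
histogram equalization `round(255·cdf(v))`, and a constant image is
returned unchanged (equalizing a single-bin histogram is otherwise
undefined).

## Augmentation

The training protocol expands the training set twelve-fold using five
transform families: gamma transformation, rotation, blur, noise addition
and flips. The composition within the factor of 12 is not fixed by the
protocol, so the package uses an auditable recipe of twelve
single-transform variants: 2 flips, 3 rotations (±10°, 180°), 3 gammas
(0.7, 1.3, 1.6), 2 Gaussian blurs (σ = 1, 2 px), 2 noise draws
(σ = 5, 10). Originals are kept separately, i.e. "12 times" is read as
twelve augmented variants per input; configurations that do not sum to 12
are rejected because the factor is a stated contract. Geometric transforms
are applied identically to image and mask (nearest-neighbour resampling
for labels; rotation fills exposed borders with background), photometric
transforms to the image only; 180° rotation is implemented as an exact
pixel permutation so loss rates are preserved bit-for-bit.

## The network

A U-Net-style encoder–decoder:

* **Encoder**: the 34-layer residual design with its classifier head
  removed — a 7×7 stride-2 stem with batch normalization and ReLU, 3×3
  stride-2 max pooling, then four stages of 3/4/6/3 basic residual blocks
  (two 3×3 conv-BN pairs plus identity or projection shortcut), doubling
  channels and halving resolution per stage; total stride 32.
* **MSP bottleneck**: parallel 3×3 convolutions at dilation rates 1, 2, 3
  (effective 3×3, 5×5, 7×7 kernels), each followed by ReLU, concatenated
  and fused by a 1×1 convolution with ReLU. The effective extents are
  verified empirically in the tests by measuring impulse-response support.
* **Decoder**: five steps of 2× bilinear upsampling, concatenation with
  the matching encoder feature map (stage 3, stage 2, stage 1, stem; the
  final full-resolution step has no skip), and two 3×3 conv-BN-ReLU
  blocks. A described alternative with 4× upscaling per step is
  inconsistent with a stride-32 encoder whose skips change resolution by
  2 per stage; it is exposed as `decoder_steps = "x4"` (4×/4×/2× with the
  skips that remain available) but is not the default, because matched
  skip resolutions are what make U-Net concatenation meaningful.
* **Head**: 1×1 convolution onto 3 class scores at input resolution;
  prediction is the per-pixel argmax, resized back to the original image
  size with nearest-neighbour interpolation.

`width_scale` multiplies every channel count (floored at 4), so the same
architecture runs from desk-scale (0.0625–0.25) to full capacity (1.0).
Weights are He-initialized from a configuration seed; no pretrained
weights are used, so results are reproducible offline. Inputs are resized
to `input_size` (default 256, must be divisible by 32) and scaled to
[0, 1].

The engine behind these layers (convolution via im2col/GEMM with explicit
backward passes, batch normalization, pooling, bilinear upsampling, Adam)
is part of the package and is validated by finite-difference gradient
checks through the complete network in the test suite.

## Training

Dice loss, written for one mask as `1 − 2|y∩y′| / (|y|+|y′|)`, is extended
to three classes as the unweighted mean of per-class soft Dice against the
one-hot target, background included (the simplest faithful extension; the
class list is configurable in effect through the mask alphabet). A
smoothing constant of 1e-6 in numerator and denominator guards the 0/0
case of a class absent from both prediction and target. L1 regularization
is applied to convolution kernel weights only (not biases or
normalization parameters) with default coefficient 1e-6 — unspecified in
the protocol, chosen so the penalty starts around 1% of the initial loss.

Optimization follows the stated protocol: Adam with decay rates 0.9 and
0.999 (the two quoted constants are Adam's canonical exponential-decay
rates), initial learning rate 3e-4 multiplied by 0.8 every five epochs
(closed form `3e-4 · 0.8^⌊e/5⌋`, epochs counted from 0), batch size 32,
up to 50 epochs. Checkpoint selection keeps the epoch with the best mean
validation DSC — the protocol reports test metrics without naming a
selection rule, and best-validation is the defensible default; without a
validation set the final parameters are kept.

## Evaluation

* **Region metrics** per image and region (eyelid = label 1, MG =
  label 2): DSC, recall, precision from pixel counts. Whether "eyelid
  region" means label 1 alone or the union with the glands is ambiguous in
  3-class annotation; the package scores label 1 alone (the annotated
  class), while the **loss rate** uses the union of labels 1 and 2 as
  eyelid area — glands lie within the eyelid, and using label 1 alone
  could push rates outside [0, 1]. Images whose truth region is empty make
  recall undefined; they are flagged and excluded from mean ± SD
  aggregates, with the exclusion count reported.
* **Meiboscore** uses right-closed intervals, with grade 0 reserved for
  exactly zero loss, mirroring the clinical "no loss / ≤1/3 / 1/3–2/3 /
  >2/3" structure.
* **Group comparisons** use the two-sided Mann–Whitney U test at
  significance level 0.01 — exact for small tie-free samples, normal
  approximation with tie correction otherwise — treating the two
  conditions as independent samples (the unpaired test is what the
  protocol names, even though conditions share images).
* **Domain-gap diagnostics**: the total-variation distance between the
  two populations' average histograms (in [0, 2]), and a 2-D embedding of
  downscaled (32×32) flattened images — PCA to at most 30 components, then
  nonmetric multidimensional scaling, a nonlinear rank-preserving
  embedding — scored by the mean silhouette width of the device labels.
  Near-zero separation for a random split of one population, clearly
  positive separation across a genuine style gap.

## The cross-device experiment

`run_experiment()` mirrors the six-condition protocol: internal-style
training/validation/testing sets and an external-style testing set are
generated; the HS template comes from the internal-style pool ("the
training device as guide"); two models are trained — one on raw images,
one on CLAHE-preprocessed images — and each condition is scored by its
matching model (CLAHE conditions by the CLAHE-trained model; the pairing
is configurable because the original description implies but never states
it). Conditions: internal, internal+CLAHE, external, external+HS,
external+CLAHE, external+HS+CLAHE. Outputs are per-image metric and
loss-rate tables, mean ± SD summaries, per-condition RMSE of predicted
vs true loss rate, pairwise Mann–Whitney comparisons between
preprocessing variants, and the two domain-gap diagnostics, all as CSV
plus a JSON run record with the seed and package version.

## Problem sizes and numerical choices

The packaged validation runs use deliberately small problem sizes chosen
as the smallest at which each claim is meaningful: phantoms of 64–256 px;
a quarter-width network at 64 px input for training runs (60 training
phantoms, 20 epochs, batch 4, protocol learning rate) that recovers
held-out same-style MG DSC ≈ 0.98 while the strongly shifted external
style scores far lower — the qualitative domain-shift ordering, which is
the claim the synthetic study can support. The single-image overfit
diagnostic (200 steps, one phantom) uses a constant learning rate of 1e-3
rather than the full protocol schedule: with one image per epoch the
per-epoch decay collapses the step size within 200 "epochs", which is an
artifact of the degenerate fixture rather than of the protocol, and the
diagnostic's purpose is to show the engine can drive Dice loss below 0.1
on a memorizable input.

Other numerical conventions: 8-bit intensities end to end with 256-bin
histograms; label resampling is always nearest-neighbour; bilinear
interpolation uses aligned corners; Dice smoothing 1e-6; batch
normalization momentum 0.1 and epsilon 1e-5; Adam epsilon 1e-8; the
finite-difference gradient check passes at relative error below 1e-3 (the
engine achieves ~1e-7).

## Known limitations

* Phantoms are geometric idealizations; no claim is made about clinical
  Dice levels, and the published clinical tables are not reproducible
  without the original images.
* The device styles are free choices with a histogram gap far stronger
  than typical real device pairs, so external-condition degradation on
  phantoms is more extreme than the published cross-device gaps.
* The embedding diagnostic uses nonmetric MDS rather than t-SNE; both are
  nonlinear neighbour-preserving embeddings, and the separation score, not
  the particular algorithm, carries the diagnostic content.
* Training is CPU-bound and single-threaded beyond BLAS; full-width
  256-px training at batch 32 is architecturally supported but intended
  for machines with substantially more compute.
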