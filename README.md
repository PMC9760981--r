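# meibseg

Segmentation and atrophy quantification for infrared meibography, with a
cross-device evaluation protocol.

Meibomian glands (MG) secrete the lipid layer of the tear film; their
dropout, visible on meibography as loss of the bright gland stripes inside
the tarsal eyelid, drives evaporative dry eye. `meibseg` segments each
image into background / eyelid / gland (labels 0/1/2) with a compact
residual U-Net and derives the two clinical quantities:

* **MG loss rate** `= 1 − |MG| / |eyelid|` (areas in pixels, eyelid taken
  as the union of labels 1 and 2), a value in [0, 1];
* **meiboscore**, the 0–3 grade that increments for each third of the
  eyelid lost.

The segmentation network is a U-Net-style encoder–decoder: a 34-layer
residual encoder (stem + stages of 3/4/6/3 basic blocks, no fully
connected layers), a multi-scale perception bottleneck of parallel 3×3
convolutions at dilation rates 1/2/3 (effective 3×3, 5×5, 7×7 kernels)
fused by a 1×1 convolution, and a bilinear-upsampling decoder with skip
concatenations onto a 3-class head. Training uses multi-class soft Dice
loss `L = 1 − 2|y∩y′| / (|y|+|y′|)` (averaged over classes) with L1
regularization, Adam (0.9/0.999), learning rate `3e-4 · 0.8^⌊epoch/5⌋`,
batch 32, up to 50 epochs, and a 12-fold augmentation recipe (flips,
rotations, gamma, blur, noise).

Because segmentation models are usually trained on one device and
deployed on another, the package also implements the two intensity
harmonization operators studied for that setting — **histogram
specification** to the averaged histogram of the training-device
population, and **CLAHE** — plus per-region DSC/recall/precision,
loss-rate RMSE, Mann–Whitney comparisons between preprocessing
conditions, and 2-D embedding / histogram-gap domain diagnostics.

No public meibography dataset with 3-class masks exists, so the package
ships a synthetic phantom generator: parallel tortuous gland stripes
inside a curved eyelid band, a controllable atrophy fraction realised by
distal truncation of each stripe, and two device "styles" (tone curve,
contrast, vignetting, noise) with strongly different intensity
histograms. Everything downstream — preprocessing, training, evaluation,
the six-condition cross-device experiment — is exercised and tested on
these phantoms.

## Worked example

```r
library(meibseg)

# one labelled phantom at 40% atrophy, internal-device style
ph <- generate_phantom(phantom_spec(atrophy_frac = 0.4, seed = 7),
                       style_internal())
ph
#> <labeled_image> 256x256, style 'internal', MG loss rate 0.407
mg_loss_rate(ph$mask)        # 0.407  (realised loss rate of the mask)
meiboscore(mg_loss_rate(ph$mask))   # 2    (in (1/3, 2/3])

# a desk-scale network: same architecture, quarter width, 64 px input
net <- build_network(network_config(width_scale = 0.25, input_size = 64))
net
#> <mgseg_net> residual U-Net, width 16 (scale 0.25), stages 3-4-6-3,
#>   MSP dilations 1,2,3, input 64x64, 2,033,811 parameters

# two device populations and their domain gap
a <- generate_dataset(20, phantom_sampler(height = 64, width = 64),
                      style_internal(), seed = 1)
b <- generate_dataset(20, phantom_sampler(height = 64, width = 64),
                      style_external(), seed = 2)
style_histogram_gap(a, b)           # 1.705  (total variation, max 2)
domain_embedding(a, b, seed = 3)$separation   # 1  (silhouette: fully separated)

# train, predict, evaluate
fit <- fit_network(net, a, val_set = b[1:4],
                   config = train_config(batch_size = 4, max_epochs = 10,
                                         input_size = 64))
pred <- predict(fit, a[[1]])        # label matrix over {0,1,2}
region_metrics(pred, a[[1]]$mask, region_label = 2)$dsc
```

The numbers mean: the phantom's mask realises the requested 40% atrophy
(loss rate 0.407, meiboscore grade 2); the two device styles differ by a
total-variation histogram distance of 1.705 out of 2 and separate
completely in the 2-D embedding — the domain shift the cross-device
protocol studies.

The full six-condition protocol (internal / internal+CLAHE / external /
external+HS / external+CLAHE / external+HS+CLAHE, two trained models,
metric tables, RMSE, Mann–Whitney comparisons, diagnostics) runs with:

```r
report <- run_experiment(experiment_config(seed = 1, out_dir = "runs/demo"))
report$metrics_summary
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/meibseg.R` (`generate`, `preprocess`, `augment`, `evaluate`,
`run-experiment`).

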