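# denseunet

Slice-wise segmentation of the prostate gland and its zones — central zone
(CZ) and peripheral zone (PZ) — on axial T2-weighted-like MR volumes, using a
family of densely connected U-nets. The package is a complete, self-contained
R implementation of the model family and its training/evaluation protocol:
volume I/O and preprocessing, a seeded synthetic prostate phantom generator,
elastic/rigid augmentation, the training losses, a full evaluation suite and
a k-fold cross-validation harness. The convolutional engine (im2col
convolutions, max pooling, strided transposed convolutions, softmax, Adam,
hand-written backpropagation) is built into the package via Rcpp, so nothing
beyond an ordinary R toolchain is required.

## Who it is for

Researchers in medical image analysis who want a transparent, fully testable
reference implementation of the Dense-X U-net family and of the evaluation
conventions used for zonal prostate segmentation (Dice, MRAVD, Hausdorff and
mean surface distance in mm, apex/mid/base regional scoring, paired t-tests)
— runnable end-to-end on synthetic phantoms, without patient data or a GPU.

## The models

Both variants are fully convolutional encoder–decoders with six
encoder/decoder stages plus a 1024-wide bottleneck (feature widths
16 → 1024), 2×2 max pooling, 3×3 stride-2 transposed convolutions, long skip
concatenations between mirrored stages, and a 1×1 convolution + pixel-wise
softmax head over 3 classes (background / CZ / PZ; whole prostate = CZ ∪ PZ):

* **classical U-net** — two 3×3 conv+ReLU per stage: 34.6 M parameters;
* **Dense-X U-net** — each stage holds X dense blocks (four 3×3 convolutions
  whose input concatenates the block input and all previous layer outputs,
  growth rate `min(width/8, 26)`) followed by a 1×1 transition back to the
  stage width. Dense-2 at full scale: 15.6 M parameters, 0.45× the classical
  budget.

Training minimises cross-entropy, focal or soft-Dice loss (or weighted
combinations) with Adam on pooled, shuffled axial slices.

See `vignettes/dense-unet-methods.Rmd` for the full methods account:
architecture conventions and how the parameter budgets were calibrated, the
loss formulas, phantom design, metric definitions and known limitations.

## Worked example

```r
library(denseunet)

## full-scale architectures: parameter budgets
dense2_full    <- build_dense_unet(network_spec(dense_blocks = 2))
classical_full <- build_classical_unet(network_spec(dense_blocks = 0))
count_parameters(dense2_full) / 1e6
#> [1] 15.57094
count_parameters(classical_full) / 1e6
#> [1] 34.60415

## desk-scale end-to-end: 12 phantoms, reduced Dense-2, 60 iterations
p <- phantom_params(n_slices = c(10, 14), inplane_size = 64, inplane_mm = 2)
cohort <- generate_cohort(p, 12, seed = 7)

spec <- network_spec(stage_widths = c(8, 16, 32, 64), dense_blocks = 2,
                     growth = 4, input_size = 64)
set.seed(42)
net <- build_dense_unet(spec)
cfg <- train_config(loss = loss_config("cross_entropy"), batch_size = 5,
                    learning_rate = 1e-3, max_iterations = 60, seed = 1)
fit <- train(net, cohort[1:10], cfg)
round(fit$log$loss[c(1, 30, 60)], 3)
#> [1] 0.719 0.106 0.034

## segment the two held-out phantoms and evaluate
preds  <- lapply(cohort[11:12], function(cs) predict_volume(fit$net, cs$volume))
report <- evaluate(preds, lapply(cohort[11:12], `[[`, "labels"))
report
#> EvalReport: 2 cases x 3 structures
#> Cohort summary:
#>  structure n   MDS   CI95    StD  MeDS  MRAVD    MHD   MSD   Sen   Spc
#>         cz 2 77.03 0.6213 0.4483 77.03 8.7221  9.821 2.335 73.67 99.50
#>   prostate 2 98.17 0.7037 0.5077 98.17 0.3908  2.000 0.228 97.98 99.89
#>         pz 2 81.34 0.8684 0.6266 81.34 5.7169 11.678 1.088 83.66 99.14
```

After one minute of CPU training the network segments the whole gland almost
perfectly (mean Dice 98.2%); the thin zonal structures score lower (CZ 77%,
PZ 81%) — the same difficulty ordering seen on real data, driven by class
imbalance and boundary ambiguity. `MDS`/`MeDS`/`StD`/`CI95` are percent Dice
statistics, `MRAVD` the mean absolute relative volume difference (%), `MHD`
and `MSD` the mean directed Hausdorff and mean surface distance in mm, and
`Sen`/`Spc` voxel-wise sensitivity/specificity (%).

A YAML-driven cross-validation experiment (fold construction, training of
several variants, per-fold metric CSVs, pooled summaries and pairwise paired
t-tests) runs through `run_experiment()`; a thin command-line front end lives
in `inst/cli/denseunet.R` (`phantom-generate`, `experiment-run`, `evaluate`).

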