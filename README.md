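# voxseg

Semi-supervised semantic segmentation of 3D grayscale volumes (knee MRI and
the like) when expert labels are scarce. The package implements, from first
principles in R + Rcpp:

* a **3D U-Net** segmentation network whose decoder skip connections carry a
  concurrent spatial & channel squeeze-and-excitation attention block with
  parallel global max- and average-pooling branches (*scSE-block+*), trained
  by Adam on voxel-wise cross-entropy — forward *and* backward passes are
  implemented in the package (BLAS offset-GEMM convolutions), so runs are
  bit-reproducible from a single seed;
* a **self-training loop**: train on the labeled set, partition the
  unlabeled volumes into subsets, pseudo-label one subset per round, refine,
  extend the training set (truth labels are never overwritten), retrain;
* a **fully-connected CRF** over voxels for pseudo-label edge refinement,
  with energy

  E(f) = Σᵢ ψᵤ(fᵢ) + Σ_{i<j} μ(fᵢ,fⱼ)·k(i,j),    ψᵤ = −log P,

  Potts compatibility μ, and Gaussian appearance + smoothness kernels
  k(i,j) = ω₁·exp(−‖xᵢ−xⱼ‖²/2σ_α² − (yᵢ−yⱼ)²/2σ_β²) + ω₂·exp(−‖xᵢ−xⱼ‖²/2σ_γ²),
  solved by mean-field iteration (exact dense message passing at desk scale,
  truncated neighborhoods for full volumes), plus an exhaustive-enumeration
  global minimizer as a test oracle;
* the standard **evaluation suite** — Dice, average symmetric surface
  distance (ASSD), and 95th-percentile Hausdorff distance (HD95) — each
  validated against brute-force all-pairs oracles to 1e-9;
* a seedable **phantom generator** (ellipsoidal "bone" wrapped by a thin
  "cartilage" shell, Gaussian noise, optional bias field) so every pipeline
  runs and tests offline, plus NIfTI I/O for real volumes.

See `vignettes/semi-supervised-volumetric-segmentation.Rmd` for the full
methods account.

## Worked example

```r
library(voxseg)

# a small synthetic cohort: 3 labeled, 6 unlabeled, 2 held-out phantoms
cohort <- generate_dataset(
  phantom_config(shape = c(16, 16, 16), bone_radius_range = c(0.14, 0.22),
                 noise_sigma = 0.05),
  n_labeled = 3, n_unlabeled = 6, n_test = 2, seed = 42)

cfg <- selftrain_config(
  num_subsets = 2, use_crf = TRUE,
  crf = crf_config(neighborhood_radius = 2, iterations = 5),
  train = train_config(learning_rate = 1e-3, epochs = 10),
  initial_train = train_config(learning_rate = 3e-3, epochs = 40),
  network = network_config(num_classes = 3, base_channels = 8),
  seed = 42)

res <- run_self_training(cfg, cohort$split, held_out = cohort$test)
res$records
#>   round_index num_pseudo_added mean_train_loss heldout_dice
#> 1           0                0      0.33708267    0.8958017
#> 2           1                3      0.02632432    0.9245477
#> 3           2                3      0.02585330    0.9309011

evaluate(predict_labels(res$net, cohort$test[[1]]$volume),
         cohort$test[[1]]$labels)
#> <vox_metrics> foreground: dice 0.8864 | assd 0.3830 voxels | hd95 1.4728 voxels
#>  class      dice       assd     hd95 status
#>      1 0.9689441 0.06896552 1.000000     ok
#>      2 0.8351648 0.21703029 1.414214     ok
```

Row 0 of `records` is the labeled-only model (the baseline); subsequent rows
show the training set growing by one pseudo-labeled subset per round, and
`heldout_dice` tracks the mean foreground Dice on the held-out pairs. The
final `evaluate()` call prints the three indices — Dice (overlap in [0,1]),
ASSD and HD95 (boundary distances; voxels here because spacing is unit) —
pooled over the foreground and per class (1 = bone, 2 = cartilage shell).

A command-line interface wrapping the same functions (subcommands
`simulate`, `train`, `predict`, `refine`, `evaluate`, `selftrain`) is
installed at `system.file("cli", "voxseg.R", package = "voxseg")`.

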