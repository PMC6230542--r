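# petac — PET attenuation correction from pseudo-CT synthesized out of uncorrected PET

`petac` is an R implementation of a deep-learning route to quantitative PET
attenuation correction (AC) when no CT or MR is available: a convolutional
encoder-decoder (CED) is trained to map 2D axial slices of a
non-attenuation-corrected (NAC) FDG-PET image to a continuously valued
*pseudo-CT* in Hounsfield units. The pseudo-CT is converted to a 511 keV
attenuation map by the standard piecewise-linear CT scaling and used in
ordinary attenuation-corrected OSEM reconstruction, so PET quantification
no longer depends on an acquired CT.

The package is aimed at researchers in PET methodology who want a fully
inspectable, desk-scale version of this pipeline: every stage the clinic
delegates to the scanner — attenuated forward projection, Poisson counting
noise, ordered-subsets MLEM reconstruction, post filtering — is implemented
here, together with a seeded digital head-phantom generator that supplies
paired CT / tracer-activity volumes. That closes the loop end to end and
makes every claim testable.

## The method in brief

* **Network** — VGG16-style encoder of unit layers (3×3 conv → batch norm →
  ReLU, 2×2/stride-2 max pooling; 13 conv layers, 64→512 filters in the
  full-size spec), mirrored decoder with bilinear un-pooling, one-filter
  output convolution, four symmetric encoder→decoder shortcut connections
  inserted *before* batch norm and activation (full pre-activation), plus an
  input→output shortcut. A reduced spec shares the same code path for
  desk-scale work.
* **Preprocessing** — PET scaled by 6000 Bq/ml; CT offset +1000 HU and
  scaled by 2000 HU; minimal bounding-box crop (one box per volume, from the
  PET object); slice-wise bilinear resampling to the network matrix
  (200×180 full-size, 64×64 desk); pixel-wise Softsign
  `x/(1+|x|)`; all steps exactly invertible back to HU.
* **Training** — ADAM, fixed learning rate 0.001, mini-batch 12, MSE image
  loss in the Softsign domain, He-style init, per-epoch checkpoints, model
  taken at the least-loss epoch.
* **Physics** — μ = μ_w(1+HU/1000) below 0 HU (clamped), μ_w + s·HU above;
  attenuated parallel-beam projection `c·exp(−∫μ dl)·∫a dl` with a matched
  adjoint; OSEM (24 iterations, 3 subsets) with attenuation in the system
  model and a 4 mm Gaussian post filter.
* **Evaluation** — tissue discretization (bone HU > 300, air HU < −400,
  strict), per-tissue Dice, MAE in HU, voxel-wise percent PET error vs the
  CT-based reference, ROI statistics with paired t-tests and Bonferroni
  correction (0.05/21 ≈ 0.0024).

## Worked example

```r
library(petac)

# a small cohort: 4 training + 2 held-out phantoms, short schedule
cfg <- run_config(master_seed = 1, n_train = 4, n_test = 2, n_epochs = 4)
res <- full_run(cfg, out_dir = "demo_run", verbose = TRUE)
unlist(res$metrics)
```

A full desk-scale run (`run_config(master_seed = 1)`: 40 training / 8
held-out phantoms, 64×64×8 grid, reduced network, 64 epochs, ~16 min on one
core) printed:

```
dice_soft                  0.8864
dice_bone                  0.7657
dice_air_cavity            0.5805
mae_hu                   218.2
mae_baseline_hu          282.7
pet_abs_err_deepac_pct     6.20
pet_abs_err_nac_pct       75.0
nac_to_deepac_error_ratio 12.10
```

Reading: on held-out phantoms the synthesized pseudo-CT overlaps the true
CT with Dice 0.89 / 0.77 / 0.58 for soft tissue / bone / in-head air
(soft tissue highest, as expected — it dominates the head), with a mean
absolute error of ~218 HU against a 283 HU all-soft-tissue baseline. PET
reconstructed with the pseudo-CT μ-map lands within ~6% of the CT-corrected
reference on average, while the uncorrected NAC image is off by ~75% — a
~12-fold error reduction. The soft-tissue and bone overlaps sit near the
resolution limit of the coarse 3.5 mm desk grid (every 1-px interface ring
is several percent of the head cross-section); in-head air is hardest, since
an MSE-trained network predicts the conditional mean and small noisy cavities
pull it toward the −400 HU threshold. `res$roi_report` holds the per-ROI
error table with paired t-tests.

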