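# epreg — edge-aware pyramidal deformable registration of 3D volumes

`epreg` performs unsupervised deformable registration of 3D scalar
volumes (typically skull-stripped T1-weighted brain MRI in NIfTI
format). Given a fixed volume *I<sub>f</sub>* and a moving volume
*I<sub>m</sub>*, it predicts a dense deformation φ minimizing

L = Σ<sub>i=1..4</sub> LNCC( down<sub>2^i</sub>(I<sub>f</sub>),
down<sub>2^i</sub>(I<sub>m</sub>) ∘ G<sub>i</sub> ) + λ ·
Σ<sub>p</sub> ‖∇φ(p)‖²

with no ground-truth deformations: LNCC is patch-based local
normalized cross-correlation (window 9³), the second term a diffusion
regularizer (λ = 1000), and G<sub>4</sub>..G<sub>1</sub> a
coarse-to-fine pyramid of deformation grids. The network (EPReg) feeds
each stream a two-channel input — the intensity volume plus its 3D
Sobel edge map — through a shared convolutional encoder; an affine
block regresses 12 degrees of freedom from the coarsest paired
features and three deformable blocks progressively refine residual
displacement fields, G<sub>i</sub> = up₂(G<sub>i+1</sub>) + φ<sub>i</sub>.
A trained network registers a pair in one forward pass. Training (Adam,
lr 2e-4 halved every 10 epochs) and the required reverse-mode
differentiation are implemented in the package (R + Rcpp/Armadillo);
no deep-learning framework is needed.

The package is aimed at researchers in volumetric image analysis who
want a self-contained, CPU-runnable implementation of edge-aware
pyramidal registration: every stage — Sobel edge maps, spatial-
transformer warping, multi-scale loss, Dice / Hausdorff / ASSD
evaluation, synthetic ground-truth experiments — is exposed as an R
function and as a CLI subcommand.

## Worked example

Register a synthetic pair with a known ground-truth deformation and
evaluate the result:

```r
library(epreg)

# labelled 48^3 phantom, deformed by a known smooth field (max 4 voxels)
# plus a small affine transform
pair <- make_pair(shape = 48L, n_rois = 4L, seed = 1L, amplitude = 4)

# optimize the registration objective on this pair from scratch
# (the deformed image is the fixed input so the ideal grid is the truth)
cfg <- epreg_config(widths = c(8L, 16L, 16L, 32L))
fit <- instance_optimize(pair$moving, pair$fixed, cfg = cfg,
                         iters = 200L, seed = 1L)
reg <- register_pair(pair$moving, pair$fixed, fit$params,
                     moving_labels = pair$labels_f)

labs <- 1:4
mean(sapply(labs, function(l) dsc(pair$labels_m, pair$labels_f, l)))
#> [1] 0.8219518          # mean ROI Dice before registration
mean(sapply(labs, function(l) dsc(pair$labels_m, reg$warped_labels, l)))
#> [1] 0.9448667          # mean ROI Dice after registration

err <- field_to_voxel(reg$agg_field - pair$gt_field)
mean(sqrt(err[,,,1]^2 + err[,,,2]^2 + err[,,,3]^2))
#> [1] 0.5347876          # mean endpoint error vs truth, voxels
```

The pre-registration mean displacement of this pair is 1.63 voxels, so
the recovered field removes about two thirds of the misalignment while
the ROI overlap rises from 0.82 to 0.94. `evaluate_pair()` produces the
full per-label Dice/HD/ASSD table, and `sobel_edge_map()`,
`total_loss()`, `train_epreg()` etc. expose the individual stages.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/epreg.R", package = "epreg"))')
Rscript $CLI synth --shape 48 --n-rois 4 --amplitude 4 --seed 7 --out-dir fx/
Rscript $CLI sobel --in fx/fixed.nii.gz --out fx/edge.nii.gz
Rscript $CLI train --data-dir fx/ --out-checkpoint net.rds --epochs 3
Rscript $CLI register --fixed fx/fixed.nii.gz --moving fx/moving.nii.gz \
        --checkpoint net.rds --out-warped fx/warped.nii.gz
Rscript $CLI evaluate --fixed-labels fx/fixed_labels.nii.gz \
        --warped-labels fx/moving_labels.nii.gz --out metrics.csv
```

Every run writes a JSON manifest (command, options, seed, input
digests) beside its outputs.

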