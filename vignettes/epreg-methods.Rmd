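---
title: "Edge-aware pyramidal deformable registration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-aware pyramidal deformable registration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epreg)
```

## The registration problem

Deformable registration seeks a dense deformation $\phi$ such that a
moving volume warped by it, $I_m \circ \phi$, matches a fixed volume
$I_f$:

$$\hat\phi \;=\; \arg\min_\phi \;
  \mathcal{L}_{sim}(I_f,\, I_m \circ \phi)
  \;+\; \lambda\, \mathcal{L}_{smooth}(\phi).$$

Classical methods solve this per pair by iterative optimization; an
unsupervised registration network instead amortizes the optimization
into a convolutional model that emits $\phi$ in one forward pass,
trained with exactly the objective above and no ground-truth
deformations. `epreg` implements an edge-aware pyramidal network of
this family (EPReg) for 3D scalar volumes such as skull-stripped
T1-weighted brain MRI.

## Architecture

**Dual inputs.** Each stream receives two channels: the intensity
volume (min–max normalized to $[0,1]$) and its 3D Sobel edge map

$$E = \sqrt{(S_x * I)^2 + (S_y * I)^2 + (S_z * I)^2},$$

where each $3^3$ kernel differentiates along one axis (slice at offset
$-1$ equal to $[[1,2,1],[2,4,2],[1,2,1]]$, zero centre slice, negated
slice at $+1$) and smooths across the others. The edge channel
emphasizes boundaries so that alignment attends to structure rather
than raw intensity alone; disabling it with
`epreg_config(use_edges = FALSE)` yields the intensity-only ablation
("PReg"). Gradient magnitudes are invariant under kernel flip, so the
maps are computed as cross-correlations; borders use replicate padding;
the edge channel is rescaled to $[0,1]$ so both channels enter the
encoder on comparable scales (the rescale keeps the two input channels
commensurate and costs nothing because local NCC is intensity-affine
invariant).

**Shared encoder.** One parameter set encodes both streams (features of
fixed and moving volumes live in the same space). Four stride-2 blocks
produce pyramids $F_1..F_4$ and $M_1..M_4$ at strides 2–16: block 1 is
a strided convolution; blocks 2–3 add two residual blocks each; block 4
ends in an atrous spatial pyramid pooling module (parallel $3^3$
convolutions at dilations 1, 2, 4, fused by a $1^3$ convolution). Every
block applies feature normalization and ReLU.

**Affine block.** $F_4 \Vert M_4$ pass through a residual block, a
$1^3$ convolution to 12 channels and global average pooling: 12 values
forming a $3{\times}4$ matrix that generates the dense affine grid
$G_4$ (rotation/scale/shear + translation, the rigid-ish global
alignment that shrinks the search space of the deformable stages).

**Deformable blocks.** For $i = 3, 2, 1$ the block sees
$[\,F_i \,\Vert\, M_i \circ \mathrm{up}(G_{i+1}) \,\Vert\,
\mathrm{up}(F_{i+1}) \,\Vert\, \mathrm{up}(M_{i+1} \circ G_{i+1})
\,\Vert\, \mathrm{up}(\phi_{i+1})\,]$, i.e. the current level's paired
features (the moving side warped by the coarser grid), the fused
coarser paired features, and the coarser residual field. Two residual
blocks and a $1^3$ convolution emit the 3-channel residual $\phi_i$,
and

$$G_i = \mathrm{up}_2(G_{i+1}) + \phi_i.$$

The moving volume is finally warped by $G_1$ upsampled $2\times$ to
full resolution (the finest level sits at stride 2, so a final
upsampling is unavoidable; we upsample the grid rather than the warped
half-resolution image).

Notable reading choices where the architecture description is loose:
the written residual-block form of the deformable input lists the
unwarped $M_i$, while the accompanying prose warps it with the previous
estimate — the prose is followed. "Combination" of grids across levels
is additive in normalized coordinates, not resampling-based composition
(addition is what makes zero residuals an exact no-op at every level).
Paired features and dual inputs are fused by channel concatenation, the
minimal operator consistent with the description.

## Coordinates, units and the identity anchor

All grids and fields live in normalized $[-1,1]$ align-corners
coordinates per axis: voxel $j$ of an $n$-voxel axis sits at
$-1 + 2j/(n-1)$. Under this convention trilinear $2\times$ upsampling
of a grid needs no magnitude rescaling and maps the identity grid of a
coarse level exactly onto the identity grid of the finer level, which
is what makes the additive pyramid well defined. Converters
`field_to_voxel()` / `field_to_normalized()` translate displacement
units.

The final $1^3$ convolutions of the affine and deformable heads are
zero-initialized, so an untrained network is *exactly* the identity
map: its loss equals the similarity of the unwarped pair. This anchors
training (the first gradient step starts from a meaningful baseline
rather than a random deformation) and gives the tests an exact
invariant.

Feature normalization is per-channel over the spatial domain (instance
normalization). With volumetric batches of size 1 — the operating
regime of this package — batch statistics coincide with instance
statistics and running averages are degenerate, so a single normalizer
is used in both training and inference; this also keeps single-pair
instance optimization stable.

## Losses

**Similarity.** Patch-based local normalized cross-correlation with a
$v^3$ window ($v = 9$ by default): for each voxel $p$,

$$cc(p) = \frac{\bigl(\textstyle\sum_{p_n}(I_f - \bar I_f)(I_w - \bar
I_w)\bigr)^2}{\bigl(\sum_{p_n}(I_f-\bar I_f)^2\bigr)\bigl(\sum_{p_n}(I_w-\bar
I_w)^2\bigr) + \varepsilon}, \qquad
\mathcal{L}_{sim} = -\sum_{p\in\Omega} cc(p).$$

A form of this loss sometimes written without the squares in the
denominator is dimensionally inconsistent (not invariant under
intensity rescaling and not bounded by 1), so the standard squared-sum
local-NCC denominator is implemented — flagged here deliberately. $\varepsilon = 10^{-5}$ (on $[0,1]$
intensities) handles locally constant patches, where the exact
expression is $0/0$. Windows that exit the volume are filled by edge
replication. Window sums use separable box filtering and are pinned to
a direct triple-loop summation in the tests.

**Regularizer.** A diffusion penalty on the aggregated full-resolution
field $\phi = \sum_{i=1}^4 \mathrm{up}_{2^i}(\phi_i)$ (the affine
level contributes its dense grid minus the identity):

$$\mathcal{L}_{smooth}(\phi) = \sum_p \lVert\nabla\phi(p)\rVert^2$$

with forward finite differences; boundary sites without a forward
neighbour are excluded. The field enters in its stored
normalized-coordinate units (the choice of units for this term is a
convention; using the stored representation keeps the term independent of
any unit conversion and is the convention recorded here for
reproducibility). $\lambda = 1000$ by default.

**Total.** Similarity is applied at all four pyramid scales against
trilinearly downsampled images,

$$\mathcal{L} = \sum_{i=1}^4 \mathcal{L}_{sim}\bigl(\mathrm{down}_{2^i}(I_f),\,
\mathrm{down}_{2^i}(I_m) \circ G_i\bigr) + \lambda\,
\mathcal{L}_{smooth}(\phi).$$

Note the sum runs over the four grid levels only — the full-resolution
pair is never compared directly; the finest comparison happens at
stride 2. This follows the stated objective; its consequence is that
sub-voxel detail at full resolution is driven only indirectly.

## Differentiation and optimization

Gradients flow through warping (trilinear sampling is differentiable
in both the image and the grid), the box-filtered correlation and the
finite-difference regularizer via a small reverse-mode autodiff tape
built into the package (dense R arrays, Rcpp kernels for convolution,
resampling and window sums). An end-to-end finite-difference check of
$\partial\mathcal{L}/\partial\phi$ is part of the test suite.

Population training (`train_epreg()`) uses
Adam, initial learning rate $2\times10^{-4}$ halved every 10 epochs
(`lr_schedule()`), all ordered pairs of distinct training volumes
shuffled per epoch, batch size 1. The "0.5 weight decay after every 10
epoch" phrasing is read as learning-rate step decay, not Adam weight
decay — the sentence attaches it to the learning rate.

Instance optimization (`instance_optimize()`) fits the same objective
on a single pair from the identity initialization; it is the
desk-scale surrogate for population training used throughout the
experiments here. Its constant learning rate defaults to $10^{-3}$: a
rate large enough to move the zero-initialized heads appreciably in
200 steps, small enough that the first steps do not destroy the
identity anchor (larger rates visibly diverge in the first few
iterations).

## Synthetic data

`make_phantom()` builds smooth textured backgrounds with `n_rois`
blob-shaped regions of distinct intensity and matching labels;
`make_deformation()` samples an affine transform within stated
magnitudes plus Gaussian-smoothed white noise rescaled to a maximum
displacement norm of `amplitude` voxels; `make_pair()` warps the
phantom with the composed ground-truth grid (labels warped
nearest-neighbour), so recovery can be scored against a known answer.
Everything is a pure function of its seed.

The phantoms emulate what the method needs from its inputs — smooth
intensity fields, labelled structures with edges, deformations of
controlled amplitude and smoothness. They do *not* emulate MRI
acquisition (bias fields, Rician noise, anatomical shape statistics,
inter-subject variability), so passing recovery tests demonstrates the
correctness and the basic capacity of the machinery, not clinical-grade
registration accuracy on real brains.

Because the generator produces `moving = warp(fixed, G_gt)`, the
recovery experiment feeds the *deformed* image as the network's fixed
input and the phantom as its moving input; the ideal predicted grid is
then `G_gt` itself and the recovered field is scored directly against
the truth (registering the other way round would target the inverse
deformation, which the generator does not provide in closed form).

## Experiment scale

At full scale the method is meant for GPU-class training on $192^3$
inputs over hundreds of epochs; this package targets CPU-scale reproducibility of the
method's *properties*. The recovery and ablation experiments
(`recovery_experiment()`, `edge_ablation_experiment()`) use $48^3$
phantoms with 4 ROIs, non-rigid amplitude 4 voxels (smoothness 6
voxels) plus a small affine (3°, 3% scale, 2% translation), 200
instance-optimization steps, 3 seeds, and encoder widths
$(8, 16, 16, 32)$; the package default widths are $(16, 32, 32, 64)$.
Widths are a free architecture hyperparameter; both settings are recorded in checkpoints.

```{r, eval = FALSE}
tab <- edge_ablation_experiment(seeds = 1:3)
tab
```

## Numerical choices

* Out-of-domain warp samples clamp to the border; sampling positions
  within $10^{-9}$ voxels of a lattice node collapse to the node, so
  identity warps are bitwise exact.
* Trilinear resampling is align-corners everywhere (preprocessing,
  pyramid up/down-sampling, loss downsampling) for consistency with
  the coordinate convention.
* Min–max intensity normalization maps constant volumes to all-zero
  (degenerate range) rather than erroring.
* Label maps are warped nearest-neighbour (trilinear would blend
  integer labels).
* Surface metrics use 6-connectivity boundary voxels and exact
  Euclidean point-set distances; the Hausdorff distance is the true
  maximum (not HD95), with points interior to the other region
  contributing distance zero, which makes the boundary-based
  computation equal to the solid-region definition. Distances are in
  voxel units. Dice of a label absent from both maps is defined as 1
  with a warning (strict mode errors).

## Known limitations

* The deformation model is not diffeomorphic: nothing prevents folding
  beyond the diffusion penalty. No scaling-and-squaring integration or
  inverse consistency is provided.
* The smoothness/similarity balance depends on resolution when fields
  are expressed in normalized coordinates; $\lambda = 1000$ is the
  method's default and was not re-tuned for $48^3$ volumes.
* Instance optimization fits network weights to one pair; it shares
  the objective with population training but not its generalization —
  use `train_epreg()` with a volume collection for a reusable model.
* CPU-scale channel widths bound the detail the deformable heads can
  express; at full widths and $192^3$ inputs the implementation is
  functional but slow without GPU-class hardware.
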