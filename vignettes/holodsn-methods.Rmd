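---
title: "Adaptive 3D descattering for inline holography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive 3D descattering for inline holography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holodsn)
```

## The problem

Inline holography records a single intensity image — the interference of a
coherent illumination wave with the light scattered by the sample — and
asks for the three-dimensional sample behind it. For dense particle
suspensions the linear reconstruction (backpropagating the hologram depth
by depth) is overwhelmed by two artifact families: the missing-cone
elongation of every particle along the optical axis, and multiple-scattering
cross-talk that grows with particle density, size and refractive-index
contrast, and with depth into the volume. `holodsn` implements a
simulation-trained, adaptive descattering pipeline for this setting: a
physics simulator generates holograms with known ground truth, a
mixture-of-experts network removes the scattering artifacts from the linear
reconstruction, and an assignment-based protocol scores 3D particle
localization.

The imaged system is a water-filled channel (refractive index 1.33) of
particles illuminated at 632.8 nm and imaged through a 0.4 NA, 20x
objective onto a sensor with 3.45 um pixels: effective lateral pixel
172.5 nm, lateral resolution $\lambda_m/\mathrm{NA} \approx 1.2$ um, axial
resolution $\lambda_m/(1-\sqrt{1-\mathrm{NA}^2}) \approx 5.7$ um. The
full-scale volume is $176.64 \times 176.64 \times 500\ \mu m^3$,
i.e. $1024 \times 1024$ pixels and 500 um of depth.

```{r optics}
cfg <- optics_config()
effective_pixel(cfg)
axial_resolution(cfg)
unlist(grid_dimensions(cfg))
```

## Scene synthesis

`sample_particle_field()` draws particle centers by Poisson-disk dart
throwing: uniform candidates are rejected when they fall closer than a
minimum distance to an accepted center. The minimum distance defaults to
the particle diameter, which is the weakest constraint that still forbids
overlapping spheres; nothing in the physical model requires a larger
exclusion zone, so none is imposed. Counts follow from number density
times box volume (`density_to_count()`): $1.6 \times 10^4\ \mu L^{-1}$ in
the full-scale box gives 250 particles; the seen-density grid
$\{1.6, 3.2, 6.41, 12.82\} \times 10^4\ \mu L^{-1}$ spans 250–2000.
Heterogeneous suspensions draw each particle's index contrast and/or
diameter from uniform distributions centered on the nominal values
(`sample_heterogeneity()`), with half-widths given as percentages.

`voxelize()` renders the field on the fine grid by testing sphere
membership at voxel centers — no antialiasing, because the downstream
labels are binary and detection-valued, so a partial-occupancy voxel has
no meaning the loss could use.

## Forward model: split-step beam propagation

Holograms are simulated by the beam-propagation method: the volume is
sliced at $\delta z = 118.4$ nm (a quarter of the in-medium wavelength;
this fine sampling is what lets the simulation capture multiple
scattering), and a unit plane wave is marched through the slices,
alternating a thin phase screen
$\exp\!\big(i \tfrac{2\pi}{\lambda}\,\Delta n(x,y,z)\, \delta z\big)$
with angular-spectrum diffraction over $\delta z$ in the background
medium. After the last slice the field sits at the volume's exit face,
which is the hologram plane; the recorded hologram is $|field|^2$.

Numerical choices, all explicit in the code:

* The quarter-wavelength constant is kept at 118.4 nm, which yields
  exactly 4222 fine slices over 500 um. ($\lambda/(4 \times 1.33)$ is
  strictly 118.95 nm; the 0.5% difference is irrelevant to the physics but
  the grid constant is the one that defines the voxel counts, so it wins.)
* Evanescent components are zeroed rather than exponentially decayed:
  propagation is then exactly unitary on the propagating band, which the
  tests exploit (`angular_spectrum_propagate` round trips to 1e-10).
* Lateral wrap-around is controlled by optional FFT padding. The padding
  margin is filled with the unscattered carrier wave — a constant that
  propagates into itself — so padding never creates artificial edges and a
  scatter-free volume still produces unit intensity to 1e-6. The default
  pad factor is 2 for grids up to 256 px and 1 (periodic) at full scale,
  where the field of view is large compared to single-particle diffraction
  cones.
* Sensor noise is limited to optional additive Gaussian noise on the
  intensity (clamped at zero); no shot noise or MTF modeling.

## Linear reconstruction: holographic backpropagation

The network input is the minimum-norm linear estimate: the hologram is
numerically propagated backwards slice by slice,
$R(x,y;z_j) = \mathcal{F}^{-1}\{\mathcal{F}\{I\} \cdot H(u,v;z_j)\}$,
with $H$ the conjugated angular-spectrum (Weyl) form of the free-space
Green's-function transfer kernel, unit-modulus on the propagating band and
zero outside. The analytic kernel is used instead of an FFT of the sampled
$e^{ikr}/r$: it is alias-free, and any constant prefactor of the Green's
function is irrelevant because the volume is standardized before entering
the network.

Reconstruction slices sit at $z_j = j \cdot 5\ \mu m$, $j = 1..100$
(full scale), measured **from the hologram plane into the volume** — slice
1 is nearest the hologram and the hologram plane itself is not a
reconstruction slice. The 5 um step approximately matches the axial
resolution; localizing finer than the optics resolve would be spurious
precision. Because the hologram plane is the exit face, scene coordinates
(measured from the illumination entrance face) map to reconstruction depth
as $d = L_z - z$; `make_ground_truth()` and `truth_centroids()` apply this
mapping so labels, reconstructions and scores share one axial axis. A
regression test pins the convention: a particle simulated nearer the
hologram plane peaks at a smaller slice index.

Ground-truth volumes are built by projecting each fine slice to its
nearest reconstruction slice with a logical OR within each bin — OR rather
than averaging because the labels are detections, and a particle present
anywhere in the bin is present in the bin.

## Preprocessing

Volumes enter the network as the amplitude of the complex backpropagation;
each volume and each hologram is standardized to zero mean and unit
variance **as a whole**, never per patch, so a patch keeps the evidence of
its parent's scattering level (this is what lets the gating network read
the scattering condition off a patch). Per-slice rescaling is deliberately
not applied: depth-dependent artifact statistics are part of the signal
the network must learn. Patches of $128 \times 128$ pixels (full axial
extent) are cut on a grid of stride 64 for training (64-pixel overlap) and
stride 128 for validation/testing, offsets starting at 0 with trailing
remainders dropped; this floor rule is the one that produces the published
counts (225 sub-volumes per training image, 10800 from 48 volumes, 15750
from 70; 64 patches per image, 5120 from 80). All-background sub-volumes
are kept: they occur at the lowest density and the network must handle
them.

## The dynamic synthesis network

A single "expert" is a V-net style 3D encoder–decoder. Each of four
scales applies two convolution blocks (3x3x3 convolution, instance
normalization with learnable gain/shift, ReLU) and a ceil-mode 2x max
pooling; with a $128 \times 128 \times 100$ patch the bottleneck is
$8 \times 8 \times 7$ (lateral 128-64-32-16-8, axial 100-50-25-13-7).
The decoder mirrors the encoder with nearest-neighbour upsampling,
skip-connection concatenation and a 1x1x1 sigmoid head emitting per-voxel
particle probabilities. Channel widths double per scale from a
configurable base (16 at full scale, giving a few-million-parameter
expert). The exact layer tables of the original implementation are not
published; the V-net here is parameterized to satisfy every printed
constraint (bottleneck size, parameter ratios) and is otherwise a design
choice of this package.

The dynamic synthesis network (DSN) holds $n \ge 2$ such experts (3 by
default) and a gating network (GTN): a small VGG-style 2D CNN
(conv/ReLU/maxpool stages, global average pooling, two dense layers) that
maps the matching normalized hologram patch to synthesis weights
$\alpha = \mathrm{softmax}(\cdot)$, nonnegative and summing to one.
Softmax is chosen as the normalization because the weights must form a
convex combination; one $\alpha$ gates everything for a given input. Per
input:

* **feature synthesis** — every scale of the expert encoders' feature
  pyramids, bottleneck included, is blended as
  $F_s = \sum_i \alpha_i F_i$, and the blended skip features pass directly
  to the decoder without further encoding;
* **decoder synthesis** — every learnable decoder parameter is blended as
  $D_s = \sum_i \alpha_i D_i$, so the decoder that runs is literally a
  convex combination of the expert decoders.

Instance-norm gains and shifts are included in the decoder blend: they are
learnable parameters like any other, and excluding them would break the
defining identity below. (Were batch-style running statistics used, they
would be excluded as non-learnable; instance normalization sidesteps the
question.) The keystone property — tested for every expert index — is
that a one-hot $\alpha$ makes the DSN output equal that expert's output
exactly; training never enforces this, the architecture guarantees it.

## Training

The loss is voxel-wise binary cross entropy against the binary ground
truth (predictions clamped to $[10^{-7}, 1-10^{-7}]$), which promotes
sparse detections; all depths are weighed equally. The DSN adds L2 weight
decay $\gamma \lVert W \rVert_2^2$ with $\gamma = 10^{-6}$. Adam is the
optimizer throughout. Full-scale hyperparameters are kept as named
presets: expert (lr $10^{-4}$, batch 4), baseline generalist (lr
$10^{-5}$, batch 20), 3x generalist (lr $10^{-4}$, batch 1), DSN (lr
$10^{-5}$, batch 1). Two initializations are implemented: Xavier for
everything, or Xavier for the GTN with the experts copied from per-density
pretrained checkpoints; the pretrained route is what makes the
mixture-of-experts mechanism legible, because each expert starts already
specialized. Model selection takes the checkpoint with the lowest
validation loss — the published procedure names only "a validation set",
so the selection metric is this package's choice; selecting on validation
Jaccard index instead is possible by scoring checkpoints externally. No
learning-rate schedule or early stopping is used (none was described).

All forward and backward passes are written natively (Rcpp kernels for
convolutions and pooling, hand-derived gradients elsewhere), verified
against central finite differences. The gradient of the synthesis weights
collects both blending paths:
$\partial L/\partial \alpha_i = \langle \partial L/\partial D_s, D_i\rangle
 + \sum_{scales} \langle \partial L/\partial F_s, F_i \rangle$.

## Localization scoring

The network's probability volume is scored as a detection problem:

1. **Binarization** — per-slice Otsu thresholding (256 histogram bins over
   the slice's own range; near-constant slices become background).
   Slice-wise, because artifact severity grows with depth and one global
   threshold would trade shallow precision against deep recall.
2. **Cluster filter** — 26-connected components with fewer than 10 voxels
   are discarded (a 1 um particle occupies ~21 voxels on the
   reconstruction grid); the boundary is inclusive at 10.
3. **Centroids** — per-component means of voxel centers, in um.
4. **Matching** — a minimum-total-Euclidean-distance one-to-one assignment
   between predicted and true centroids (Jonker–Volgenant-style solver,
   exhaustively verified at small n), then an elliptical gate of
   $4 \times 4 \times 12\ \mu m$ (4x the particle size laterally,
   about twice the axial resolution in depth): matched pairs inside the
   gate are true positives; everything else decomposes into false
   positives and false negatives. Matching on plain Euclidean distance
   with the gate applied afterwards mirrors the published order of
   operations; a gate-normalized assignment metric is available behind a
   flag. No distance cutoff is applied inside the assignment itself —
   the gate performs that role afterwards.
5. **Jaccard index** — $JI = TP/(TP+FP+FN)$, reported per group of 10
   axial slices (50 um) with mean and standard deviation across volumes.
   TP/FN bins come from the ground-truth depth; FP particles have no true
   partner, so they bin by predicted depth.

`weight_statistics()` summarizes GTN outputs per scattering condition
(component-wise mean and spread), the desk-scale analogue of inspecting
how the gate routes different conditions.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions: spherical scatterers of
controlled density, size and index contrast, placed without overlap,
imaged through the stated optics with full multiple scattering. It does
not emulate experimental nuisances — sensor noise beyond optional additive
Gaussian, aberrations, partial coherence, cuvette-wall reflections, or
particle motion. Passing tests therefore demonstrate the correctness of
the simulator, the reconstruction, the synthesis mechanism and the
scoring, and the trainability of the models at desk scale; they do not
certify descattering quality on experimental holograms, which at full
scale required days of GPU training on thousands of sub-volumes.

## Problem sizes used by the tests and the acceptance script

The package's own experiments run on a reduced grid chosen as the smallest
system in which every mechanism is still exercised end to end: a
$32 \times 32\ \mu m$ field of view at 64 px (0.5 um pixel), 40 um of
depth (336 BPM slices, 8 reconstruction slices), 2 um particles at 3
(sparse) and 30 (dense) particles per volume, experts with two scales and
two base channels, 200 pretraining and 400 co-training iterations. These
sizes are stated here as the package's reference desk-scale configuration;
`optics_mini_config()` and `dsn_mini_architecture()` encode them.

## Known limitations

* The BPM's paraxial-free split-step is standard but not exact for very
  high-NA scattering; the published implementation's padding and boundary
  details were not restated there, so this package's choices (carrier
  padding, evanescent zeroing) are documented replacements.
* Training at full scale (1024x1024x100, millions of parameters, ~100k
  iterations) is out of scope on CPU; full-scale figures of merit from GPU
  training are not reproduced here.
* UMAP embedding of hologram patches is not included; the patch-extraction
  arithmetic that would feed it is (`patch_origins()`).
* Only spherical, non-absorbing, stationary scatterers are modeled.
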