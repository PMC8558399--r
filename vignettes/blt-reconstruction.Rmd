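---
title: "Learned bioluminescence tomography on layered phantoms: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned bioluminescence tomography on layered phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Bioluminescence tomography (BLT) tries to recover the three-dimensional
distribution of an internal luminescent source — typically
luciferase-labeled tumor cells in a small animal — from the light that
reaches the tissue surface. Photons at these wavelengths are strongly
scattered, so the surface pattern is a heavily blurred, depth-attenuated
shadow of the source, and the inverse problem is ill-posed: many internal
distributions explain the same surface image, and small measurement noise
maps to large reconstruction errors.

`bltrecon` implements a learned inverse operator: a compact one-dimensional
convolutional network (1DCNN) is trained on simulated pairs of surface
photon flux density and known source support, and then maps a measured flux
vector directly to a per-node source score. Everything needed to reproduce
the study — phantom meshes, the forward model, dataset synthesis, training
and evaluation — is generated programmatically from a single seed.

## Forward model

Light propagation is modeled with the diffusion approximation to the
radiative transfer equation, appropriate for scattering-dominated tissue
($\mu_s' \gg \mu_a$):

$$-\nabla\cdot\big(D\,\nabla\varphi\big) + \mu_a\,\varphi = S,
\qquad D = \frac{1}{3(\mu_a + \mu_s')},$$

with the Robin (partial-current) boundary condition
$\varphi + 2AD\,\partial\varphi/\partial n = 0$ at the tissue–air
interface. $A$ captures internal reflection from the refractive-index
mismatch; by default it is derived from $n = 1.37$ through the standard
empirical polynomial fit for the effective reflection coefficient,
giving $A \approx 3.05$, and it can be overridden.

The equation is discretized with linear tetrahedral finite elements. The
assembled operator — stiffness plus absorption mass plus the boundary mass
scaled by $1/(2A)$ — is sparse, symmetric positive definite; one sparse
Cholesky factorization per (mesh, optics) pair is reused for every source
in a dataset sweep. Sources are entered as unit power density on the
source's tetrahedra, i.e. the load vector is the plain mass matrix applied
to the binary node indicator, so total emitted power scales with source
volume. The forward map is linear in the source, which is what licenses
building dual-source samples by adding single-source fluxes.

The forward interface is deliberately small (`assemble_system()`,
`solve_forward()`, `surface_flux()`), so a higher-order transport model
(e.g. a simplified spherical-harmonics solver) can be swapped in without
touching the learning pipeline.

Default optical coefficients (mm⁻¹), typical of mouse head tissue at the
firefly-luciferase emission band:

| region | $\mu_a$ | $\mu_s'$ |
|--------|---------|----------|
| brain  | 0.0389  | 1.7134   |
| skull  | 0.0804  | 2.0690   |
| muscle | 0.1154  | 0.4674   |

The table's scattering column is treated as *reduced* scattering
$\mu_s'$: the magnitudes (0.5–2 mm⁻¹) are characteristic of $\mu_s'$, not
of the raw scattering coefficient, which is one to two orders larger in
tissue. This is configurable.

## Phantom generation

The anatomy is a three-region nested sphere — brain core, skull shell,
muscle shell — meshed by splitting every cell of a regular lattice into six
tetrahedra (Freudenthal/Kuhn subdivision, conforming across cells) and
keeping cells whose center lies inside the outer radius. Each tetrahedron
is labeled by the innermost region containing its centroid. The default is
radii 4/6/8 mm at 1 mm edge length: 2,849 nodes, 13,056 tetrahedra, 1,250
surface nodes, and 437 brain-region nodes. These proportions were chosen
once so that the scaled study has roughly 3,000 mesh nodes at ~1 mm
spacing and a few hundred enumerable brain-node single sources — a brain
core occupying a modest fraction of the head, as in a real mouse — and are
free parameters of `phantom_spec()`.

Surface nodes are persisted with the mesh in ascending node-index order;
that order defines the arrangement of every surface flux vector, which is
what makes stored datasets and trained models mutually consistent. Depth
of a source is defined as the distance from its barycenter to the nearest
boundary triangle (exact point-to-triangle distance); the lattice surface
is a staircase, so depths carry an $O(h)$ geometric wobble relative to the
ideal sphere.

One caveat of the lattice mesh: the Kuhn subdivision singles out the cube
diagonal, so the mesh is symmetric under coordinate permutations and point
inversion but not under the full octahedral group. A centered source
therefore produces surface flux that is exactly equal only within
permutation/inversion orbits; tests assert exactly that invariance.

## Dataset synthesis

Single sources follow a traversal scheme: every node of the brain region
in turn is a source center, and the source is the set of tetrahedra
incident to that node (a "node star", 1.3–4 mm³ on the default phantom —
smaller and more uniform than an irregular anatomical mesh would give,
where the same construction spans roughly 3–25 mm³). The label vector `X`
is binary over mesh nodes, marking the star's vertices; binary labels are
what the sigmoid read-out and cross-entropy loss expect.

Dual sources are superpositions: a seeded random draw of distinct pairs of
singles without replacement, with overlapping node sets rejected and
redrawn (cap 100 attempts per sample) so labels stay binary and sources
countable. The dual flux is the sum of the constituents' raw fluxes —
equal, by linearity, to solving the summed source, which the tests verify
to 1e-8. No minimum separation is imposed; the barycenter gap is recorded
per sample and used for stratified evaluation. The default scaled dataset
is all 437 singles plus 1,500 duals.

Each flux vector is normalized to unit maximum before training. The
physical calibration of simulated flux is arbitrary, and per-sample
normalization makes the pipeline invariant to absolute source power; the
cost is that absolute brightness (an independent depth cue) is discarded,
and the network must infer depth from the spatial width of the surface
spot alone. Optional additive Gaussian measurement noise (relative to each
sample's maximum) is available and off by default.

Splits are seeded, sample-level, and stratified by sample type
(80/10/10 train/validation/test by default), so the test set contains both
singles and duals and every test single's center node is unseen as a
training single. Constituents of training duals are drawn from the full
single pool, so a test single may appear inside some training dual; the
single-source generalization claim is about unseen *single-source*
measurements, which is how the random-pairing scheme behaves at full scale
too.

## Network and training

The inverse operator is an end-to-end map from the length-N flux vector to
a length-M per-node score in (0,1): three strided 1-D convolutions, each
followed by ReLU, no pooling (strides do the downsampling; pooling would
discard the spatial arrangement the network must preserve), then a flatten
and one fully connected layer read out through a sigmoid. Convolution
kernels and strides are derived from N: strides of roughly the cube root
of the remaining length per layer, kernels about twice the stride, so
three layers compress the sequence to a single position. The final channel
count is set to about `budget / M` so that the fully connected layer
dominates a ~1e5 parameter budget at full scale (at N = 1,250, M = 5,831
the default spec counts 122,063 parameters; the fully connected baseline
at the same dimensions counts 2,270,407, about 19x more). Channel widths
(16/32) were fixed by validation loss on the default phantom — a wider
32/64 stack was tried and gave worse validation cross-entropy.

Training minimizes binary cross-entropy between the sigmoid outputs and
the binary labels with Adam (learning rate 0.001, β₁ = 0.9, β₂ = 0.999,
ε = 1e-8), 200 epochs, batch size 32. A squared-error objective on the
sigmoid outputs is available as a config option (`loss = "l2"`); it
corresponds to reading the optimization target as a least-squares fit,
but cross-entropy is the default as the natural match to sigmoid outputs
and binary labels. The reported model is the epoch with minimum validation
loss; there is no learning-rate schedule, weight decay, or early stopping.
All randomness (initialization, shuffling, pairing, splitting) derives
from one user seed through labeled stage streams, and repeat runs are
bitwise identical on one machine.

The layers, losses, backpropagation and Adam are implemented directly on
dense linear algebra inside the package (im2col + GEMM convolutions); the
gradients are verified against central finite differences in the test
suite at 1e-4 relative tolerance.

## Evaluation

* **Location error (LE)** — Euclidean distance between the
  intensity-weighted barycenter of the reconstruction,
  $SC = \sum_i P_i x_i / \sum_i x_i$, and the unit-weighted barycenter of
  the true node set. Scale-free in the intensities.
* **Dice** — $2|S_1 \cap S_2| / (|S_1| + |S_2|)$ on node sets.

Turning a continuous prediction into node sets is under-determined, so the
rule is explicit and configurable: retain nodes at or above 0.5 of the
prediction's maximum, split them into connected components of the mesh
node-adjacency graph, and drop components below 2 nodes as artifacts. For
dual samples the two largest components (by retained intensity) are
assigned to the true sources by the better of the two pairings of
barycenter distances; LE1/LE2 follow the true-source indexing and total
LE = LE1 + LE2. Dice for duals compares unions. A sample whose prediction
yields no usable component for a true source keeps Dice as computed (0 if
nothing was retained), its missing LE is excluded from LE means, and the
failure is tallied separately in the report.

Aggregates are mean ± sd, overall and stratified by source depth
(default bins 0–2/2–4/4–6/6–8 mm) for singles and by barycenter gap
(width-4 bins from 2 mm) for duals; both binnings are overridable.

## Problem sizes and runtime

The canonical scaled run (`blt_benchmark()`, also driven by
`scripts/acceptance.R`) uses the default phantom (2,849 nodes), 437
singles + 1,500 duals, and the default 200-epoch protocol; it completes in
a few minutes on one CPU core, with training dominating. The tiny phantom
used throughout the tests (radii 3/3.5/4 mm, ~330 nodes) keeps per-test
solves and training runs in the seconds range. These sizes are the
package's chosen study conditions; the full-scale anatomical problem is
larger (5,831 output nodes), and the parameter-budget checks instantiate
the architecture at that output dimension.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the original study — layered
optics, node-star sources spanning a range of depths and separations,
superposed duals, scale-free normalized measurements — on a geometry that
is deliberately idealized: concentric spheres, a uniform lattice mesh,
noiseless simulated measurements, and a forward model (diffusion
approximation) that is also the data generator. Passing the scaled
benchmark shows that the learned operator inverts this forward model
accurately on held-out sources; it does not show robustness to model
mismatch (training on one transport model, measuring with another),
anatomical irregularity, camera calibration, or measurement noise — the
noise hook exists precisely so that sensitivity can be probed. Dice values
here also benefit from the near-uniform source volumes of the lattice
phantom.

## Known limitations

* Diffusion approximation only; low-scattering regions (e.g. cerebrospinal
  fluid) and sources within ~2 mean free paths of the surface are outside
  its validity.
* Single wavelength, steady state, no free-space camera model.
* Dual-source evaluation assumes exactly two true sources; more general
  n-source composition is straightforward for data generation (the
  superposition is general) but scoring is implemented for n ≤ 2.
* The 0.5·max segmentation threshold is a convention; Dice is sensitive
  to it, which is why it is exposed as a parameter rather than fixed.
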