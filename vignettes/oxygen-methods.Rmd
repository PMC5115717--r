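---
title: "Stochastic tumour vasculature and the computation of tissue oxygen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic tumour vasculature and the computation of tissue oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascox)
```

## The model

`vascox` builds a schematic but macroscopically sized tumour vasculature and
computes the steady-state oxygen partial pressure (pO~2~) field it supports.
The pipeline has four stages.

**1. Stochastic vessel trees.** Vessels bifurcate: at every branch point two
daughter segments leave in directions drawn from tabulated cumulative
distributions of the polar deflection angle (one table per branch), with the
azimuth uniform on $[0, 2\pi)$. Polar angles are drawn by inverse-transform
sampling of the piecewise-linear CDF; local angles are rotated into the
global frame with direction cosines. Macrovessel trees use nine generations
(so $2^9 = 512$ end branches of roughly 100 µm diameter); each end branch
seeds a five-generation microvessel tree whose segment lengths fall from
about 400 µm to 50 µm on average. Segments shorter than 40 µm are discarded:
at the working resolution they would largely overlap their parent vessel and
contribute nothing to the oxygen field.

The published branching statistics and the segment-dimension regressions are
available only graphically, so the package ships documented defaults:
piecewise-linear angle CDFs favouring small deflections for branch 1 and
larger ones for branch 2 (`default_angle_cdfs()`, replaceable by any
two-column CSV), geometric length schedules matching the printed endpoints
(10 mm → 0.4 mm for macrotrees, 400 µm → 50 µm for microtrees, ±20 % uniform
jitter), a macrotree starting radius of 140 µm with a uniform 5–15 µm radius
decrement per generation, and a geometric microtree radius schedule from
50 µm (the macrotree end-branch radius) to 5 µm (capillary scale). The
decrement rule alone cannot be continued through five microvessel
generations — a mean 10 µm decrement from a 50 µm start reaches zero — which
is why microtrees use an explicit radius schedule instead.

**2. Rasterization.** Each microtree is drawn into a 10 µm isotropic voxel
grid: branch points are connected with a 3D generalisation of Bresenham's
line algorithm (driving axis = largest axis difference, ties x > y > z; the
path is 26-connected with no gaps), and the one-voxel centreline is dilated
by a spherical kernel of the segment radius (voxel centres within the
radius, boundary included). For a binary centreline this dilation is exactly
"convolve with a ball and threshold at any positive level". Every vessel
voxel records the arc length to the tree root along the centreline that
deposited it; collisions keep the minimum, the physically sensible choice
for the oxygen level assigned next.

**3. Oxygen transport.** Vessel voxels are Dirichlet sources: 100 mmHg
(arterial) at the tree root, falling linearly with centreline distance to
40 mmHg (venous) at the most distant vessel voxel of that tree. The tissue
field is evolved by iterating

* one diffusion step — convolution with the Green's function of the
  diffusion equation, a Gaussian with per-axis standard deviation
  $\sigma = \sqrt{2 D_O t}$ (20 µm at the defaults $D_O = 2000$ µm²/s,
  $t = 0.1$ s), sampled at voxel centres, truncated at $4\sigma$ and
  renormalised to sum to 1, applied separably with zero padding, after
  which vessel voxels are re-clamped to their source values; and
* one consumption step — Michaelis–Menten kinetics
  $C = C_0 \, p/(p + K_M)$ with $C_0 = 15$ mmHg/s and $K_M = 1$ mmHg,
  applied explicitly as $p \leftarrow \max(0,\, p - tC(p))$ on tissue
  voxels only.

The tabulated normalisation constant $k = 1000\,(4 D_O t \pi)^{-3/2}$ is
recorded in `phys_params()` but is inert: the 1000 is the 10 µm voxel volume
in µm³, i.e. the factor that makes the sampled continuous Gaussian sum to
about one, and the implementation renormalises the discrete kernel exactly
instead. The clamp at zero absorbs the overshoot of the explicit update near
anoxia, where $tC_0 = 1.5$ mmHg can exceed the remaining oxygen; a
consequence worth knowing is that the hypoxic interior relaxes to exact
zeros (diffusive inflow below ≈0.2 mmHg is consumed entirely within a step),
so anoxic regions have genuinely compact support rather than exponential
tails. Iteration order within a step is diffuse → clamp vessels → consume.

Convergence is declared when the total tissue pO~2~ changes by less than a
relative `tolerance` (default 1e-4) for three consecutive iterations. This
criterion is the package's own choice: total tissue oxygen is the natural
scalar summarising the field volume, and the three-in-a-row rule
guards against an accidentally small single step. At the defaults, a single
microtree field converges in 60–110 iterations, and tightening the tolerance
from 1e-4 to 1e-6 changes the hypoxic fractions by less than 1e-4, so the
default is adequate.

**4. Tumour assembly.** Macrotrees are seeded at uniform random positions in
a configurable ball with isotropic random root directions (isotropy is the
minimal assumption where no anatomical prior exists), their
leaves pooled, leaves falling in the same 100 µm occupancy cell removed
(the coarse grid used by the individual tree method is the natural
collision structure), and each surviving leaf is assigned one
of a library of precomputed microtree archetypes uniformly at random. The
tumour perimeter is the convex hull of the leaves (triangulated in-package;
no 3D hull dependency is used) and the functional microvessel density is
`n_leaves × mean archetype vessel volume / hull volume`.

## The two computation methods

**CTM (combined tree method).** All trees reaching a sample box (3×3×3 mm³
in the full-scale study) are rasterized into one 10 µm grid — colliding
vessel voxels take the maximum source value, mirroring the ITM combination
rule — and solved jointly. The box is padded (default 150 µm = 15 voxels per
side, consistent with 330³ vessel volumes against 300³ oxygen volumes in the
deposited data) and the pad is cropped after solving. Inter-tree interaction
is fully represented.

**ITM (individual tree method).** Each archetype's field is solved once in
its own zero-padded box, block-mean down-sampled to the 100 µm grid, and
translated to every leaf position (nearest-voxel placement); where several
fields reach a voxel, the highest value wins. Block-mean is the only
down-sampling that preserves the field average, and the comparison between a
field and its own down-sampled version confirms the information loss from
down-sampling alone is small. Voxels reached by no field stay at zero.

Because each tree is solved in isolation and then averaged onto a coarse
grid, the ITM misses inter-tree interaction and smears sub-100 µm hypoxic
pockets into oxygenated coarse voxels. The package reproduces the direction
of the resulting bias on a synthetic 1 mm³ sample of four adjacent small
trees: the jointly solved field has the higher hypoxic fraction at 1 mmHg,
i.e. the ITM underestimates hypoxia.

## Evaluation statistics

`po2_distribution()` summarises a field as a 1 mmHg-resolution normalised
histogram with its cumulative curve, hypoxic fractions HF~0.01~, HF~1~,
HF~5~ (strict `<`, over all voxels of the cropped sample), vascular
fraction, mean and population SD. `rmsd()` is the root mean square
deviation between two *cumulative* normalised distributions: this is the
reading under which 0 means identical and ≈1 means total lack of agreement
(two delta distributions at opposite ends of a 101-bin range give
$\sqrt{100/101} \approx 0.995$); a density-histogram variant is available
via `on = "density"`. `ks_two_sample()` computes the exact merged-ECDF
sup-distance and applies the large-sample criterion
$D > c(\alpha)\sqrt{(n_1+n_2)/(n_1 n_2)}$ with
$c(\alpha) = \sqrt{-\ln(\alpha/2)/2}$ (1.36 at α = 0.05, 1.95 at α = 0.001).
`correlation_matrix()` gives pairwise Pearson r with two-sided t-based
p-values over per-sample property tables.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the study — bifurcating trees
with tabulated branching angles, per-generation dimension schedules, the
linear intravascular oxygen ramp, the physical constants — but not any
specific realisation: the deposited tumour (127 cm³, 130 955 microtrees) is
one random draw under dimension data that are not printed. Hull volume,
leaf counts and density are therefore checked as order-of-magnitude and
bookkeeping identities, not as reproductions. Real tumour vasculature is
additionally tortuous, collision-avoiding, flow-coupled and permeability
heterogeneous; none of that is modelled here, so passing tests demonstrate
correctness of the computational method, not physiological fidelity of any
one field.

## Problem sizes and numerical choices

The packaged studies run at desk scale: 1 mm³ samples (100³ fine voxels,
10³ coarse) with four 3-generation microtrees, archetype libraries of a few
trees, and tumours of ~10 macrotrees — about 1/1000 of the full study's
linear density — exercising exactly the code paths of the full-scale
configuration. Key numerical choices, all config-exposed: kernel truncation
4σ (beyond-truncation mass ≈ 6×10⁻⁵ per axis); solver tolerance 1e-4 with
the 3-in-a-row rule; Bresenham tie-break x > y > z (the a↔b reversal may
differ by sub-voxel choices, accepted); dilation includes boundary voxels
whose centre lies exactly on the sphere; block down-sampling crops trailing
remainders on non-divisible shapes; voxel indices are 0-based externally
(raw-volume sidecars) and 1-based inside R arrays, with a point mapping to
the voxel whose centre is nearest.

## Known limitations

* No haemodynamics: vessel oxygen is a fixed linear ramp, not a flow
  solution, and vessels never deplete (Dirichlet clamping).
* The explicit consumption update is non-monotone below ≈0.22 mmHg; the
  zero clamp makes the scheme stable but means the hypoxic front position
  carries O(voxel) discretisation error.
* Whole-tumour solves at 10 µm are out of scope by design; the CTM applies
  to sub-volumes only.
* The convex hull is the tumour perimeter; concave (alpha-shape) perimeters
  are not implemented.
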