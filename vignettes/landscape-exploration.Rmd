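---
title: "Exploring protein energy landscapes from collective-motion variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring protein energy landscapes from collective-motion variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modescape)
```

## The problem

Proteins interconvert between structurally distinct functional states.
The energy landscape — the mapping from conformations to energies —
organises those states into basins separated by barriers, but neither
wet-laboratory structure determination nor brute-force simulation can
chart it for a protein of realistic size.  A productive compromise is
*sample-based* reconstruction: explore a low-dimensional space of
carefully chosen collective variables, one conformation at a time,
under a stochastic-optimization loop, and read the landscape off the
accumulated samples and their energies.

Everything then hinges on the variables.  `modescape` supports two
interchangeable choices:

* **Extrinsic modes (PCA).**  When many structures of a protein (and
  near-identical variants) are available, the principal components of
  their superposed CA coordinates capture the dominant *observed*
  structural variation.  The eigenvalue $e_i$ of PC$_i$ is the
  ensemble variance along that axis.
* **Intrinsic modes (NMA).**  When only a single structure is
  available, the normal modes of an elastic network built from that
  one structure predict its *intrinsic* flexibility.  Low-frequency
  modes describe slow, collective motions — the ones that carry a
  protein between states.

The central scientific question the package lets you probe on synthetic
data is how much of the landscape you can recover with intrinsic modes
from a *single* structure compared to extrinsic modes from a full
ensemble.

## The model

### PCA basis

$n$ CA traces of length $k$ are iteratively superposed onto their
running mean (plain centring would leave relative rotations in the
data; we iterate until the mean moves by less than $10^{-6}$ Å, at most
20 rounds), stacked into a $3k \times n$ matrix $A$, and centred.  The
thin SVD

$$\tfrac{1}{\sqrt{n-1}}A = U \Sigma V^{\mathsf T}$$

gives the principal components as columns of $U$ and eigenvalues
$e_i = \Sigma_{ii}^2$, sorted high to low; $V$ is discarded.  The
number of retained axes $m$ is the smallest prefix of PCs whose
cumulative eigenvalue fraction reaches a threshold (default 0.8).

### NMA basis

A single CA trace defines an anisotropic elastic network: every CA
pair within a cutoff (default 15 Å) is joined by a Hookean spring of
uniform constant $\gamma = 1$.  The $3k \times 3k$ Hessian has 3×3
blocks $-\gamma\,\hat r \hat r^{\mathsf T}$ off the diagonal and
compensating diagonal blocks, so it annihilates the six rigid-body
displacements by construction.  After diagonalisation exactly six
near-zero eigenvalues are discarded (fewer or more signals a
degenerate or disconnected network and is an error); the remaining
$d = 3k - 6$ modes are renumbered in order of frequency
$f_i = \sqrt{\lambda_i}$, low to high.  Masses are uniform and no
force field beyond the single spring constant is assumed; the cutoff
and $\gamma$ are configurable.  There is no non-parametric rule for
$m$ when only one structure exists; the package exposes $m$ as a
parameter with default 10, and the reconstruction-loss curve
(`loss_curve()`) quantifies the trade-off whenever an ensemble is
available to test against.

Axis signs are arbitrary in both decompositions; each axis is flipped
so that its largest-magnitude component is positive, which makes
serialisation, comparisons and tests deterministic.  Ties between
degenerate eigenvalues keep their original order; tests assert on
subspaces, not individual degenerate vectors.

### Projection, reconstruction and the loss curve

A structure is projected by superposing it onto the basis origin (the
ensemble mean for PCA, the source structure for NMA) and taking dot
products of the displacement with the first $m$ axes; reconstruction
is the linear combination added back to the origin.  With all $d$
axes the round trip is exact; truncation to $m < d$ loses the
orthogonal residual, and `loss_curve()` reports the mean and median
lRMSD of that loss per mode count over an ensemble.

Because the axes are *linear* displacement directions, a large rigid
rotation of a subdomain — exactly what a hinge motion is — is only
approximated by any truncated linear basis.  On the package's default
two-state fixture the ten slowest one-structure modes leave a
truncation floor of about 1 Å lRMSD against the opposite state.  This
is a property of linearised collective variables, not of the
implementation, and it bounds how sharply any $m=10$ exploration can
resolve the far basin (see *Limitations*).

### The exploration loop

Starting from the projections of the seed structures, each iteration:

1. **selects** a member with probability
   $w(C) \propto (1 + n_{\text{cell}}(C))^{-\alpha}\,
   e^{-(E(C)-E_{\min})/T}$, computed over a 2D grid (default
   100×100 cells) spanned by the first two variable axes — crowded
   cells and high-energy members are both penalised;
2. **varies** it by a global motion vector $g$ with independent fair
   signs per axis: $|g_i| = \delta_1 e_i / e_1$ for PCA (steps
   proportional to captured variance) and
   $|g_i| = \delta\sqrt{2/m}/f_i$ for NMA.  The NMA scaling makes a
   full displacement along any single scaled axis cost the same
   network energy $\delta^2/m$, so no mode is favoured
   energetically;
3. **transforms** the displaced conformation to a CA trace,
   regularizes its chain geometry, re-projects the regularized trace,
   evaluates its energy, and appends it.  Parents are never removed;
   a failed (divergent) regularization discards the candidate and
   logs it.

Defaults follow the production settings of the two bases:
$\delta_1 \in \{1,2,3\}$ for PCA and $\delta \in \{0.25,0.5,0.75\}$
for NMA, with the middle value as the single-run default.  Grid
bounds default to the seed population's bounding box expanded
threefold symmetrically, with a minimum half-width of 5 per axis so a
single-structure seed (a zero-width box) still yields a usable grid;
samples outside the bounds clamp to edge cells.  The temperature $T$
defaults to the interquartile range of the current population's
energies, recomputed each step and floored at $10^{-6}$; the crowding
exponent is $\alpha = 1$.  The weighting function itself is a design
choice of this package: the two penalties are stated requirements,
and the product of a power-law crowding term with a Boltzmann-like
energy term is the simplest form with one interpretable knob each.

### The surrogate energy

Transforming samples to all-atom structures and minimising them under
a molecular-mechanics force field is out of scope here; the package
scores CA traces directly with a coarse-grained surrogate:

$$E = k_b \sum_i (d_{i,i+1} - 3.8)^2 +
      k_c \!\!\sum_{\substack{|i-j|\ge 2 \\ d_{ij} < r_c}}\!\! (r_c - d_{ij})^2
      \;+\; k_n \!\!\sum_{\substack{i<j \\ d^{\text{ref}}_{ij} < r_n}}\!\!
      (d_{ij} - d^{\text{ref}}_{ij})^2,$$

with defaults $k_b = k_c = 1$, bond target 3.8 Å (canonical
consecutive-CA spacing), clash radius $r_c = 4$ Å, and the
reference-network restraint off ($k_n = 0$, $r_n = 10$ Å when used).
Scores are unitless and rank conformations by geometric strain; they
are not kcal/mol and imply no force-field equivalence.
`regularize_trace()` minimises this energy by steepest descent
(default 200 iterations, step 0.01, gradient tolerance $10^{-4}$,
step halving up to 10 times before declaring divergence).  Users who
do have an all-atom pipeline can plug it in as an external minimiser
command on the energy model; the package never requires one.

## The synthetic fixture

`make_hinge_ensemble()` generates the test system: a regular helix
(defaults rise 1.5 Å, turn 100°, radius 2.3 Å, giving a consecutive-CA
spacing of ≈3.83 Å) whose C-terminal arm rotates about a hinge
residue.  Hinge angles are drawn either uniformly in ±`angle_range`
or, with `bimodal = TRUE`, from a two-component Gaussian mixture at
±`angle_range` — the two-state case that emulates a protein with two
functional basins.  The mixture component sd is 3°, small enough that
the two states stay well separated at the default ±30° yet wide
enough to give each basin internal variance; isotropic Gaussian noise
(default 0.1 Å per coordinate) stands in for experimental and thermal
scatter.  The standard study system in the tests and the acceptance
script is $k = 30$, hinge at residue 15, ±30°, $n = 100$.

What the fixture emulates: a dominant, collective, two-state motion
plus small-amplitude noise — the situation in which PCA/NMA
correspondence and landscape reconstruction are meaningful.  What it
does not emulate: side-chain packing, sequence heterogeneity,
anharmonic local substates, real force-field ruggedness, or
experimental artefacts of deposited structures.  Passing tests on the
fixture therefore validate the machinery (geometry, spectra,
operators, loop contracts) and the qualitative PCA/NMA story, not
force-field-level accuracy on real proteins.

## Numerical choices

* Rigid-equivalence and reconstruction tolerances are $10^{-6}$ Å;
  orthonormality checks use $10^{-8}$.
* Zero-frequency (rigid-body) modes are classified by
  $\lambda < 10^{-8}\lambda_{\max}$ — scale-free in double precision.
* Superposition uses the SVD form of the Kabsch solution with
  determinant correction, so reflections are never returned.
* Bases persist as delimited text with 17 significant digits, which
  round-trips IEEE doubles exactly; the PDB copy of the origin trace
  is for interchange and carries the format's 0.001 Å resolution.
* Problem sizes in the tests are chosen to keep the full suite fast:
  $k$ between 10 and 30, ensembles of 20–100, exploration runs of
  20–2000 iterations; the acceptance script's two-state run uses the
  full study system (55 seed structures, 2000 iterations).

## Limitations

* Linear mode bases approximate large rotations poorly: on the
  default fixture the $m = 10$ one-structure basis cannot get closer
  than ≈1 Å lRMSD to the opposite state, so the reconstructed far
  basin is displaced and blurred relative to the true one.  More
  modes, or a basis extracted from a less open structure, reduce the
  floor.
* The grid-archive selection expands coverage diffusively; within a
  few thousand iterations a sampler seeded in one basin approaches
  but does not densely populate a basin several Å away.  Production
  landscape studies of this kind run tens of thousands of samples per
  setting.
* The surrogate energy has no attractive terms, so basins are
  encoded only through the seed structures and the geometry of the
  variable space, not through energetic minima; with the optional
  reference-network term the landscape acquires a single artificial
  minimum at the reference.
* Only CA traces are modelled; no mmCIF input, no all-atom or
  torsional normal modes, no mass weighting.

## A worked example

```{r example, eval = FALSE}
ens  <- make_hinge_ensemble(k = 30, hinge_index = 15, angle_range = 30,
                            n = 100, noise_sd = 0.1, seed = 7,
                            bimodal = TRUE)
nma  <- extract_nma(make_hinge_trace(30, 15, -30), m = 10)
pca  <- extract_pca(superpose_ensemble(ens))

# how well do one-structure modes cover the ensemble's main motion?
compare_bases(nma, pca, top = 10)[, 1]

# how many modes does reconstruction need?
head(loss_curve(ens, nma))

# explore from one basin and tabulate the landscape
angles <- vapply(ens$traces, attr, numeric(1), which = "hinge_angle")
pop <- explore_run(ca_ensemble(ens$traces[angles < 0]), nma,
                   iterations = 2000, seed = 1)
head(landscape_table(pop))
```
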