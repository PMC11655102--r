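---
title: "Voxel-wise brain graphs: models, phantom design, and numerical choices"
author: "voxelgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise brain graphs: models, phantom design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxelgraph)
```

## Overview

`voxelgraph` builds weighted graphs whose nodes are the individual voxels
inside a brain mask and whose edges connect Moore-lattice neighbours,
weighted by local diffusion coherence. It then analyses these graphs
spectrally (normalized Laplacian eigenmodes), treats volumetric signals
as graph signals (graph Fourier transform, ensemble energy spectral
density, null models), and aligns eigenmodes across subjects with a
Procrustes scheme. Because real diffusion MRI inputs require an external
preprocessing chain (tensor fitting, ODF estimation, registration) that
is out of this package's scope, a synthetic phantom generator provides
all inputs with the statistical structure the downstream analyses assume.

## Neighborhood schemes

Two lattice neighborhoods are supported.

* **3-connectivity**: the 26 nonzero offsets of the 3×3×3 Moore cube.
* **5-connectivity**: those 26 plus the 5×5×5 outer shell *minus* the 26
  outer offsets that are positive integer multiples (exactly `2*o`) of an
  inner offset `o`. Parallel offsets duplicate directions already
  encoded, so removing them leaves 26 + 72 = 98 distinct directions. The
  larger neighborhood trades spatial localization for angular resolution.

Each direction is assigned an equal share of the sphere, `4*pi/26` or
`4*pi/98` steradians. Unit directions are computed in *physical*
coordinates (`offset * voxel_size`, then normalized), so anisotropic
voxels skew the direction set correctly, while lattice adjacency itself
is independent of voxel size.

## Diffusion profiles

The per-voxel, per-direction diffusion estimates `p(i, r_ij)` come from
one of two models.

**Tensor model.** `p` is the 3D Gaussian density with the voxel's tensor
as covariance, evaluated at the physical displacement:
`p = (2*pi)^(-3/2) |T|^(-1/2) exp(-r' T^{-1} r / 2)`. We evaluate the
continuous density directly at the 26 (or 98) displacement vectors,
keeping their true lengths — outer-shell neighbours enter at up to twice
the inner-shell distance, so they are attenuated accordingly. A
discretization that integrates the Gaussian over each neighbour's cell
(an FIR-filter view of the 3×3×3 stencil) would be an alternative; since
the edge-weight normalization `beta_k` cancels any per-voxel scale, the
choice affects only the relative weighting across directions, and the
direct evaluation keeps the implementation transparent and exactly
testable against closed forms.

**ODF model.** Given `N_o` samples of the orientation distribution
function on a shared direction table, `p` along a neighbour direction is
the mean of the sharpened amplitudes `O_k^n` over the samples falling in
that direction's spherical cap. The cap half-angle inverts the cap-area
relation `2*pi*(1 - cos(theta)) = Omega` exactly; caps are allowed to
overlap (the solid angle defines a neighbourhood of each direction, not a
partition of the sphere). Normalizing by cap cardinality compensates for
unequal sample counts per cap. The sharpening exponent defaults to
`n = 2` — ODFs are blunt functions of orientation, and a modest power
accentuates peaks without destroying the two-level closed forms used in
the tests; it is configurable wherever it appears.

## Edge weights

For lattice-adjacent in-mask voxels,

`a_ij = [P(v_i) P(v_j) / alpha^2] * [p(i, r_ij)/beta_i + p(j, r_ji)/beta_j]`

with `P` the anisotropy map (FA or QA), `alpha` its in-mask maximum, and
`beta_k` twice the maximum of voxel k's profile over its available
neighbours. The magnitude factor suppresses edges into weakly anisotropic
tissue (e.g. CSF); the orientation factor rewards mutually coherent
diffusion. Both factors are bounded to [0, 1] by construction, hence so
is every weight, and the expression is symmetric in (i, j) so the
adjacency is exactly symmetric — it is assembled once per antipodal
direction pair, never symmetrized numerically.

Edges to voxels outside the mask simply do not exist. Voxels whose
profile is all zero (`beta = 0`) or whose incident weights all vanish are
dropped, then the largest connected component is kept; both counts are
logged and stored on the graph object. Dropping first and extracting the
component second is a fixed, documented order.

## Spectral analysis

The normalized Laplacian `L = I − D^{−1/2} A D^{−1/2}` has spectrum in
[0, 2] with `lambda_1 = 0` and `u_1` proportional to `D^{1/2} 1` for a
connected graph. The leading `C` eigenpairs are computed by shift-invert
Lanczos: a sparse Cholesky factor of `L + 0.1 I` drives an ARPACK
iteration on the inverse operator, whose largest eigenvalues map back to
the smallest of `L`. The lower end of the spectrum is dense near zero for
large graphs, which makes plain smallest-magnitude iteration converge
poorly; shift-invert is the standard remedy. Problems with at most 400
nodes use dense diagonalization instead. Each returned pair must satisfy
`||L u − lambda u|| <= 1e-8` or the solver errors out with the achieved
residuals.

Eigenvector sign is fixed by making the largest-absolute entry positive
(ties broken by lowest node index): signs are arbitrary for any
eigensolver, and a deterministic convention makes runs reproducible.
Within numerically degenerate eigenspaces (`|lambda_i - lambda_j|`
below ~1e-10) only the spanned subspace is well defined; tests compare
spectral projectors there, not individual vectors.

Total variation `TV(x) = x' L x` equals `lambda_i` for unit eigenvectors
and grounds the frequency interpretation. The weighted zero-crossing
count sums `a_ij` over edges whose endpoint values have strictly opposite
signs; an exactly-zero endpoint contributes nothing (a measure-zero event
in floating point, resolved conservatively).

## Graph signal processing

A volumetric frame becomes a graph signal by reading its values at the
graph's voxels in node (scan) order. Each frame is demeaned by regressing
out `u_1` and normalized to unit energy; its squared GFT coefficients are
then per-mode energies, and averaging over frames gives the ensemble
energy spectral density (EESD). The first index is analytically zero
after demeaning and is stored as exact zero. Frames parallel to `u_1`
(zero residual) are flagged and excluded with a message.

The ensemble average is taken over *squared* coefficients: energies are squared magnitudes by definition,
an unsquared sum could be negative, and the demeaning guarantee
(`|x~[1]|^2 = 0`, energies summing to 1) only makes sense for squares.

Two null models accompany the EESD: spatial shuffling (per-frame
permutation of node values, preserving each frame's value distribution
while destroying spatial order) and white Gaussian frames. For Gaussian
frames the demeaned energy shares are exchangeable across the remaining
`N − 1` basis directions, so each index carries `1/(N−1)` in expectation
— the refinement of the `1/N` chance level that accounts for the
regressed-out first mode.

## Synthetic phantom

The generator emulates the inputs the analyses assume.

* **Tissue volume**: an ellipsoidal mask with relative semi-axes
  1 : 0.84 : 0.72 (the approximate proportions of a human head), holding
  a ~1-voxel CSF rim, a GM interior, and a cylindrical WM bundle along a
  chosen axis. The distinct semi-axes are deliberate: *the phantom must
  not have exact spatial symmetries*. A symmetric mask (e.g. a cube with
  a centered axial bundle) forces degenerate Laplacian eigenvalues whose
  eigenspaces rotate freely between subjects, making individual-mode
  comparisons ill-posed for reasons that have nothing to do with the
  data — real anatomy has no such symmetry.
* **Anisotropy**: 0.8 in the bundle (typical of coherent white matter),
  0.15 in GM, 0.05 in CSF, with jitter of sd 0.02; zero outside the
  mask. WM therefore always dominates GM and CSF in mean anisotropy.
* **Tensor field**: prolate tensors along the (slightly jittered) bundle
  direction with a configurable axial/radial eigenvalue ratio (default
  5, FA ≈ 0.8) in WM; near-isotropic tensors elsewhere; unit mean
  diffusivity throughout (the weight normalization cancels scale). All
  tensors are SPD by construction (eigendecomposition synthesis).
* **ODF field**: Watson-type profiles `exp(kappa((d·mu)^2 − 1))` in WM
  (antipodally symmetric by construction), exactly constant ODFs
  elsewhere, sampled on a Fibonacci full-sphere table closed under
  negation (default 642 directions, ~6.5 samples per 98-scheme cap).
* **Graph signals**: random eigenmode combinations with coefficient
  variance `i^(-gamma)` for indices `i >= 2` (default `gamma = 2`,
  echoing the power-law energy decay seen in functional data), plus
  white node-space noise.
* **Cohorts**: one base phantom; per subject, a smooth random anisotropy
  perturbation and a small random rotation of the bundle direction, both
  of scale `perturbation_sd`. Zero perturbation yields bit-identical
  subjects. All subjects share one grid, so spatial alignment is the
  identity and the matching analyses are isolated from registration
  error. The generator makes no claim about the statistics of real
  inter-subject variability; it provides a controllable ordering (more
  perturbation, more variability).

What passing tests on these phantoms do *not* show: behaviour under
registration error, crossing fibers, scanner noise, or at
hundreds-of-thousands-of-nodes scale. The phantoms validate the
machinery — weight formulas, spectral contracts, energy accounting,
matching — not clinical performance.

## Eigenmode matching

Across subjects, eigenmodes suffer sign flips, order swaps, and mixing
between modes with close eigenvalues. Matching reorders each subject's
first `K` modes against a running group average: the exact linear
assignment (Hungarian algorithm) on the absolute cosine-similarity
matrix, signs set to make matched cosines non-negative. The group loop
initializes the average at subject 1, reorders every subject, re-averages
element-wise (no re-orthonormalization — cosine matching is
norm-invariant), and by default iterates until no permutation or sign
changes (capped at 20 passes) so the average is not biased toward its
initialization. Translation is omitted from the alignment: eigenvectors
of a connected graph's normalized Laplacian beyond the first are
orthogonal to `D^{1/2}1`, so their means are near zero and a translation
term would be numerically negligible.

The Procrustes error `E(K)` — half the Frobenius norm of the off-diagonal
cosine matrix — is zero for perfectly matched orthonormal sets, grows
with `K` (it sums non-negative terms over a growing index set), and is
symmetric. A signed permutation can correct swaps and flips but *not*
continuous mixing inside near-degenerate clusters; that residual is
exactly what `E` is designed to measure. Bootstrap validation repeats
pairwise matching over random subject pairs for a grid of `K` and
reports the mean and standard deviation per `K`.

**What "small perturbation" means.** Comparing a cohort against the
random-orthonormal null (`mu_K(cohort) < mu_K(null)` at every `K`)
presupposes that matching is well-posed, i.e. that the perturbation-
induced coupling between modes is small relative to the eigenvalue gaps
in the studied band. At the cohort scale used here (14³ volume, ~570
nodes, `K <= 20`, gaps down to ~2e-3), that perturbative regime holds at
`perturbation_sd = 0.002`, which the cohort-vs-null checks use; by
0.02–0.05 near-degenerate clusters mix strongly and the matched error
rises above the null level even though subjects remain visibly similar.
The monotonicity checks (matching reduces `E`; more perturbation, larger
`mu_K`) are run at 0.05, where they are most informative.

## Problem sizes and tolerances

The test and acceptance workloads use a 24³ tensor-model phantom
(~3.4k nodes, 50 modes) for spectral contracts, a 14³ five-subject ODF
cohort (~570 nodes, 20 modes) for matching, a ~200-node subgraph for
dense-vs-iterative eigensolver agreement (1e-8) and full-spectrum
Gaussian-null flatness (5 standard errors at 500 frames), and 2×2×2
hand-checkable toys for the weight formula (1e-12) and Parseval
(1e-10). Orthonormality and TV–eigenvalue agreement are asserted at
1e-6, eigen-residuals at 1e-8. These sizes were chosen so that every
contract is exercised on a genuinely multi-scale graph while the whole
suite remains quick to run.

## Known limitations

* Fidelity is to the tensor/ODF *models*; estimating tensors or
  ODFs from raw diffusion-weighted images is out of scope, as are
  registration and template normalization.
* The DTI profile evaluates the Gaussian pointwise rather than
  integrating it over neighbour cells (see above).
* Only single-bundle phantoms are generated; crossing-fiber geometries
  would exercise the ODF model's angular resolution more sharply.
* The matching scheme outputs strict signed permutations; subspace
  rotations within degenerate clusters are measured (via `E`), not
  corrected.
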