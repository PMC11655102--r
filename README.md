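# voxelgraph

Voxel-wise structural brain graphs from diffusion MRI, their Laplacian
spectra, and graph signal processing on top of them — with a synthetic
diffusion-phantom generator so every stage can be exercised and validated
without any scanner data.

## The scientific problem

Structural connectomes are usually region-wise: nodes are atlas parcels,
edges count streamlines between them. An alternative is to keep the full
spatial resolution of the data and model **every voxel inside the brain
mask as a graph node**, connecting each voxel to its Moore-lattice
neighbours — 26 directions for the 3×3×3 neighborhood, or 98 for a 5×5×5
neighborhood whose outer-shell offsets parallel to an inner offset are
removed (they duplicate directions already encoded). Edge weights express
*inter-voxel fiber coherence* estimated from diffusion MRI, so that the
graph encodes local tissue microstructure rather than long-range
tractography.

For adjacent voxels \(v_i, v_j\) with displacement \(r_{ij}\), the weight
is

    a_ij = [P(v_i) P(v_j) / alpha^2] * [ p(i, r_ij)/beta_i + p(j, r_ji)/beta_j ]

where

* `p(i, r_ij)` is the extent of diffusion at voxel `i` towards `j`,
  computed either from the **diffusion tensor** `T` as the 3D Gaussian
  density `(2*pi)^(-3/2) |T|^(-1/2) exp(-r' T^{-1} r / 2)`, or from the
  **orientation distribution function (ODF)** as the mean of sharpened
  sample amplitudes `O_k^n` over a spherical cap of solid angle `4*pi/26`
  (or `4*pi/98`) around the direction;
* `P(v)` is the voxel's anisotropy (FA for the tensor model, QA for the
  ODF model), `alpha` its maximum over the mask, and
  `beta_k = 2 max_l p(k, r_kl)`. These normalizations bound both factors —
  and hence every weight — to [0, 1].

On the resulting graph the package computes the **normalized Laplacian**
`L = I − D^{−1/2} A D^{−1/2}`, its leading eigenmodes (sparse
shift-invert Lanczos), total variation `x'Lx` and weighted zero-crossings;
projects node signals onto the eigenmode basis (graph Fourier transform)
and measures their **ensemble energy spectral density** against shuffled
and white-Gaussian nulls; and aligns eigenmodes across subjects with a
**Procrustes matching scheme** (exact signed-permutation assignment,
iterated group averaging) whose residual — half the Frobenius norm of the
off-diagonal cosine-similarity matrix — quantifies inter-subject
structural variability as a function of the subspace size K.

## Worked example

```r
library(voxelgraph)

sch <- build_scheme(3)                       # 26-direction neighborhood
ph  <- make_tissue_phantom(c(18, 18, 18), bundle_radius = 3, seed = 1)
fld <- make_tensor_field(ph, eigenvalue_ratio = 5, seed = 1)
g   <- assemble_graph(dti_profile(fld, sch))
g
#> Voxel-wise brain graph: 1320 nodes, 14452 edges, weights in [5e-05, 0.972]

L   <- normalized_laplacian(g)
dec <- eigendecompose(L, C = 20, graph = g, seed = 1)
round(head(dec$values, 5), 6)
#> [1] 0.000000 0.026870 0.070111 0.078182 0.097100

round(tapply(degrees(g), node_labels(g, ph), mean), 3)
#>     1     2     3
#> 0.615 5.458 0.089
```

The first eigenvalue is numerically zero with `u_1` proportional to
`D^{1/2} 1`, and all eigenvalues stay below 2, as the normalized Laplacian
guarantees. Mean node degree is an order of magnitude higher in the white
matter bundle (label 2) than in gray matter (1) or CSF (3): the anisotropy
magnitude term concentrates connectivity in coherent fiber tissue.

Smooth signals synthesized with a power-law graph spectrum concentrate
their energy in the low-frequency eigenmodes:

```r
sig <- make_graph_signals(dec, spectral_exponent = 2, num_frames = 100,
                          noise_sd = 0.01, seed = 1)
eesd(sig, dec)
#> Energy spectrum: 20 indices over 100 frames; cumulative at C = 0.7877
```

that is, ~79% of the (demeaned, unit-normalized) signal energy lives in
the first 20 modes; spatially shuffling the same frames collapses this to
roughly the chance level `C/N`.

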