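Package: voxelgraph
Title: Voxel-Wise Brain Graphs from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Construction and spectral analysis of voxel-wise structural brain
    graphs from diffusion MRI. Nodes are voxels inside a brain mask; edges
    connect lattice neighbours (26- or 98-direction Moore schemes) and are
    weighted by inter-voxel fiber coherence derived either from diffusion
    tensors or from orientation distribution functions, modulated by
    anisotropy. Includes the normalized graph Laplacian and its leading
    eigenmodes, graph-signal-processing tools (graph Fourier transform,
    ensemble energy spectral density, shuffled and Gaussian null models),
    Procrustes-based inter-subject eigenmode matching with bootstrap
    validation, and a synthetic diffusion-phantom generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
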