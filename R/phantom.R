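#' Synthetic tissue phantom with a coherent fiber bundle
#'
#' Generates a labeled 3D volume emulating a brain mask with three tissue
#' classes: an ellipsoidal mask holding gray matter (GM, label 1) in its
#' interior, a single cylindrical white-matter bundle (WM, label 2)
#' running through it along a lattice axis, and a roughly one-voxel
#' cerebrospinal-fluid rim (CSF, label 3) at the mask boundary. Voxels
#' outside the mask carry label 0. A per-voxel anisotropy map (playing the
#' role of fractional or quantitative anisotropy) is high inside the
#' bundle and low elsewhere.
#'
#' The mask is an ellipsoid with deliberately distinct semi-axes (relative
#' factors 1, 0.84, 0.72 of the available half-extent, the approximate proportions of a human head). Like a real brain,
#' the phantom has no exact spatial symmetry: a symmetric mask would force
#' (near-)degenerate Laplacian eigenvalues, under which individual
#' eigenmodes are not identifiable across subjects and eigenmode-matching
#' analyses become ill-posed for reasons unrelated to the data.
#'
#' Default tissue anisotropy levels are `bundle_level` for WM (default 0.8,
#' typical of a coherent fiber bundle), 0.15 for GM and 0.05 for CSF, each
#' with additive Gaussian jitter of sd 0.02, clipped to (0, 1].
#'
#' @param shape integer length-3, volume dimensions (each >= 8).
#' @param voxel_size length-3 numeric, mm.
#' @param bundle_axis `"x"`, `"y"` or `"z"` (or a 3-vector, projected to the
#'   nearest axis for the cylinder geometry).
#' @param bundle_radius cylinder radius in voxels; must fit inside the
#'   GM interior.
#' @param bundle_level anisotropy level inside the bundle, in (0, 1].
#' @param seed integer RNG seed; identical arguments and seed reproduce the
#'   phantom exactly.
#' @return An object of class `tissue_phantom`: list with `labels` (3D
#'   integer array), `anisotropy` (3D array in \[0,1\], zero outside the
#'   mask), `voxel_size`, `bundle` (axis unit vector, radius, level) and
#'   `seed`.
#' @examples
#' ph <- make_tissue_phantom(c(16, 16, 16), bundle_radius = 2, seed = 1)
#' table(ph$labels)
#' @export
make_tissue_phantom <- function(shape, voxel_size = c(1, 1, 1),
                                bundle_axis = "x", bundle_radius = 3,
                                bundle_level = 0.8, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3)
  if (any(shape < 8)) stop("each dimension of `shape` must be at least 8")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  direction <- axis_to_unit(bundle_axis)
  ax <- which.max(abs(direction))

  # ellipsoidal mask with distinct semi-axes; inner ellipsoid (GM) sits
  # ~1 voxel inside the CSF rim
  semi <- c(1, 0.84, 0.72) * (shape / 2 - 1)
  semi_in <- semi - 1.2
  perp <- setdiff(1:3, ax)
  max_radius <- min(semi_in[perp]) - 1  # GM must surround the bundle
  if (bundle_radius > max_radius) {
    stop(sprintf(
      "bundle of radius %g does not fit: max radius for shape (%s) is %g",
      bundle_radius, paste(shape, collapse = ","), max_radius
    ))
  }

  labels <- array(0L, shape)
  center <- (shape + 1) / 2
  idx <- list(seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]))
  ellipsoid <- function(semiaxes) {
    co <- lapply(1:3, function(k) ((idx[[k]] - center[k]) / semiaxes[k])^2)
    outer(outer(co[[1]], co[[2]], `+`), co[[3]], `+`) <= 1
  }
  labels[ellipsoid(semi)] <- 3L
  labels[ellipsoid(semi_in)] <- 1L

  # cylindrical bundle through the volume center along `ax`
  co <- lapply(1:3, function(k) idx[[k]] - center[k])
  r2 <- outer(
    outer(co[[1]]^2 * (ax != 1), co[[2]]^2 * (ax != 2), `+`),
    co[[3]]^2 * (ax != 3), `+`
  )
  labels[labels == 1L & r2 <= bundle_radius^2] <- 2L

  anis <- array(0, shape)
  base <- c(0.15, bundle_level, 0.05) # GM, WM, CSF
  with_seed(seed, {
    jitter <- array(stats::rnorm(prod(shape), sd = 0.02), shape)
    for (lab in 1:3) {
      sel <- labels == lab
      anis[sel] <- clip01(base[lab] + jitter[sel], lo = 0.01)
    }
  })

  structure(
    list(
      labels = labels, anisotropy = anis, voxel_size = voxel_size,
      bundle = list(direction = direction, axis = ax, radius = bundle_radius,
                    level = bundle_level),
      seed = as.integer(seed)
    ),
    class = "tissue_phantom"
  )
}

#' @export
#' @method print tissue_phantom
print.tissue_phantom <- function(x, ...) {
  tb <- table(factor(x$labels, levels = 0:3,
                     labels = c("outside", "GM", "WM", "CSF")))
  cat(sprintf("Tissue phantom %s, voxel size %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  print(tb)
  invisible(x)
}

#' Synthetic diffusion-tensor field on a tissue phantom
#'
#' Assigns every in-mask voxel a symmetric positive-definite 3x3 diffusion
#' tensor. Bundle (WM) voxels get a prolate tensor whose principal
#' eigenvector follows `bundle_direction` with small angular jitter and
#' whose axial-to-radial eigenvalue ratio is `eigenvalue_ratio`; all other
#' voxels get near-isotropic tensors. Eigenvalues are scaled to unit mean
#' diffusivity (the edge-weight normalization makes the global scale
#' irrelevant).
#'
#' @param phantom a [make_tissue_phantom()] result.
#' @param bundle_direction unit 3-vector; defaults to the phantom's bundle
#'   axis. Non-unit input is normalized with a warning.
#' @param eigenvalue_ratio axial/radial eigenvalue ratio, > 1.
#' @param seed integer RNG seed.
#' @return Object of class `tensor_field`: list with `tensors` (n_mask x 6
#'   matrix of lower-triangular components Txx,Txy,Tyy,Txz,Tyz,Tzz),
#'   `mask_index` (linear indices of in-mask voxels in array order),
#'   `dim`, `voxel_size` and `phantom`.
#' @export
make_tensor_field <- function(phantom, bundle_direction = NULL,
                              eigenvalue_ratio = 5, seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (eigenvalue_ratio <= 1) stop("`eigenvalue_ratio` must be > 1")
  if (is.null(bundle_direction)) bundle_direction <- phantom$bundle$direction
  nrm <- sqrt(sum(bundle_direction^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("`bundle_direction` is not unit-norm; normalizing")
    bundle_direction <- bundle_direction / nrm
  }

  mask_index <- which(phantom$labels > 0L)
  n <- length(mask_index)
  is_wm <- phantom$labels[mask_index] == 2L

  with_seed(seed, {
    # principal directions: bundle direction with small jitter in WM,
    # irrelevant (isotropic) elsewhere but still well defined
    e1 <- matrix(bundle_direction, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, sd = 0.02), n, 3)
    e1 <- normalize_rows(e1)
    triad <- orthonormal_triads(e1)

    ratio <- ifelse(is_wm, eigenvalue_ratio,
                    1 + abs(stats::rnorm(n, sd = 0.02)))
    lam1 <- 3 * ratio / (ratio + 2)  # trace fixed at 3 (unit mean)
    lam23 <- 3 / (ratio + 2)
  })

  comp <- function(a, b) {
    lam1 * triad$e1[, a] * triad$e1[, b] +
      lam23 * (triad$e2[, a] * triad$e2[, b] + triad$e3[, a] * triad$e3[, b])
  }
  tensors <- cbind(
    Txx = comp(1, 1), Txy = comp(1, 2), Tyy = comp(2, 2),
    Txz = comp(1, 3), Tyz = comp(2, 3), Tzz = comp(3, 3)
  )

  structure(
    list(
      tensors = tensors, mask_index = mask_index, dim = dim(phantom$labels),
      voxel_size = phantom$voxel_size, phantom = phantom,
      bundle_direction = bundle_direction
    ),
    class = "tensor_field"
  )
}

#' Fractional anisotropy of a tensor field
#'
#' FA is computed from the tensor eigenvalues:
#' `sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`.
#'
#' @param field a [make_tensor_field()] result.
#' @return 3D array of FA values, zero outside the mask.
#' @export
fractional_anisotropy <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  fa <- array(0, field$dim)
  ev <- tensor_eigenvalues(field$tensors)
  mbar <- rowMeans(ev)
  fa[field$mask_index] <-
    sqrt(1.5 * rowSums((ev - mbar)^2) / rowSums(ev^2))
  fa
}

# eigenvalues of each row-packed symmetric tensor (n x 6 -> n x 3)
tensor_eigenvalues <- function(tensors) {
  t(apply(tensors, 1L, function(v) {
    m <- matrix(v[c(1, 2, 4, 2, 3, 5, 4, 5, 6)], 3, 3)
    eigen(m, symmetric = TRUE, only.values = TRUE)$values
  }))
}

#' Antipodally symmetric sphere direction table
#'
#' Fibonacci-lattice points on one hemisphere plus their antipodes, giving a
#' quasi-uniform full-sphere set closed under negation.
#'
#' @param n even integer, total number of directions.
#' @return n x 3 matrix of unit row vectors.
#' @export
sphere_directions <- function(n) {
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("`n` must be even (antipodal symmetry)")
  m <- n %/% 2L
  i <- seq_len(m) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / m                 # hemisphere z in (0, 1)
  r <- sqrt(1 - z^2)
  hemi <- cbind(r * cos(phi), r * sin(phi), z)
  unname(rbind(hemi, -hemi))
}

#' Synthetic ODF field on a tissue phantom
#'
#' Samples an orientation distribution function at each in-mask voxel over a
#' shared antipodally symmetric direction table. Bundle (WM) voxels carry a
#' Watson-type profile `exp(sharpness * ((d . mu)^2 - 1))` peaked along the
#' (jittered) bundle direction; all other voxels carry a constant
#' (isotropic) ODF.
#'
#' @param phantom a [make_tissue_phantom()] result.
#' @param bundle_direction unit 3-vector; defaults to the phantom's bundle
#'   axis.
#' @param sharpness Watson concentration, > 0; larger values sharpen the
#'   peak.
#' @param n_directions even integer >= 60; with fewer samples the spherical
#'   caps of the 98-direction scheme would be empty.
#' @param seed integer RNG seed.
#' @return Object of class `odf_field`: list with `amplitudes` (n_mask x
#'   n_directions, non-negative), `directions` (n_directions x 3 unit rows),
#'   `mask_index`, `dim`, `voxel_size`, `phantom`.
#' @export
make_odf_field <- function(phantom, bundle_direction = NULL, sharpness = 8,
                           n_directions = 642, seed = 1) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (sharpness <= 0) stop("`sharpness` must be > 0")
  if (n_directions < 60) {
    stop("`n_directions` must be >= 60 for adequate spherical-cap coverage")
  }
  if (is.null(bundle_direction)) bundle_direction <- phantom$bundle$direction
  bundle_direction <- bundle_direction / sqrt(sum(bundle_direction^2))

  dirs <- sphere_directions(n_directions)
  mask_index <- which(phantom$labels > 0L)
  n <- length(mask_index)
  is_wm <- phantom$labels[mask_index] == 2L

  amplitudes <- matrix(1, n, nrow(dirs))
  if (any(is_wm)) {
    with_seed(seed, {
      mu <- matrix(bundle_direction, sum(is_wm), 3, byrow = TRUE) +
        matrix(stats::rnorm(3 * sum(is_wm), sd = 0.02), ncol = 3)
      mu <- normalize_rows(mu)
    })
    cosang <- mu %*% t(dirs)               # n_wm x n_dir
    amplitudes[is_wm, ] <- exp(sharpness * (cosang^2 - 1))
  }

  structure(
    list(
      amplitudes = amplitudes, directions = dirs, mask_index = mask_index,
      dim = dim(phantom$labels), voxel_size = phantom$voxel_size,
      phantom = phantom, bundle_direction = bundle_direction,
      sharpness = sharpness
    ),
    class = "odf_field"
  )
}

#' Synthesize graph signals with a power-law spectral energy profile
#'
#' Each frame is a random linear combination of Laplacian eigenmodes with
#' coefficient standard deviation proportional to `i^(-spectral_exponent/2)`
#' for spectral indices `i >= 2` (so the expected per-mode energy follows
#' `i^(-spectral_exponent)`), zero weight on the constant-like first mode,
#' plus additive white Gaussian noise in node space.
#'
#' @param decomp a [eigendecompose()] result with at least 2 modes.
#' @param spectral_exponent power-law exponent of the expected energy
#'   profile (0 gives a flat profile over modes 2..C).
#' @param num_frames number of frames S.
#' @param noise_sd standard deviation of the additive node-space noise.
#' @param seed integer RNG seed.
#' @return Object of class `graph_signal_set`: list with `signals` (N x S
#'   matrix) and `frame_count`.
#' @export
make_graph_signals <- function(decomp, spectral_exponent = 2,
                               num_frames = 100, noise_sd = 0, seed = 1) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  C <- ncol(decomp$vectors)
  if (C < 2) stop("`decomp` must hold at least 2 modes")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  N <- nrow(decomp$vectors)
  sds <- c(0, (2:C)^(-spectral_exponent / 2))
  with_seed(seed, {
    coef <- matrix(stats::rnorm(C * num_frames), C, num_frames) * sds
    signals <- decomp$vectors %*% coef
    if (noise_sd > 0) {
      signals <- signals +
        matrix(stats::rnorm(N * num_frames, sd = noise_sd), N, num_frames)
    }
  })
  structure(
    list(signals = unname(as.matrix(signals)), frame_count = num_frames),
    class = "graph_signal_set"
  )
}

#' @export
#' @method print graph_signal_set
print.graph_signal_set <- function(x, ...) {
  cat(sprintf("Graph signal set: %d frames on %d nodes\n",
              x$frame_count, nrow(x$signals)))
  invisible(x)
}

#' Synthetic multi-subject cohort of diffusion fields
#'
#' Builds one base phantom, then derives `num_subjects` fields sharing its
#' grid. Each subject perturbs (i) the anisotropy map by a smooth random
#' field of scale `perturbation_sd`, and (ii) the bundle direction by a
#' random rotation of angle `~ |N(0, perturbation_sd)|` radians. With
#' `perturbation_sd = 0` all subjects are identical. The field-construction
#' seed is shared across subjects, so only the perturbations differ.
#'
#' @param base_phantom_args list of arguments for [make_tissue_phantom()].
#' @param num_subjects integer >= 2.
#' @param perturbation_sd perturbation scale (anisotropy units / radians).
#' @param seed integer RNG seed.
#' @param model `"odf"` or `"dti"`.
#' @param field_args extra arguments for [make_odf_field()] /
#'   [make_tensor_field()].
#' @return list of `odf_field` (or `tensor_field`) objects, one per subject,
#'   each with a `subject_id` element.
#' @export
make_cohort <- function(base_phantom_args, num_subjects, perturbation_sd,
                        seed = 1, model = c("odf", "dti"),
                        field_args = list()) {
  model <- match.arg(model)
  if (num_subjects < 2) stop("`num_subjects` must be >= 2")
  if (perturbation_sd < 0) stop("`perturbation_sd` must be >= 0")
  base <- do.call(make_tissue_phantom, base_phantom_args)
  mask <- base$labels > 0L

  lapply(seq_len(num_subjects), function(s) {
    ph <- base
    dir_s <- base$bundle$direction
    if (perturbation_sd > 0) {
      with_seed(seed + 1000L * s, {
        noise <- box_smooth3(
          array(stats::rnorm(prod(dim(base$labels)), sd = perturbation_sd),
                dim(base$labels))
        )
        ph$anisotropy[mask] <- clip01(base$anisotropy[mask] + noise[mask],
                                      lo = 0.01)
        axis <- stats::rnorm(3)
        angle <- abs(stats::rnorm(1, sd = perturbation_sd))
        dir_s <- rotate_about(dir_s, axis, angle)
      })
    }
    fld <- switch(model,
      odf = do.call(make_odf_field, c(
        list(phantom = ph, bundle_direction = dir_s, seed = seed), field_args
      )),
      dti = do.call(make_tensor_field, c(
        list(phantom = ph, bundle_direction = dir_s, seed = seed), field_args
      ))
    )
    fld$subject_id <- s
    fld
  })
}
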