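#' Diffusion profile from a tensor field
#'
#' Evaluates, for every in-mask voxel i and every neighborhood direction,
#' the 3D Gaussian diffusion model
#' `p(i, r) = (2*pi)^(-3/2) |T|^(-1/2) exp(-r' T^{-1} r / 2)`
#' at the physical displacement `r = offset * voxel_size` (mm), where `T`
#' is the voxel's diffusion tensor. Displacements keep their true lengths,
#' so outer-shell neighbors of the 98-direction scheme enter at up to
#' twice the inner-shell distance.
#'
#' @param field a [make_tensor_field()] result (or compatible list).
#' @param scheme a [build_scheme()] result.
#' @return Object of class `diffusion_profile`: list with `values` (n_mask x
#'   n_directions matrix, `NA` where the neighbor voxel is outside the
#'   mask), `present` (logical matrix), `mask_index`, `dim`, `voxel_size`,
#'   `anisotropy` (phantom map if available) and `scheme`.
#' @export
dti_profile <- function(field, scheme) {
  stopifnot(inherits(scheme, "neighborhood_scheme"))
  tens <- field$tensors
  n <- nrow(tens)

  # closed-form inverse/determinant of each symmetric 3x3 tensor
  a <- tens[, 1]; b <- tens[, 2]; c <- tens[, 3]
  d <- tens[, 4]; e <- tens[, 5]; f <- tens[, 6]
  det <- a * (c * f - e * e) - b * (b * f - e * d) + d * (b * e - c * d)
  bad <- !(det > 0)
  if (any(bad)) {
    coords <- arrayInd(field$mask_index[which(bad)[1]], field$dim)
    stop(sprintf(
      "singular or non-positive-definite tensor at voxel (%d, %d, %d)",
      coords[1], coords[2], coords[3]
    ))
  }
  # adjugate entries (symmetric): inv = adj / det
  i11 <- (c * f - e * e) / det
  i12 <- (d * e - b * f) / det
  i22 <- (a * f - d * d) / det
  i13 <- (b * e - c * d) / det
  i23 <- (b * d - a * e) / det
  i33 <- (a * c - b * b) / det

  disp <- sweep(scheme$offsets, 2L, field$voxel_size, `*`)
  norm_const <- (2 * pi)^(-1.5) / sqrt(det)
  values <- matrix(NA_real_, n, nrow(disp))
  for (k in seq_len(nrow(disp))) {
    r <- disp[k, ]
    q <- i11 * r[1]^2 + i22 * r[2]^2 + i33 * r[3]^2 +
      2 * (i12 * r[1] * r[2] + i13 * r[1] * r[3] + i23 * r[2] * r[3])
    if (any(q < 0)) {
      coords <- arrayInd(field$mask_index[which(q < 0)[1]], field$dim)
      stop(sprintf(
        "non-positive-definite tensor at voxel (%d, %d, %d)",
        coords[1], coords[2], coords[3]
      ))
    }
    values[, k] <- norm_const * exp(-q / 2)
  }

  new_profile(values, field, scheme)
}

# shared constructor: mark directions whose neighbor is outside the mask
new_profile <- function(values, field, scheme) {
  d <- field$dim
  mask <- array(FALSE, d)
  mask[field$mask_index] <- TRUE
  coords <- arrayInd(field$mask_index, d)
  present <- matrix(FALSE, nrow(values), nrow(scheme$offsets))
  for (k in seq_len(nrow(scheme$offsets))) {
    nb <- sweep(coords, 2L, scheme$offsets[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    inb <- rep(FALSE, nrow(coords))
    inb[ok] <- mask[nb[ok, , drop = FALSE]]
    present[, k] <- inb
  }
  values[!present] <- NA_real_
  anis <- if (!is.null(field$phantom)) field$phantom$anisotropy else NULL
  structure(
    list(
      values = values, present = present, mask_index = field$mask_index,
      dim = d, voxel_size = field$voxel_size, anisotropy = anis,
      scheme = scheme
    ),
    class = "diffusion_profile"
  )
}

#' @export
#' @method print diffusion_profile
print.diffusion_profile <- function(x, ...) {
  cat(sprintf(
    "Diffusion profile: %d voxels x %d directions (%d-connectivity)\n",
    nrow(x$values), ncol(x$values), x$scheme$connectivity
  ))
  invisible(x)
}

#' Spherical-cap membership of ODF sample directions
#'
#' Assigns every ODF sample direction to the neighborhood direction(s)
#' whose spherical cap it falls in. Each neighborhood direction subtends a
#' cap of solid angle `Omega = 4*pi/26` (3-connectivity) or `4*pi/98`
#' (5-connectivity); inverting the cap-area relation
#' `2*pi*(1 - cos(theta)) = Omega` gives the half-angle
#' `theta = arccos(1 - Omega/(2*pi))`. Caps may overlap; every sample can
#' belong to several caps.
#'
#' @param sample_directions N_o x 3 matrix of unit row vectors.
#' @param scheme a [build_scheme()] result.
#' @return Object of class `cap_membership`: list with `members` (list of
#'   sample-index vectors, one per scheme direction), `counts`,
#'   `cos_threshold`, `scheme`.
#' @export
cap_membership <- function(sample_directions, scheme) {
  stopifnot(inherits(scheme, "neighborhood_scheme"))
  sample_directions <- as.matrix(sample_directions)
  nrm <- sqrt(rowSums(sample_directions^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("sample directions must be unit-norm")
  }
  cos_threshold <- 1 - scheme$solid_angle / (2 * pi)
  cosang <- sample_directions %*% t(scheme$directions)
  members <- lapply(seq_len(ncol(cosang)), function(k) {
    which(cosang[, k] >= cos_threshold)
  })
  counts <- lengths(members)
  if (any(counts == 0)) {
    k <- which(counts == 0)[1]
    stop(sprintf(
      "empty spherical cap for direction (%d, %d, %d): too few ODF samples",
      scheme$offsets[k, 1], scheme$offsets[k, 2], scheme$offsets[k, 3]
    ))
  }
  structure(
    list(members = members, counts = counts, cos_threshold = cos_threshold,
         scheme = scheme),
    class = "cap_membership"
  )
}

#' Diffusion profile from an ODF field
#'
#' For each voxel and neighborhood direction, averages the sharpened ODF
#' amplitudes over the direction's spherical cap:
#' `p(i, r) = mean_{k in cap}( O_{i,k}^n )`,
#' the discrete cap-average of the ODF raised to the sharpening power `n`.
#' Normalization by cap cardinality compensates for unequal numbers of
#' samples per cap.
#'
#' @param field a [make_odf_field()] result (or compatible list).
#' @param scheme a [build_scheme()] result.
#' @param exponent_n sharpening power, > 0 (default 2).
#' @return A `diffusion_profile`, as in [dti_profile()].
#' @export
odf_profile <- function(field, scheme, exponent_n = 2) {
  stopifnot(inherits(scheme, "neighborhood_scheme"))
  if (exponent_n <= 0) stop("`exponent_n` must be > 0")
  amp <- field$amplitudes
  if (any(amp < 0)) stop("ODF amplitudes must be non-negative in the mask")

  caps <- cap_membership(field$directions, scheme)
  indicator <- matrix(0, nrow(field$directions), length(caps$members))
  for (k in seq_along(caps$members)) indicator[caps$members[[k]], k] <- 1
  values <- (amp^exponent_n %*% indicator) /
    matrix(caps$counts, nrow(amp), length(caps$counts), byrow = TRUE)

  new_profile(unname(values), field, scheme)
}
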