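# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Row-normalize a matrix of vectors; errors on zero rows.
normalize_rows <- function(m, what = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm ", what)
  m / nrm
}

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# 3x3x3 box smoothing of a 3D array (edge-renormalized); used for smooth
# spatial perturbation fields.
box_smooth3 <- function(a) {
  d <- dim(a)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    acc[xs - dx, ys - dy, zs - dz] <-
      acc[xs - dx, ys - dy, zs - dz] + a[xs, ys, zs]
    cnt[xs - dx, ys - dy, zs - dz] <- cnt[xs - dx, ys - dy, zs - dz] + 1
  }
  acc / cnt
}

# Complete a set of unit vectors (rows of e1) to right-handed orthonormal
# triads; returns list(e1, e2, e3) of n x 3 matrices.
orthonormal_triads <- function(e1) {
  n <- nrow(e1)
  # helper axis least aligned with each e1
  h <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  flip <- abs(e1[, 1]) > 0.9
  h[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  e2 <- h - e1 * rowSums(h * e1)
  e2 <- normalize_rows(e2)
  e3 <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Apply a rotation taking unit vector `from` a small angle towards
# randomness: rotate `v` about a random axis by `angle` radians.
rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) +
    c(
      axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]
    ) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

axis_to_unit <- function(axis) {
  if (is.character(axis)) {
    i <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(i)) stop("bundle axis must be 'x', 'y' or 'z'")
    unit <- c(0, 0, 0)
    unit[i] <- 1
    unit
  } else {
    v <- as.numeric(axis)
    stopifnot(length(v) == 3)
    v / sqrt(sum(v^2))
  }
}
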