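#' Graph Fourier transform
#'
#' Projects a node signal onto the Laplacian eigenvector basis:
#' `x_tilde = U' x`. With the full basis the inverse transform
#' `U x_tilde` reconstructs `x` exactly; with a partial basis it gives the
#' orthogonal projection onto the spanned subspace.
#'
#' @param U N x C matrix of orthonormal eigenvector columns (or a
#'   `spectral_decomposition`).
#' @param x numeric signal of length N, or an N x S matrix of frames.
#' @return length-C coefficient vector (or C x S matrix).
#' @export
gft <- function(U, x) {
  if (inherits(U, "spectral_decomposition")) U <- U$vectors
  if (is.matrix(x)) {
    stopifnot(nrow(x) == nrow(U))
    crossprod(U, x)
  } else {
    stopifnot(length(x) == nrow(U))
    as.numeric(crossprod(U, x))
  }
}

#' Inverse graph Fourier transform
#'
#' @param U N x C eigenvector matrix (or a `spectral_decomposition`).
#' @param coef length-C coefficient vector (or C x S matrix).
#' @return signal of length N (or N x S matrix).
#' @export
inverse_gft <- function(U, coef) {
  if (inherits(U, "spectral_decomposition")) U <- U$vectors
  if (is.matrix(coef)) U %*% coef else as.numeric(U %*% coef)
}

#' Demean and normalize a graph signal
#'
#' Removes the component along the first Laplacian eigenvector and scales
#' to unit Euclidean norm:
#' `x_out = (x - (u1' x) u1) / || x - (u1' x) u1 ||`.
#' The result is orthogonal to `u1` (its first GFT coefficient is zero)
#' and carries unit total energy.
#'
#' @param x numeric signal of length N.
#' @param u1 first eigenvector (unit norm).
#' @param tol relative residual below which the frame is declared
#'   degenerate (parallel to `u1`).
#' @return unit-norm signal orthogonal to `u1`. A frame parallel to `u1`
#'   raises a condition of class `voxelgraph_degenerate_frame`.
#' @export
demean_normalize <- function(x, u1, tol = 1e-12) {
  stopifnot(length(x) == length(u1))
  r <- x - sum(u1 * x) * u1
  nrm <- sqrt(sum(r^2))
  if (nrm <= tol * max(sqrt(sum(x^2)), 1e-300)) {
    stop(structure(
      class = c("voxelgraph_degenerate_frame", "error", "condition"),
      list(message = "frame is parallel to u1: zero residual after demeaning",
           call = sys.call(-1))
    ))
  }
  r / nrm
}

#' Ensemble energy spectral density of a set of graph signals
#'
#' Each frame is demeaned and normalized (see [demean_normalize()]); its
#' energy at spectral index i is the squared GFT coefficient
#' `|x_tilde[i]|^2`. The ensemble energy spectral density is the mean of
#' these energies over frames, reported for indices `1..C`; index 1 is
#' exactly zero by construction (the first-mode component is regressed
#' out). Degenerate frames (parallel to the first eigenvector) are excluded
#' with a message.
#'
#' @param signals a `graph_signal_set` or N x S matrix.
#' @param decomp a `spectral_decomposition` with at least `C` modes.
#' @param C cutoff index (default: all available modes, conventionally
#'   1000 on large graphs).
#' @return Object of class `energy_spectrum`: list with `index`, `eesd`,
#'   `cumulative`, `frame_count` (frames used), `C`.
#' @export
eesd <- function(signals, decomp, C = NULL) {
  X <- if (inherits(signals, "graph_signal_set")) signals$signals else
    as.matrix(signals)
  stopifnot(inherits(decomp, "spectral_decomposition"))
  if (is.null(C)) C <- decomp$C
  if (C > decomp$C) stop("`C` exceeds the available number of modes")
  if (nrow(X) != nrow(decomp$vectors)) {
    stop("signal length does not match graph node count")
  }
  u1 <- decomp$vectors[, 1]
  U <- decomp$vectors[, seq_len(C), drop = FALSE]

  used <- 0L
  acc <- numeric(C)
  for (k in seq_len(ncol(X))) {
    xk <- tryCatch(demean_normalize(X[, k], u1), voxelgraph_degenerate_frame =
                     function(e) NULL)
    if (is.null(xk)) next
    acc <- acc + gft(U, xk)^2
    used <- used + 1L
  }
  if (used == 0L) stop("all frames are degenerate (parallel to u1)")
  if (used < ncol(X)) {
    message(sprintf("eesd: excluded %d degenerate frame(s)",
                    ncol(X) - used))
  }
  e <- acc / used
  e[1] <- 0  # analytically exact after demeaning
  structure(
    list(index = seq_len(C), eesd = e, cumulative = cumsum(e),
         frame_count = used, C = C),
    class = "energy_spectrum"
  )
}

#' @export
#' @method print energy_spectrum
print.energy_spectrum <- function(x, ...) {
  cat(sprintf(
    "Energy spectrum: %d indices over %d frames; cumulative at C = %.4f\n",
    x$C, x$frame_count, x$cumulative[x$C]
  ))
  invisible(x)
}

#' @export
plot.energy_spectrum <- function(x, log = "xy", ...) {
  keep <- x$index >= 2 & x$eesd > 0
  graphics::plot(
    x$index[keep], x$eesd[keep], type = "l", log = log,
    xlab = "spectral index", ylab = "ensemble energy",
    main = "ensemble energy spectral density", ...
  )
  invisible(x)
}

#' Spatially shuffled null signals
#'
#' Independently permutes each frame's values across nodes, destroying
#' spatial order while preserving each frame's value distribution.
#'
#' @param signals a `graph_signal_set` or N x S matrix.
#' @param seed integer RNG seed.
#' @return a `graph_signal_set`.
#' @export
shuffle_null <- function(signals, seed = 1) {
  X <- if (inherits(signals, "graph_signal_set")) signals$signals else
    as.matrix(signals)
  out <- with_seed(seed, {
    apply(X, 2L, function(col) col[sample.int(length(col))])
  })
  structure(list(signals = out, frame_count = ncol(out)),
            class = "graph_signal_set")
}

#' White Gaussian null signals
#'
#' @param N number of nodes.
#' @param S number of frames.
#' @param seed integer RNG seed.
#' @return a `graph_signal_set` of i.i.d. standard normal frames.
#' @export
gaussian_null <- function(N, S, seed = 1) {
  X <- with_seed(seed, matrix(stats::rnorm(N * S), N, S))
  structure(list(signals = X, frame_count = S),
            class = "graph_signal_set")
}
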