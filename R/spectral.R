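#' Normalized graph Laplacian
#'
#' `L = I - D^{-1/2} A D^{-1/2}`, symmetric positive semi-definite with
#' spectrum in \[0, 2\]. Diagonal entries are 1, off-diagonals
#' `-a_ij / sqrt(d_i d_j)`.
#'
#' @param graph a `brain_graph` (or any object with a sparse symmetric
#'   `adjacency` element).
#' @return sparse symmetric `dsCMatrix`.
#' @export
normalized_laplacian <- function(graph) {
  A <- if (inherits(graph, "brain_graph")) graph$adjacency else graph
  deg <- Matrix::rowSums(A)
  if (any(deg <= 0)) stop("zero-degree node: cannot normalize")
  dinv <- 1 / sqrt(deg)
  n <- nrow(A)
  L <- Matrix::Diagonal(n) - Matrix::Diagonal(n, dinv) %*% A %*%
    Matrix::Diagonal(n, dinv)
  methods::as(Matrix::forceSymmetric(L), "CsparseMatrix")
}

#' Leading eigenpairs of the normalized Laplacian
#'
#' Computes the `C` algebraically smallest eigenvalues and eigenvectors of
#' a sparse symmetric Laplacian, sorted ascending. Because the lower end of
#' the spectrum is dense near zero for large graphs, the iterative path
#' uses shift-invert: a sparse Cholesky factor of `L + sigma*I`
#' (`sigma = 0.1`) feeds an ARPACK Lanczos iteration on its inverse, whose
#' largest eigenvalues map back to the smallest of `L`. Small problems fall
#' back to dense diagonalization.
#'
#' Each eigenvector's sign is fixed so that its largest-absolute entry is
#' positive (ties broken by lowest node index), making results reproducible
#' up to eigenvalue degeneracy.
#'
#' @param L sparse symmetric Laplacian, e.g. [normalized_laplacian()].
#' @param C number of leading eigenpairs, `C < N`.
#' @param method `"auto"` (dense for N <= 400), `"arpack"` or `"dense"`.
#' @param tol residual tolerance: each pair must satisfy
#'   `||L u - lambda u|| <= tol` (default 1e-8).
#' @param seed seed for the ARPACK starting vector.
#' @param graph optional `brain_graph` to attach.
#' @return Object of class `spectral_decomposition`: list with `values`
#'   (ascending), `vectors` (N x C, orthonormal columns), `residuals`, `C`,
#'   `method`, and `graph`.
#' @export
eigendecompose <- function(L, C, method = c("auto", "arpack", "dense"),
                           tol = 1e-8, seed = 1, graph = NULL) {
  method <- match.arg(method)
  n <- nrow(L)
  C <- as.integer(C)
  if (C >= n) stop("`C` must be smaller than the number of nodes")
  if (method == "auto") method <- if (n <= 400) "dense" else "arpack"

  if (method == "dense") {
    eig <- eigen(as.matrix(L), symmetric = TRUE)
    ord <- order(eig$values)
    vals <- eig$values[ord][seq_len(C)]
    vecs <- eig$vectors[, ord, drop = FALSE][, seq_len(C), drop = FALSE]
  } else {
    sigma <- 0.1
    ch <- Matrix::Cholesky(L + sigma * Matrix::Diagonal(n), LDL = FALSE)
    fn <- function(x, extra = NULL) {
      as.numeric(Matrix::solve(ch, x, system = "A"))
    }
    res <- with_seed(seed, igraph::arpack(
      fn, sym = TRUE,
      options = list(
        n = n, nev = C, ncv = min(n, max(2 * C + 1, 20)),
        which = "LM", maxiter = 3000
      )
    ))
    vals <- 1 / res$values - sigma
    ord <- order(vals)
    vals <- vals[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }

  # clean tiny negative round-off at the bottom of the spectrum
  vals[vals < 0 & vals > -tol] <- pmax(vals[vals < 0 & vals > -tol], 0)

  # sign convention: largest-absolute entry positive, ties -> lowest index
  for (k in seq_len(ncol(vecs))) {
    v <- vecs[, k]
    i <- which(abs(v) == max(abs(v)))[1]
    if (v[i] < 0) vecs[, k] <- -v
  }

  residuals <- vapply(seq_len(C), function(k) {
    sqrt(sum((as.numeric(L %*% vecs[, k]) - vals[k] * vecs[, k])^2))
  }, numeric(1))
  if (any(residuals > tol)) {
    stop(sprintf(
      "eigensolver did not converge: max residual %.3g exceeds tol %.3g",
      max(residuals), tol
    ))
  }

  structure(
    list(values = vals, vectors = unname(vecs), residuals = residuals,
         C = C, method = method, graph = graph),
    class = "spectral_decomposition"
  )
}

#' @export
#' @method print spectral_decomposition
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf(
    "Spectral decomposition: %d modes on %d nodes (%s)\n",
    x$C, nrow(x$vectors), x$method
  ))
  cat(sprintf("  eigenvalues in [%.3g, %.3g], max residual %.2g\n",
              min(x$values), max(x$values), max(x$residuals)))
  invisible(x)
}

#' @export
plot.spectral_decomposition <- function(x, ...) {
  graphics::plot(
    seq_along(x$values), x$values, type = "l",
    xlab = "spectral index", ylab = expression(lambda[i]),
    main = "lower-end Laplacian spectrum", ...
  )
  invisible(x)
}

#' Total variation of a graph signal
#'
#' `TV(x) = x' L x`, the quadratic-form smoothness measure. For a
#' unit-norm eigenvector `u_i` it equals the eigenvalue `lambda_i`,
#' grounding the graph-frequency interpretation of the spectrum.
#'
#' @param L sparse symmetric Laplacian.
#' @param x numeric signal of length N.
#' @return non-negative scalar.
#' @export
total_variation <- function(L, x) {
  stopifnot(length(x) == nrow(L))
  as.numeric(Matrix::crossprod(x, L %*% x))
}

#' Weighted zero-crossings of a graph signal
#'
#' `ZC(u) = (1/2) * sum_{i != j} a_ij * H(-u[i] u[j])`: the edge-weight
#' weighted count of edges whose endpoint values have strictly opposite
#' signs (`H(0) = 0`, so an exactly-zero endpoint contributes nothing).
#' The half and the symmetric double sum make each undirected edge count
#' once.
#'
#' @param graph a `brain_graph`.
#' @param u numeric signal of length N.
#' @return non-negative scalar.
#' @export
zero_crossings <- function(graph, u) {
  A <- if (inherits(graph, "brain_graph")) graph$adjacency else graph
  stopifnot(length(u) == nrow(A))
  Ag <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  upper <- Ag@i < Ag@j   # 0-based triplets; each undirected edge once
  i <- Ag@i[upper] + 1L; j <- Ag@j[upper] + 1L; w <- Ag@x[upper]
  sum(w[u[i] * u[j] < 0])
}
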