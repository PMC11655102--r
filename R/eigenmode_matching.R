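#' Procrustes-based column matching of two eigenmode sets
#'
#' Finds the signed permutation of the columns of `X_m` that best matches
#' the columns of `X_ref`, maximizing the total absolute cosine similarity
#' between matched columns. Eigenmodes are defined only up to sign, and
#' modes with close eigenvalues may swap order across subjects; a signed
#' permutation corrects exactly these ambiguities. The assignment is solved
#' exactly by the Hungarian algorithm on the `K x K` absolute
#' cosine-similarity matrix; each matched column's sign is chosen to make
#' its cosine to the reference non-negative.
#'
#' @param X_ref N x K reference matrix (near-orthonormal columns).
#' @param X_m N x K matrix to reorder.
#' @return list with `permutation` (column `j` of the output is column
#'   `permutation[j]` of the input), `signs` (+1/-1 per output column) and
#'   `X` (the reordered, sign-fixed matrix).
#' @export
procrustes_reorder <- function(X_ref, X_m) {
  X_ref <- as.matrix(X_ref); X_m <- as.matrix(X_m)
  if (!all(dim(X_ref) == dim(X_m))) stop("matrices must share shape")
  cref <- sweep(X_ref, 2L, sqrt(colSums(X_ref^2)), `/`)
  cm <- sweep(X_m, 2L, sqrt(colSums(X_m^2)), `/`)
  M <- crossprod(cref, cm)              # K x K cosine similarities
  perm <- solve_assignment(-abs(M))     # minimize negative |cosine|
  signs <- ifelse(M[cbind(seq_len(ncol(M)), perm)] >= 0, 1, -1)
  X <- sweep(X_m[, perm, drop = FALSE], 2L, signs, `*`)
  list(permutation = perm, signs = signs, X = X)
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# for square cost matrices; returns perm with perm[row] = assigned column
# minimizing sum(cost[i, perm[i]]).
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)        # p[col] = row assigned to col (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                  # column indices offset by 1 (1 = dummy)
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2L:(n + 1L)) perm[p[j]] <- j - 1L
  perm
}

#' Group-level matching of eigenmode sets
#'
#' Iteratively aligns M subjects' eigenmode matrices to a running group
#' average: the average is initialized to subject 1's matrix; each pass
#' reorders every subject against the current average
#' (see [procrustes_reorder()]) and then recomputes the average as the
#' element-wise mean of the reordered matrices. Iterating past the first
#' pass removes the bias of the average toward subject 1. By default the
#' loop stops when no permutation or sign changes between passes, capped
#' at `max_iter`.
#'
#' @param sets list of M matrices (N x K each), M >= 2, or objects with an
#'   `$X` matrix element.
#' @param J fixed number of passes; `NULL` (default) iterates to
#'   convergence.
#' @param max_iter cap on passes when `J` is `NULL`.
#' @return Object of class `eigenmode_match`: list with `sets` (reordered
#'   matrices), `average` (element-wise mean), `permutations`, `signs`,
#'   `iterations`, `converged`.
#' @export
group_match <- function(sets, J = NULL, max_iter = 20L) {
  sets <- lapply(sets, function(s) if (is.list(s)) as.matrix(s$X) else
    as.matrix(s))
  M <- length(sets)
  if (M < 2) stop("at least 2 subjects are required")
  dims <- vapply(sets, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all eigenmode sets must share N and K")
  }
  K <- dims[2, 1]

  X_avg <- sets[[1]]
  perms <- lapply(seq_len(M), function(m) seq_len(K))
  signs <- lapply(seq_len(M), function(m) rep(1, K))
  n_pass <- if (is.null(J)) max_iter else J
  converged <- FALSE
  it <- 0L
  for (j in seq_len(n_pass)) {
    it <- j
    changed <- FALSE
    for (m in seq_len(M)) {
      r <- procrustes_reorder(X_avg, sets[[m]])
      new_perm <- perms[[m]][r$permutation]
      new_sign <- signs[[m]][r$permutation] * r$signs
      if (!identical(new_perm, perms[[m]]) ||
          !isTRUE(all.equal(new_sign, signs[[m]]))) {
        changed <- TRUE
      }
      perms[[m]] <- new_perm
      signs[[m]] <- new_sign
      sets[[m]] <- r$X
    }
    X_avg <- Reduce(`+`, sets) / M
    if (is.null(J) && !changed) {
      converged <- TRUE
      break
    }
  }
  if (!is.null(J)) converged <- NA

  structure(
    list(sets = sets, average = X_avg, permutations = perms, signs = signs,
         iterations = it, converged = converged),
    class = "eigenmode_match"
  )
}

#' @export
#' @method print eigenmode_match
print.eigenmode_match <- function(x, ...) {
  cat(sprintf(
    "Eigenmode match: %d subjects, K = %d, %d iteration(s)%s\n",
    length(x$sets), ncol(x$average), x$iterations,
    if (isTRUE(x$converged)) " (converged)" else ""
  ))
  invisible(x)
}

#' Procrustes error between two eigenmode sets
#'
#' Half the Frobenius norm of the off-diagonal of the column-wise cosine
#' similarity matrix:
#' \deqn{E_{m,n}(K) = \frac{1}{2}\sqrt{\sum_{i} \sum_{j \ne i}
#'   \left(\frac{u_{i,m}' u_{j,n}}{\|u_{i,m}\| \|u_{j,n}\|}\right)^2}}
#' Zero iff matched modes are mutually exclusive across subjects (identity
#' cosine-similarity pattern); larger values indicate residual
#' subject-specific structure that a signed permutation cannot remove.
#'
#' @param X_m,X_n N x K matrices.
#' @return non-negative scalar, symmetric in its arguments.
#' @export
procrustes_error <- function(X_m, X_n) {
  X_m <- as.matrix(X_m); X_n <- as.matrix(X_n)
  if (!all(dim(X_m) == dim(X_n))) stop("matrices must share shape")
  nm <- sqrt(colSums(X_m^2)); nn <- sqrt(colSums(X_n^2))
  if (any(nm == 0) || any(nn == 0)) stop("zero-norm column")
  Ccos <- crossprod(X_m / rep(nm, each = nrow(X_m)),
                    X_n / rep(nn, each = nrow(X_n)))
  0.5 * sqrt(sum(Ccos^2) - sum(diag(Ccos)^2))
}

#' Bootstrap validation of eigenmode matching over subspace sizes
#'
#' For each subspace size `K` in `K_grid`, repeatedly samples a pair of
#' subjects (without replacement within a draw), matches their first `K`
#' eigenmodes pairwise (see [group_match()]), and records the resulting
#' Procrustes error. Reports the mean and standard deviation per `K`.
#' Rising mean error with larger `K` indicates that higher modes carry
#' more subject-specific (or noise) structure that matching cannot align.
#'
#' @param sets list of >= 2 subject matrices (N x K_max).
#' @param K_grid integer vector of subspace sizes, each <= K_max.
#' @param draws bootstrap repetitions per K.
#' @param seed integer RNG seed.
#' @param J passed to [group_match()].
#' @return Object of class `procrustes_stats`: list with `K_grid`, `mu`,
#'   `sigma`, `draws`.
#' @export
bootstrap_validation <- function(sets, K_grid, draws = 100, seed = 1,
                                 J = NULL) {
  sets <- lapply(sets, as.matrix)
  if (length(sets) < 2) stop("at least 2 subjects are required")
  K_max <- min(vapply(sets, ncol, integer(1)))
  bad <- K_grid[K_grid > K_max]
  if (length(bad)) {
    stop(sprintf("K = %d exceeds the available %d modes", bad[1], K_max))
  }
  mu <- sigma <- numeric(length(K_grid))
  with_seed(seed, {
    for (g in seq_along(K_grid)) {
      K <- K_grid[g]
      eps <- vapply(seq_len(draws), function(j) {
        pair <- sample.int(length(sets), 2L)
        sub <- lapply(sets[pair], function(X) X[, seq_len(K), drop = FALSE])
        m <- group_match(sub, J = J)
        procrustes_error(m$sets[[1]], m$sets[[2]])
      }, numeric(1))
      mu[g] <- mean(eps)
      sigma[g] <- stats::sd(eps)
    }
  })
  structure(
    list(K_grid = as.integer(K_grid), mu = mu, sigma = sigma,
         draws = as.integer(draws)),
    class = "procrustes_stats"
  )
}

#' @export
#' @method print procrustes_stats
print.procrustes_stats <- function(x, ...) {
  cat(sprintf("Procrustes validation over %d draws per K:\n", x$draws))
  print(data.frame(K = x$K_grid, mu = x$mu, sigma = x$sigma),
        row.names = FALSE)
  invisible(x)
}

#' Random orthonormal eigenmode sets (null model)
#'
#' Draws `K` orthonormal columns in `N` dimensions from the Haar measure
#' (QR of a Gaussian matrix), serving as a structure-free null against
#' which cohort Procrustes errors are compared.
#'
#' @param N,K dimensions.
#' @param num_subjects number of independent sets.
#' @param seed integer RNG seed.
#' @return list of N x K matrices.
#' @export
random_orthonormal_sets <- function(N, K, num_subjects, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(num_subjects), function(s) {
      qr.Q(qr(matrix(stats::rnorm(N * K), N, K)))
    })
  })
}
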