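# Shared fixtures, built in code. Memoised within a test run: several test
# files reuse the same small phantom graphs.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# 24^3 DTI phantom graph with 50 modes (the workhorse spectral fixture)
dti_fixture <- function() {
  memo("dti24", function() {
    ph <- make_tissue_phantom(c(24, 24, 24), bundle_radius = 3, seed = 11)
    fld <- make_tensor_field(ph, eigenvalue_ratio = 5, seed = 11)
    sch <- build_scheme(3)
    pr <- dti_profile(fld, sch)
    g <- assemble_graph(pr)
    L <- normalized_laplacian(g)
    dec <- eigendecompose(L, C = 50, method = "arpack", graph = g)
    list(phantom = ph, field = fld, scheme = sch, profile = pr, graph = g,
         L = L, decomp = dec)
  })
}

# 14^3 ODF phantom graphs at both connectivities
odf_fixture <- function() {
  memo("odf14", function() {
    ph <- make_tissue_phantom(c(14, 14, 14), bundle_radius = 2, seed = 7)
    fld <- make_odf_field(ph, sharpness = 8, n_directions = 642, seed = 7)
    sch3 <- build_scheme(3)
    sch5 <- build_scheme(5)
    pr3 <- odf_profile(fld, sch3)
    pr5 <- odf_profile(fld, sch5)
    g3 <- assemble_graph(pr3)
    g5 <- assemble_graph(pr5)
    list(phantom = ph, field = fld, scheme3 = sch3, scheme5 = sch5,
         profile3 = pr3, profile5 = pr5, graph3 = g3, graph5 = g5)
  })
}

# tiny all-in-mask box graph with isotropic tensors (hand-checkable)
toy_tensor_field <- function(shape, tensor = c(1, 0, 1, 0, 0, 1),
                             labels = NULL, anisotropy = NULL) {
  if (is.null(labels)) labels <- array(2L, shape)
  mask_index <- which(labels > 0L)
  if (is.null(anisotropy)) {
    anisotropy <- array(0, shape)
    anisotropy[mask_index] <- 0.8
  }
  phantom <- structure(
    list(labels = labels, anisotropy = anisotropy,
         voxel_size = c(1, 1, 1), bundle = NULL, seed = NA_integer_),
    class = "tissue_phantom"
  )
  structure(
    list(tensors = matrix(tensor, length(mask_index), 6, byrow = TRUE),
         mask_index = mask_index, dim = shape, voxel_size = c(1, 1, 1),
         phantom = phantom),
    class = "tensor_field"
  )
}

# brain_graph wrapper around an explicit sparse symmetric adjacency
graph_from_adjacency <- function(A) {
  A <- methods::as(Matrix::forceSymmetric(Matrix::Matrix(A, sparse = TRUE)),
                   "CsparseMatrix")
  n <- nrow(A)
  structure(
    list(adjacency = A, coords = cbind(seq_len(n), 1L, 1L),
         mask_index = seq_len(n), node_volume = NULL,
         degrees = Matrix::rowSums(A), voxel_size = c(1, 1, 1),
         dim = c(n, 1L, 1L), alpha = 1,
         dropped_isolated = 0L, dropped_component = 0L),
    class = "brain_graph"
  )
}

# small connected weighted random graph for spectral/GSP toys
toy_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- ifelse(runif(sum(up)) < p, runif(sum(up)), 0)
    A <- A + t(A)
    g <- graph_from_adjacency(A)
    if (all(Matrix::rowSums(g$adjacency) > 0)) {
      comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        g$adjacency > 0, mode = "undirected"))
      if (comp$no == 1) return(g)
    }
  }
}

# exhaustive signed-permutation assignment (oracle for K <= 6)
brute_force_assignment <- function(absM) {
  K <- nrow(absM)
  perms <- gtools_permutations(K)
  best <- NULL
  best_val <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    val <- sum(absM[cbind(seq_len(K), p)])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(permutation = best, value = best_val)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  unname(out)
}
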