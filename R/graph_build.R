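#' Assemble a voxel-wise brain graph from a diffusion profile
#'
#' Edge weights combine an anisotropy *magnitude* term with a diffusion
#' *orientation coherence* term:
#' \deqn{a_{ij} = \frac{P(v_i) P(v_j)}{\alpha^2}
#'   \left(\frac{p(i, r_{ij})}{\beta_i} + \frac{p(j, r_{ji})}{\beta_j}\right)}
#' where `P` is the voxel anisotropy (FA for tensor-derived profiles, QA for
#' ODF-derived ones), `alpha = max_k P(v_k)` over the mask, and
#' `beta_k = 2 * max_l p(k, r_kl)` over voxel k's in-mask neighbors. Both
#' terms are bounded to \[0, 1\], hence so are the weights. The formula is
#' symmetric in i and j, so the adjacency is exactly symmetric by
#' construction.
#'
#' Voxels with zero degree (all incident weights zero, or an all-zero
#' profile making `beta_k = 0`) are dropped, then the largest connected
#' component is kept; both counts are reported via `message()` and stored.
#'
#' @param profile a [dti_profile()] or [odf_profile()] result.
#' @param anisotropy 3D anisotropy map in \[0,1\] sharing the profile's
#'   grid; defaults to the phantom map carried by the profile.
#' @param mask optional 3D logical mask; defaults to the profile's voxel
#'   set. Must not extend beyond it.
#' @param scheme neighborhood scheme; defaults to the profile's.
#' @return Object of class `brain_graph`: list with `adjacency` (sparse
#'   symmetric `dsCMatrix`), `coords` (N x 3 voxel indices, 1-based, in
#'   array scan order: x fastest), `node_volume` (3D array mapping voxels
#'   to node indices, `NA` outside the graph), `degrees`, `voxel_size`,
#'   `dim`, `labels` (tissue labels at nodes if available), `alpha`,
#'   `dropped_isolated`, `dropped_component`.
#' @export
assemble_graph <- function(profile, anisotropy = NULL, mask = NULL,
                           scheme = NULL) {
  stopifnot(inherits(profile, "diffusion_profile"))
  if (is.null(scheme)) scheme <- profile$scheme
  if (is.null(anisotropy)) anisotropy <- profile$anisotropy
  if (is.null(anisotropy)) stop("an anisotropy map is required")
  if (!all(dim(anisotropy) == profile$dim)) {
    stop("anisotropy map and profile grids differ")
  }
  if (any(anisotropy < 0 | anisotropy > 1, na.rm = TRUE)) {
    stop("anisotropy must lie in [0, 1]")
  }

  d <- profile$dim
  keep <- rep(TRUE, length(profile$mask_index))
  if (!is.null(mask)) {
    if (!all(dim(mask) == d)) stop("mask and profile grids differ")
    keep <- mask[profile$mask_index]
    if (any(mask & !array(seq_len(prod(d)) %in% profile$mask_index, d))) {
      stop("mask extends beyond the profile's voxel set")
    }
  }

  mask_index <- profile$mask_index[keep]
  values <- profile$values[keep, , drop = FALSE]
  present <- profile$present[keep, , drop = FALSE]
  n <- length(mask_index)

  pm <- anisotropy[mask_index]
  alpha <- max(pm)
  if (alpha == 0) stop("all-zero anisotropy map: alpha = 0")

  # beta_k = 2 * max over available neighbors of p(k, .)
  vmax <- apply(values, 1L, function(v) {
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  })
  beta <- 2 * vmax
  zero_beta <- beta == 0

  node_of <- array(NA_integer_, d)
  node_of[mask_index] <- seq_len(n)
  coords <- arrayInd(mask_index, d)

  # one pass per antipodal representative direction
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (k in which(scheme$is_positive)) {
    ak <- scheme$antipode[k]
    has <- which(present[, k] & !zero_beta)
    if (!length(has)) next
    nb <- sweep(coords[has, , drop = FALSE], 2L, scheme$offsets[k, ], `+`)
    j <- node_of[nb]
    ok <- !is.na(j) & !zero_beta[j]
    if (!any(ok)) next
    i <- has[ok]; j <- j[ok]
    w <- (pm[i] * pm[j] / alpha^2) *
      (values[cbind(i, k)] / beta[i] + values[cbind(j, ak)] / beta[j])
    pos <- w > 0
    ii <- c(ii, i[pos]); jj <- c(jj, j[pos]); ww <- c(ww, w[pos])
  }
  if (!length(ww)) stop("graph has no edges")

  A <- Matrix::sparseMatrix(
    i = pmin(ii, jj), j = pmax(ii, jj), x = ww, dims = c(n, n),
    symmetric = TRUE
  )
  deg <- Matrix::rowSums(A)

  # drop isolated voxels, then keep the largest connected component
  connected <- deg > 0
  dropped_isolated <- sum(!connected)
  A <- A[connected, connected, drop = FALSE]
  idx <- which(connected)

  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)
  in_big <- comp$membership == which.max(comp$csize)
  dropped_component <- sum(!in_big)
  A <- A[in_big, in_big, drop = FALSE]
  idx <- idx[in_big]

  if (dropped_isolated + dropped_component > 0) {
    message(sprintf(
      "assemble_graph: dropped %d isolated voxel(s) and %d outside the largest component",
      dropped_isolated, dropped_component
    ))
  }

  node_volume <- array(NA_integer_, d)
  node_volume[mask_index[idx]] <- seq_along(idx)
  structure(
    list(
      adjacency = methods::as(Matrix::forceSymmetric(A), "symmetricMatrix"),
      coords = coords[idx, , drop = FALSE],
      mask_index = mask_index[idx],
      node_volume = node_volume,
      degrees = Matrix::rowSums(A),
      voxel_size = profile$voxel_size,
      dim = d,
      alpha = alpha,
      dropped_isolated = dropped_isolated,
      dropped_component = dropped_component
    ),
    class = "brain_graph"
  )
}

#' Node degrees of a brain graph
#'
#' Row sums of the weighted adjacency matrix.
#'
#' @param graph a `brain_graph`.
#' @return numeric vector of length N, strictly positive.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "brain_graph"))
  as.numeric(Matrix::rowSums(graph$adjacency))
}

#' @export
#' @method print brain_graph
print.brain_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  ne <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf(
    "Voxel-wise brain graph: %d nodes, %.0f edges, weights in [%.3g, %.3g]\n",
    n, ne, min(x$adjacency@x), max(x$adjacency@x)
  ))
  if (x$dropped_isolated + x$dropped_component > 0) {
    cat(sprintf("  dropped: %d isolated, %d outside largest component\n",
                x$dropped_isolated, x$dropped_component))
  }
  invisible(x)
}

#' @export
#' @method summary brain_graph
summary.brain_graph <- function(object, ...) {
  deg <- degrees(object)
  out <- list(
    n_nodes = nrow(object$adjacency),
    n_edges = Matrix::nnzero(object$adjacency) / 2,
    degree_summary = summary(deg),
    weight_range = range(object$adjacency@x)
  )
  class(out) <- "summary.brain_graph"
  out
}

#' @export
#' @method print summary.brain_graph
print.summary.brain_graph <- function(x, ...) {
  cat(sprintf("Brain graph: %d nodes, %.0f edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  edge weights in [%.4g, %.4g]\n",
              x$weight_range[1], x$weight_range[2]))
  cat("  degrees:\n")
  print(x$degree_summary)
  invisible(x)
}

#' Plot a brain-graph degree map slice
#'
#' Scatters node degrees back to the voxel grid and shows one axial slice
#' as an image.
#'
#' @param x a `brain_graph`.
#' @param slice z index (default: middle slice).
#' @param ... passed to [graphics::image()].
#' @export
plot.brain_graph <- function(x, slice = NULL, ...) {
  vol <- array(NA_real_, x$dim)
  vol[x$mask_index] <- degrees(x)
  if (is.null(slice)) slice <- ceiling(x$dim[3] / 2)
  graphics::image(
    vol[, , slice],
    main = sprintf("node degree, slice z = %d", slice),
    useRaster = TRUE, ...
  )
  invisible(x)
}

#' Tissue labels at the graph nodes
#'
#' Looks up the phantom's tissue label (1 = GM, 2 = WM, 3 = CSF) for every
#' node of a graph built on that phantom's grid.
#'
#' @param graph a `brain_graph`.
#' @param phantom the originating `tissue_phantom`.
#' @return integer vector of length N.
#' @export
node_labels <- function(graph, phantom) {
  stopifnot(inherits(graph, "brain_graph"), inherits(phantom, "tissue_phantom"))
  phantom$labels[graph$mask_index]
}
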