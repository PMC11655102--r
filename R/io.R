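#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @return list with `data` (array), `voxel_size` (mm, first 3 pixdims)
#'   and `image` (the `niftiImage` carrying the full header/affine).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(
    data = array(as.vector(img), dim(img)),
    voxel_size = RNifti::pixdim(img)[1:3],
    image = img
  )
}

#' Write an array as a NIfTI volume
#'
#' @param data 3D or 4D array.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param voxel_size length-3 voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(data)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# grids must agree between companion volumes
check_same_grid <- function(a, b, name_a, name_b, tol = 1e-4) {
  if (!all(dim(a$data)[1:3] == dim(b$data)[1:3]) ||
      any(abs(a$voxel_size - b$voxel_size) > tol)) {
    stop(sprintf("volumes '%s' and '%s' are on different grids",
                 name_a, name_b))
  }
  invisible(TRUE)
}

#' Write phantom volumes to a directory
#'
#' Writes `labels.nii.gz`, `anisotropy.nii.gz` and, per model, either
#' `tensors.nii.gz` (4D, 6 volumes in lower-triangular order
#' Txx,Txy,Tyy,Txz,Tyz,Tzz) or `odf.nii.gz` (4D, one volume per sample
#' direction) plus `directions.txt` (whitespace-delimited N_o x 3 table).
#'
#' @param field a `tensor_field` or `odf_field`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- field$phantom
  vs <- field$voxel_size
  write_volume(ph$labels, file.path(dir, "labels.nii.gz"), vs)
  write_volume(ph$anisotropy, file.path(dir, "anisotropy.nii.gz"), vs)
  if (inherits(field, "tensor_field")) {
    arr <- array(0, c(field$dim, 6))
    for (k in 1:6) {
      vol <- array(0, field$dim)
      vol[field$mask_index] <- field$tensors[, k]
      arr[, , , k] <- vol
    }
    write_volume(arr, file.path(dir, "tensors.nii.gz"), vs)
  } else if (inherits(field, "odf_field")) {
    no <- ncol(field$amplitudes)
    arr <- array(0, c(field$dim, no))
    for (k in seq_len(no)) {
      vol <- array(0, field$dim)
      vol[field$mask_index] <- field$amplitudes[, k]
      arr[, , , k] <- vol
    }
    write_volume(arr, file.path(dir, "odf.nii.gz"), vs)
    utils::write.table(field$directions, file.path(dir, "directions.txt"),
                       row.names = FALSE, col.names = FALSE)
  } else {
    stop("`field` must be a tensor_field or odf_field")
  }
  invisible(dir)
}

#' Read a diffusion field written by [write_phantom()]
#'
#' Validates companion-volume consistency: the tensor file must hold 6
#' volumes for the DTI model, and the ODF file's number of volumes must
#' match the direction-table rows.
#'
#' @param dir directory containing the phantom files.
#' @param model `"dti"` or `"odf"`.
#' @return a `tensor_field` or `odf_field` (with a minimal phantom stub
#'   carrying labels and anisotropy).
#' @export
read_phantom <- function(dir, model = c("dti", "odf")) {
  model <- match.arg(model)
  labels <- read_volume(file.path(dir, "labels.nii.gz"))
  anis <- read_volume(file.path(dir, "anisotropy.nii.gz"))
  check_same_grid(labels, anis, "labels", "anisotropy")
  mask_index <- which(labels$data > 0)
  phantom <- structure(
    list(labels = array(as.integer(round(labels$data)), dim(labels$data)),
         anisotropy = anis$data, voxel_size = labels$voxel_size,
         bundle = NULL, seed = NA_integer_),
    class = "tissue_phantom"
  )
  if (model == "dti") {
    tens <- read_volume(file.path(dir, "tensors.nii.gz"))
    check_same_grid(labels, tens, "labels", "tensors")
    if (length(dim(tens$data)) != 4 || dim(tens$data)[4] != 6) {
      stop("tensor volume must have exactly 6 components (lower-triangular)")
    }
    tmat <- sapply(1:6, function(k) tens$data[, , , k][mask_index])
    structure(
      list(tensors = tmat, mask_index = mask_index,
           dim = dim(labels$data), voxel_size = labels$voxel_size,
           phantom = phantom),
      class = "tensor_field"
    )
  } else {
    odf <- read_volume(file.path(dir, "odf.nii.gz"))
    check_same_grid(labels, odf, "labels", "odf")
    dirs <- as.matrix(utils::read.table(file.path(dir, "directions.txt")))
    dimnames(dirs) <- NULL
    if (length(dim(odf$data)) != 4 || dim(odf$data)[4] != nrow(dirs)) {
      stop("ODF volume count does not match the direction-table rows")
    }
    amp <- sapply(seq_len(nrow(dirs)), function(k) {
      odf$data[, , , k][mask_index]
    })
    structure(
      list(amplitudes = amp, directions = dirs, mask_index = mask_index,
           dim = dim(labels$data), voxel_size = labels$voxel_size,
           phantom = phantom),
      class = "odf_field"
    )
  }
}

#' Write a brain graph to a directory
#'
#' The adjacency goes to `adjacency.mtx` (Matrix Market, symmetric real
#' coordinate), the node table to `nodes.txt` (node index and 1-based
#' voxel coordinates, in scan order), degrees to `degrees.txt`, and grid
#' metadata to `meta.json`.
#'
#' @param graph a `brain_graph`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "brain_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(graph$adjacency, file.path(dir, "adjacency.mtx"))
  nodes <- data.frame(node = seq_len(nrow(graph$coords)),
                      x = graph$coords[, 1], y = graph$coords[, 2],
                      z = graph$coords[, 3])
  utils::write.table(nodes, file.path(dir, "nodes.txt"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(degree = graph$degrees),
                     file.path(dir, "degrees.txt"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(dim = graph$dim, voxel_size = graph$voxel_size,
         alpha = graph$alpha,
         dropped_isolated = graph$dropped_isolated,
         dropped_component = graph$dropped_component),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a brain graph written by [write_graph()]
#'
#' @param dir directory containing `adjacency.mtx`, `nodes.txt`,
#'   `meta.json`.
#' @return a `brain_graph`.
#' @export
read_graph <- function(dir) {
  A <- Matrix::readMM(file.path(dir, "adjacency.mtx"))
  if (!methods::is(A, "symmetricMatrix")) {
    if (!Matrix::isSymmetric(A)) {
      stop("adjacency.mtx is not marked symmetric and is not symmetric")
    }
    A <- Matrix::forceSymmetric(A)
  }
  A <- methods::as(A, "CsparseMatrix")
  nodes <- utils::read.table(file.path(dir, "nodes.txt"), header = TRUE)
  if (nrow(nodes) != nrow(A)) {
    stop("node table row count does not match adjacency dimension")
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  mask_index <- coords[, 1] + d[1] * (coords[, 2] - 1) +
    d[1] * d[2] * (coords[, 3] - 1)
  node_volume <- array(NA_integer_, d)
  node_volume[mask_index] <- seq_len(nrow(coords))
  structure(
    list(adjacency = A, coords = coords, mask_index = mask_index,
         node_volume = node_volume, degrees = Matrix::rowSums(A),
         voxel_size = as.numeric(meta$voxel_size), dim = d,
         alpha = meta$alpha,
         dropped_isolated = meta$dropped_isolated,
         dropped_component = meta$dropped_component),
    class = "brain_graph"
  )
}

#' Write a spectral decomposition to a directory
#'
#' Eigenvalues go to `eigenvalues.txt`; eigenvectors both to a dense
#' whitespace table `eigenvectors.txt` (N x C) and to `eigenmodes.nii.gz`
#' (4D, one volume per mode, node values scattered to their voxels, zeros
#' outside the graph).
#'
#' @param decomp a `spectral_decomposition` whose `graph` is set.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_spectrum <- function(decomp, dir) {
  stopifnot(inherits(decomp, "spectral_decomposition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(eigenvalue = decomp$values),
                     file.path(dir, "eigenvalues.txt"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(decomp$vectors, file.path(dir, "eigenvectors.txt"),
                     row.names = FALSE, col.names = FALSE)
  g <- decomp$graph
  if (!is.null(g)) {
    arr <- array(0, c(g$dim, decomp$C))
    for (k in seq_len(decomp$C)) {
      vol <- array(0, g$dim)
      vol[g$mask_index] <- decomp$vectors[, k]
      arr[, , , k] <- vol
    }
    write_volume(arr, file.path(dir, "eigenmodes.nii.gz"), g$voxel_size)
  }
  invisible(dir)
}

#' Read eigenmodes written by [write_spectrum()]
#'
#' @param dir directory with `eigenvalues.txt` and `eigenvectors.txt`.
#' @return list with `values` and `vectors`.
#' @export
read_spectrum <- function(dir) {
  values <- utils::read.table(file.path(dir, "eigenvalues.txt"),
                              header = TRUE)$eigenvalue
  vectors <- as.matrix(utils::read.table(file.path(dir, "eigenvectors.txt")))
  dimnames(vectors) <- NULL
  list(values = values, vectors = vectors)
}

#' Write an energy spectrum as a plain-text table
#'
#' @param spectrum an `energy_spectrum`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  utils::write.table(
    data.frame(index = spectrum$index, eesd = spectrum$eesd,
               cumulative = spectrum$cumulative),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Extract graph signals from a 4D volume
#'
#' Pulls, for each time frame, the values at the graph's voxels in node
#' (scan) order, yielding one graph signal per frame.
#'
#' @param data 4D array sharing the graph's grid.
#' @param graph a `brain_graph`.
#' @return a `graph_signal_set`.
#' @export
volume_to_signals <- function(data, graph) {
  stopifnot(inherits(graph, "brain_graph"))
  d <- dim(data)
  if (length(d) != 4 || !all(d[1:3] == graph$dim)) {
    stop("signal volume does not share the graph's grid")
  }
  S <- d[4]
  X <- matrix(0, nrow(graph$coords), S)
  for (k in seq_len(S)) {
    vol <- data[, , , k]
    X[, k] <- vol[graph$mask_index]
  }
  structure(list(signals = X, frame_count = S), class = "graph_signal_set")
}
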