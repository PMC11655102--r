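#' Moore-neighborhood connectivity schemes
#'
#' Builds the lattice neighborhood used to connect voxels: either the full
#' 3x3x3 Moore neighborhood (26 directions) or the 5x5x5 neighborhood with
#' parallel outer offsets excluded (98 directions). Each retained lattice
#' offset carries a unit direction in physical (mm) space and an equal share
#' of the sphere's solid angle, `4*pi/26` or `4*pi/98` steradians.
#'
#' An outer-shell offset is "parallel" to an inner offset when it is a
#' positive integer multiple of it; those 26 offsets (twice each inner
#' offset) duplicate directions already encoded by the inner shell and are
#' excluded, so the 5-scheme keeps 26 inner + 72 outer = 98 offsets.
#'
#' @param connectivity 3 or 5.
#' @param voxel_size positive length-3 numeric, voxel edge lengths in mm.
#'   Directions are computed on the physical grid (`offset * voxel_size`,
#'   then normalized), so anisotropic voxels skew the direction set while
#'   lattice adjacency itself is unaffected.
#' @return An object of class `neighborhood_scheme`: a list with elements
#'   `connectivity`, `voxel_size`, `offsets` (n x 3 integer matrix),
#'   `directions` (n x 3 unit rows), `displacements` (n x 3, mm),
#'   `solid_angle` (steradians per direction), `antipode` (index of the
#'   opposite offset for each row) and `is_positive` (one representative per
#'   antipodal pair, for iterating over undirected edge directions).
#' @examples
#' sch <- build_scheme(3)
#' nrow(sch$offsets)  # 26
#' sch5 <- build_scheme(5)
#' nrow(sch5$offsets) # 98
#' @export
build_scheme <- function(connectivity, voxel_size = c(1, 1, 1)) {
  if (!(length(connectivity) == 1L && connectivity %in% c(3, 5))) {
    stop("`connectivity` must be 3 or 5")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive numbers")
  }

  inner <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  inner <- inner[rowSums(abs(inner)) > 0, , drop = FALSE]

  if (connectivity == 3) {
    offsets <- inner
  } else {
    all5 <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -2:2))
    cheb <- apply(abs(all5), 1L, max)
    outer <- all5[cheb == 2L, , drop = FALSE]
    # outer offsets of the form 2 * (inner offset) are parallel: exclude
    parallel <- outer %% 2L == 0L
    is_parallel <- rowSums(parallel) == 3L
    offsets <- rbind(inner, outer[!is_parallel, , drop = FALSE])
  }
  dimnames(offsets) <- NULL
  storage.mode(offsets) <- "integer"

  displacements <- sweep(offsets, 2L, voxel_size, `*`)
  directions <- displacements / sqrt(rowSums(displacements^2))

  n <- nrow(offsets)
  # index of -offset for each offset (antipodal closure is structural)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  antipode <- match(key(-offsets), key(offsets))
  stopifnot(!anyNA(antipode), all(antipode[antipode] == seq_len(n)))

  # one representative per antipodal pair: first nonzero component positive
  first_nonzero <- apply(offsets, 1L, function(o) o[o != 0][1])
  is_positive <- first_nonzero > 0

  structure(
    list(
      connectivity = as.integer(connectivity),
      voxel_size = voxel_size,
      offsets = offsets,
      directions = directions,
      displacements = displacements,
      solid_angle = 4 * pi / n,
      antipode = antipode,
      is_positive = is_positive
    ),
    class = "neighborhood_scheme"
  )
}

#' @export
#' @method print neighborhood_scheme
print.neighborhood_scheme <- function(x, ...) {
  cat(sprintf(
    "Moore neighborhood scheme: %d-connectivity, %d directions\n",
    x$connectivity, nrow(x$offsets)
  ))
  cat(sprintf(
    "  voxel size: %s mm; solid angle per direction: 4*pi/%d = %.5f sr\n",
    paste(format(x$voxel_size), collapse = " x "),
    nrow(x$offsets), x$solid_angle
  ))
  invisible(x)
}

#' Export a neighborhood scheme as a plain-text table
#'
#' Writes one row per direction: integer lattice offset, unit direction in
#' physical space, and the solid angle, whitespace-delimited.
#'
#' @param scheme a [build_scheme()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scheme_table <- function(scheme, path) {
  stopifnot(inherits(scheme, "neighborhood_scheme"))
  tab <- data.frame(
    ox = scheme$offsets[, 1], oy = scheme$offsets[, 2],
    oz = scheme$offsets[, 3],
    dx = scheme$directions[, 1], dy = scheme$directions[, 2],
    dz = scheme$directions[, 3],
    solid_angle = scheme$solid_angle
  )
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
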