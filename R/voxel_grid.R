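#' Isotropic voxel grid over an MNI-style bounding box
#'
#' A `voxel_grid` describes a regular, isotropic grid of voxel centers in
#' MNI millimeter space. Voxel indices are 1-based; the grid `origin` is the
#' mm coordinate of the center of voxel (1, 1, 1), so the center of voxel
#' `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`. The inverse
#' mapping (mm to voxel) rounds to the nearest center and round-trips
#' exactly at voxel centers.
#'
#' The default box (-90..90, -126..90, -72..108 mm at 4 mm spacing) covers
#' the standard MNI brain with a margin, which is the working resolution for
#' the meta-analytic maps; 2 mm is available by setting `spacing = 2`.
#'
#' @param spacing voxel size in mm (isotropic), > 0.
#' @param xlim,ylim,zlim mm limits of voxel centers along each axis
#'   (`lim[1]` is the first center; the last center is the largest
#'   `lim[1] + k * spacing` not exceeding `lim[2]`).
#' @return An object of class `voxel_grid` with fields `shape` (integer
#'   triple), `spacing`, and `origin` (mm triple).
#' @examples
#' g <- voxel_grid()
#' g$shape
#' @export
voxel_grid <- function(spacing = 4,
                       xlim = c(-90, 90),
                       ylim = c(-126, 90),
                       zlim = c(-72, 108)) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  lims <- list(xlim, ylim, zlim)
  for (l in lims) stopifnot(length(l) == 2L, l[2] >= l[1])
  shape <- vapply(lims, function(l) floor((l[2] - l[1]) / spacing) + 1L, 1)
  g <- structure(
    list(
      shape = as.integer(shape),
      spacing = as.numeric(spacing),
      origin = as.numeric(c(xlim[1], ylim[1], zlim[1]))
    ),
    class = "voxel_grid"
  )
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  hi <- grid_upper(x)
  cat(sprintf(
    "voxel_grid: %d x %d x %d voxels, %.3g mm spacing\n  x: %g..%g  y: %g..%g  z: %g..%g (mm, voxel centers)\n",
    x$shape[1], x$shape[2], x$shape[3], x$spacing,
    x$origin[1], hi[1], x$origin[2], hi[2], x$origin[3], hi[3]
  ))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

# mm coordinate of the last voxel center on each axis
grid_upper <- function(grid) grid$origin + (grid$shape - 1L) * grid$spacing

#' Convert voxel indices to mm coordinates of voxel centers
#'
#' @param grid a [voxel_grid()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices, or a length-3
#'   vector.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_mm <- function(grid, idx) {
  idx <- to_coord_matrix(idx)
  sweep(sweep(idx - 1, 2, rep(grid$spacing, 3), "*"), 2, grid$origin, "+")
}

#' Convert mm coordinates to nearest-voxel indices
#'
#' Rounds through the inverse of the grid's affine: each coordinate maps to
#' the voxel whose center is nearest (ties round half up via `round`).
#'
#' @param grid a [voxel_grid()].
#' @param mm numeric matrix (n x 3) of mm coordinates, or a length-3 vector.
#' @param clamp if `TRUE`, indices are clamped into the grid; if `FALSE`
#'   (default), out-of-grid coordinates yield `NA` rows.
#' @return integer matrix (n x 3) of voxel indices (1-based).
#' @export
mm_to_voxel <- function(grid, mm, clamp = FALSE) {
  mm <- to_coord_matrix(mm)
  idx <- round(sweep(mm, 2, grid$origin, "-") / grid$spacing) + 1
  if (clamp) {
    for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), grid$shape[a])
  } else {
    bad <- idx[, 1] < 1 | idx[, 1] > grid$shape[1] |
      idx[, 2] < 1 | idx[, 2] > grid$shape[2] |
      idx[, 3] < 1 | idx[, 3] > grid$shape[3]
    idx[bad, ] <- NA_real_
  }
  storage.mode(idx) <- "integer"
  idx
}

# linear (column-major) index of voxel triples
voxel_linear_index <- function(grid, idx) {
  idx <- to_coord_matrix(idx)
  as.integer(idx[, 1] + (idx[, 2] - 1L) * grid$shape[1] +
    (idx[, 3] - 1L) * prod(grid$shape[1:2]))
}

# inverse of voxel_linear_index
linear_to_voxel <- function(grid, lin) {
  nx <- grid$shape[1]; nxy <- prod(grid$shape[1:2])
  lin0 <- lin - 1L
  cbind(
    lin0 %% nx + 1L,
    (lin0 %/% nx) %% grid$shape[2] + 1L,
    lin0 %/% nxy + 1L
  )
}

# Is each mm point inside the closed bounding box of voxel centers
# (expanded by half a voxel so every point that snaps to a voxel counts)?
inside_grid <- function(grid, mm) {
  mm <- to_coord_matrix(mm)
  hi <- grid_upper(grid)
  h <- grid$spacing / 2
  ok <- rep(TRUE, nrow(mm))
  for (a in 1:3) {
    ok <- ok & mm[, a] >= grid$origin[a] - h & mm[, a] <= hi[a] + h
  }
  ok
}

to_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 3L)
    storage.mode(x) <- "double"
  }
  x
}
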