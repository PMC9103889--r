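# Voxel lattice data structure and the generic grid operations shared by all
# occupancy-map computations.

#' Create an axis-aligned voxel grid
#'
#' A `grid3d` is an axis-aligned cubic-voxel lattice holding one real value
#' per voxel.  Voxel `(i, j, k)` (1-based indices) covers the half-open box
#' `origin + (index - 1) * spacing` (inclusive) to `origin + index * spacing`
#' (exclusive), so a point on a shared face belongs to the higher-index voxel.
#'
#' @param origin Numeric 3-vector, the coordinate (in Angstrom) of the minimum
#'   corner of voxel `(1, 1, 1)`.
#' @param shape Integer 3-vector `(nx, ny, nz)`, all components >= 1.
#' @param spacing Voxel edge length in Angstrom (default 1).
#' @return An object of class `grid3d` with fields `origin`, `shape`,
#'   `spacing` and `values` (a `shape`-dimensional array of zeros).
#' @examples
#' g <- grid3d(c(0, 0, 0), c(10, 10, 10))
#' sum(g$values)
#' @export
grid3d <- function(origin, shape, spacing = 1.0) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_config("'origin' must be a finite numeric 3-vector")
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop_config("'shape' must be a numeric 3-vector")
  shape_i <- as.integer(round(shape))
  if (any(abs(shape - shape_i) > 1e-8) || any(shape_i < 1L))
    stop_config("'shape' components must be positive integers")
  check_scalar_number(spacing, "spacing", positive = TRUE)
  structure(
    list(origin = origin, shape = shape_i, spacing = as.numeric(spacing),
         values = array(0, dim = shape_i)),
    class = "grid3d"
  )
}

is_grid3d <- function(x) inherits(x, "grid3d")

assert_grid <- function(grid, what = "grid") {
  if (!is_grid3d(grid)) stop_config("'%s' must be a grid3d object", what)
  if (any(!is.finite(grid$values)))
    stop_data("'%s' holds non-finite voxel values", what)
  invisible(grid)
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %d x %d x %d voxels, spacing %g A, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  values: sum %g, max %g\n", sum(x$values), max(x$values)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    abs(a$spacing - b$spacing) <= tol * max(1, abs(a$spacing)) &&
    all(abs(a$origin - b$origin) <= tol * pmax(1, abs(a$origin)))
}

#' Voxel index of each point
#'
#' Maps Cartesian points to 1-based voxel indices under the floor / half-open
#' ownership convention.  Out-of-bounds points get `NA` indices.
#'
#' @param grid A [grid3d()].
#' @param points An `n x 3` matrix (or data frame with `x`, `y`, `z` columns).
#' @return An integer `n x 3` matrix of voxel indices; rows of `NA` mark
#'   points outside the grid.
#' @export
voxel_of <- function(grid, points) {
  assert_grid(grid)
  points <- as_points(points)
  if (nrow(points) == 0L)
    return(matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("i", "j", "k"))))
  rel <- sweep(points, 2L, grid$origin, "-") / grid$spacing
  idx <- floor(rel) + 1
  oob <- idx[, 1] < 1 | idx[, 2] < 1 | idx[, 3] < 1 |
    idx[, 1] > grid$shape[1] | idx[, 2] > grid$shape[2] | idx[, 3] > grid$shape[3]
  idx[oob, ] <- NA_real_
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}

# Coordinates of all voxel centers along one axis.
axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing
}

#' Coordinates of voxel centers
#'
#' @param grid A [grid3d()].
#' @param index Optional integer `n x 3` matrix of voxel indices (1-based);
#'   when omitted, centers of all voxels are returned in array order
#'   (first index fastest).
#' @return A numeric `n x 3` matrix of center coordinates.
#' @export
voxel_centers <- function(grid, index = NULL) {
  assert_grid(grid)
  if (is.null(index)) {
    index <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                                   j = seq_len(grid$shape[2]),
                                   k = seq_len(grid$shape[3])))
  }
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep((index - 0.5) * grid$spacing, 2L, grid$origin, "+")
}

#' Bin points into a grid
#'
#' Each in-bounds point adds one count to the voxel that contains it; points
#' outside the grid are counted but do not raise an error (probes legitimately
#' leave the analysis region).  Counts accumulate on top of the grid's current
#' values.
#'
#' @inheritParams voxel_of
#' @return The updated grid.  The number of out-of-bounds points is attached
#'   as attribute `"out_of_bounds"`.
#' @export
bin_points <- function(grid, points) {
  assert_grid(grid)
  points <- as_points(points)
  idx <- voxel_of(grid, points)
  ok <- !is.na(idx[, 1L])
  n_oob <- sum(!ok)
  if (any(ok)) {
    nx <- grid$shape[1]; ny <- grid$shape[2]
    lin <- idx[ok, 1L] + nx * (idx[ok, 2L] - 1L) + nx * ny * (idx[ok, 3L] - 1L)
    counts <- tabulate(lin, nbins = prod(grid$shape))
    grid$values <- grid$values + array(counts, dim = grid$shape)
  }
  attr(grid, "out_of_bounds") <- n_oob
  grid
}

#' Mask of voxels near a set of reference points
#'
#' A voxel is a member iff the distance from its *center* to the nearest
#' reference point is `<= cutoff` (inclusive).  This realises the surface
#' shell "voxels within 5 Angstrom of the protein atoms".
#'
#' @param grid A [grid3d()] providing the geometry.
#' @param reference_points Non-empty `n x 3` matrix of reference coordinates.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return An object of class `voxel_mask` with fields `member` (logical array
#'   matching the grid shape), `shape`, `origin`, `spacing` and `cutoff`.
#' @export
mask_within_distance <- function(grid, reference_points, cutoff) {
  assert_grid(grid)
  reference_points <- as_points(reference_points, allow_empty = FALSE,
                                what = "reference_points")
  check_scalar_number(cutoff, "cutoff", positive = TRUE)
  member <- array(FALSE, dim = grid$shape)
  cx <- axis_centers(grid, 1L)
  cy <- axis_centers(grid, 2L)
  cz <- axis_centers(grid, 3L)
  cut2 <- cutoff^2
  for (p in seq_len(nrow(reference_points))) {
    pt <- reference_points[p, ]
    ix <- which(abs(cx - pt[1]) <= cutoff)
    iy <- which(abs(cy - pt[2]) <= cutoff)
    iz <- which(abs(cz - pt[3]) <= cutoff)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (cx[ix] - pt[1])^2
    dy2 <- (cy[iy] - pt[2])^2
    dz2 <- (cz[iz] - pt[3])^2
    sub <- outer(outer(dx2, dy2, "+"), dz2, "+") <= cut2
    member[ix, iy, iz] <- member[ix, iy, iz, drop = FALSE] | sub
  }
  structure(
    list(member = member, shape = grid$shape, origin = grid$origin,
         spacing = grid$spacing, cutoff = as.numeric(cutoff)),
    class = "voxel_mask"
  )
}

assert_mask <- function(mask, grid = NULL) {
  if (!inherits(mask, "voxel_mask")) stop_config("'mask' must be a voxel_mask")
  if (!is.null(grid) && !identical(mask$shape, grid$shape))
    stop_data("mask shape (%s) does not match grid shape (%s)",
              paste(mask$shape, collapse = "x"),
              paste(grid$shape, collapse = "x"))
  invisible(mask)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("voxel_mask: %d member voxels of %d (cutoff %g A)\n",
              sum(x$member), prod(x$shape), x$cutoff %||% NA))
  invisible(x)
}

#' Restrict a grid to a mask and normalize to unit sum
#'
#' Values outside the mask are discarded (set to zero) and the remaining
#' values are scaled so that the sum over member voxels equals 1.0.  This is
#' the restrict-and-scale step that turns a raw occupancy count grid into a
#' probability map.
#'
#' @param grid A non-negative [grid3d()].
#' @param mask A [mask_within_distance()] result with matching shape.
#' @return The normalized grid.
#' @export
normalize_masked <- function(grid, mask) {
  assert_grid(grid)
  assert_mask(mask, grid)
  if (any(grid$values < 0)) stop_data("grid values must be non-negative")
  vals <- grid$values
  vals[!mask$member] <- 0
  total <- sum(vals)
  if (total <= 0)
    stop_data(paste0("degenerate normalization: all masked voxel values are ",
                     "zero (no probe presence on the surface shell)"))
  grid$values <- vals / total
  grid
}

#' Voxelwise maximum of several grids
#'
#' @param grids A list of [grid3d()] objects sharing origin, shape and
#'   spacing.
#' @return A grid whose every voxel holds the maximum of that voxel's value
#'   across the inputs.
#' @export
voxelwise_max <- function(grids) {
  if (is_grid3d(grids)) grids <- list(grids)
  if (!is.list(grids) || length(grids) < 1L)
    stop_config("'grids' must be a non-empty list of grid3d objects")
  lapply(grids, assert_grid)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!same_geometry(ref, g))
      stop_data("geometry mismatch among input grids (origin/shape/spacing)")
  }
  out <- ref
  out$values <- Reduce(pmax, lapply(grids, `[[`, "values"))
  out
}

#' Voxels with value at or above a threshold
#'
#' The comparison is inclusive (`>= theta`), matching the "equal to or
#' greater than" surface definition, and is therefore antitone in `theta`.
#'
#' @param grid A [grid3d()].
#' @param theta Finite threshold.
#' @return A data frame with columns `i`, `j`, `k` (1-based voxel indices)
#'   and `value`.
#' @export
threshold_voxels <- function(grid, theta) {
  assert_grid(grid)
  check_scalar_number(theta, "theta")
  sel <- which(grid$values >= theta, arr.ind = TRUE)
  out <- data.frame(i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
                    k = as.integer(sel[, 3]))
  out$value <- grid$values[sel]
  out
}

#' Grid geometry covering a point cloud
#'
#' Builds an all-zero grid whose extent is the bounding box of `points` plus
#' a margin.  By default the origin is snapped down to the integer-spacing
#' lattice so voxel boundaries fall on multiples of `spacing`; this makes
#' voxel assignment independent of sub-voxel shifts of the bounding box.
#'
#' @param points `n x 3` matrix of coordinates the grid must cover.
#' @param margin Margin in Angstrom added on every side (default 8).
#' @param spacing Voxel size in Angstrom (default 1).
#' @param snap Snap the origin down to the `spacing` lattice (default TRUE).
#' @return An all-zero [grid3d()].
#' @export
grid_from_points <- function(points, margin = 8, spacing = 1, snap = TRUE) {
  points <- as_points(points, allow_empty = FALSE)
  check_scalar_number(margin, "margin")
  check_scalar_number(spacing, "spacing", positive = TRUE)
  lo <- apply(points, 2L, min) - margin
  hi <- apply(points, 2L, max) + margin
  if (snap) lo <- floor(lo / spacing) * spacing
  shape <- pmax(1, ceiling((hi - lo) / spacing - 1e-9))
  grid3d(lo, shape, spacing)
}
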