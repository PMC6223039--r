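#' Voxel grid geometry
#'
#' A `grid_spec` records the voxel-grid geometry shared by all channels of a
#' scene: the number of voxels per axis and the physical voxel size per axis,
#' in micrometres. Axis order is (z, y, x) throughout the package, matching
#' the acquisition order of a confocal z-stack; anisotropic spacing (axial
#' step larger than lateral pixel size, e.g. 0.5 um z-intervals) is the
#' normal case.
#'
#' @param shape integer vector of length 3: voxel counts per axis (z, y, x).
#' @param spacing numeric vector of length 3: physical voxel size per axis
#'   (dz, dy, dx) in micrometres.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(20, 64, 64), c(0.5, 0.25, 0.25))
#' voxel_volume(g)   # 0.03125 um^3
#' @export
grid_spec <- function(shape, spacing) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, length(spacing) == 3L)
  if (any(shape < 1L)) stop("all voxel counts must be >= 1")
  if (any(spacing <= 0)) stop("all voxel spacings must be > 0")
  structure(list(shape = shape, spacing = spacing), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels (z,y,x), spacing %.4g x %.4g x %.4g um\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Physical volume of one voxel
#'
#' @param grid a [grid_spec()].
#' @return Voxel volume in cubic micrometres (dz * dy * dx).
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  prod(grid$spacing)
}

# Physical coordinates of voxel centres along one axis (1-based index i maps
# to (i - 0.5) * spacing).
axis_coords <- function(grid, axis) {
  (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

# n x 3 matrix of physical centre coordinates for the given voxel indices
# (n x 3 integer matrix, (z, y, x), 1-based).
voxel_centers <- function(idx, grid) {
  sweep(idx - 0.5, 2, grid$spacing, "*")
}

# Integer (z,y,x) index matrix for the TRUE voxels of a 3D logical array.
which_idx3 <- function(mask) {
  w <- which(mask)
  d <- dim(mask)
  z <- (w - 1L) %% d[1] + 1L
  y <- ((w - 1L) %/% d[1]) %% d[2] + 1L
  x <- (w - 1L) %/% (d[1] * d[2]) + 1L
  cbind(z = z, y = y, x = x)
}

#' Nuclear mask container
#'
#' Binds a binary 3D mask to its grid geometry. All morphometry is computed
#' from such masks. The mask must be a single nonempty connected component.
#'
#' @param mask logical 3D array (z, y, x).
#' @param grid a [grid_spec()] with matching shape.
#' @param cell_id optional identifier carried through to reports.
#' @param check if `TRUE` (default) verify single-component connectivity.
#' @return An object of class `nuclear_mask`.
#' @export
nuclear_mask <- function(mask, grid, cell_id = NA_character_, check = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.logical(mask)) mask <- mask > 0
  dim(mask) <- dim(mask)  # keep array
  if (!identical(dim(mask), as.integer(grid$shape)))
    stop("mask shape does not match grid shape")
  if (!any(mask)) stop("mask is empty")
  if (check) {
    lab <- label_components(mask, connectivity = 26L)
    if (max(lab) != 1L) stop("mask must be a single connected component")
  }
  structure(list(mask = mask, grid = grid, cell_id = cell_id),
            class = "nuclear_mask")
}

#' @export
print.nuclear_mask <- function(x, ...) {
  cat(sprintf("nuclear_mask '%s': %d voxels, %.2f um^3\n",
              x$cell_id, sum(x$mask), sum(x$mask) * voxel_volume(x$grid)))
  invisible(x)
}

#' Multi-channel volume container
#'
#' A set of 3D intensity arrays sharing one grid, with named channels. This is
#' the unit of microscopy input consumed by segmentation and all downstream
#' measurements.
#'
#' @param data named list of numeric 3D arrays, all of the grid's shape.
#' @param grid a [grid_spec()].
#' @return An object of class `multichannel_volume`.
#' @export
multichannel_volume <- function(data, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.list(data), length(data) >= 1)
  if (is.null(names(data)) || any(names(data) == ""))
    stop("all channels must be named")
  for (nm in names(data)) {
    if (!identical(dim(data[[nm]]), as.integer(grid$shape)))
      stop(sprintf("channel '%s' does not match the grid shape", nm))
    if (any(data[[nm]] < 0)) stop(sprintf("channel '%s' has negative intensities", nm))
  }
  structure(list(data = data, grid = grid, channels = names(data)),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  cat(sprintf("multichannel_volume: channels [%s], %d x %d x %d voxels\n",
              paste(x$channels, collapse = ", "),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}
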