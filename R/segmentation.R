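#' Segment the nucleus from a DAPI channel
#'
#' Gaussian smoothing, global Otsu threshold, watershed splitting of touching
#' components (seeded from smoothed distance-transform maxima), morphological
#' closing and hole filling, then retention of the largest object -- the
#' standard workflow for building a coherent binary nuclear mask from a DAPI
#' z-stack. One nucleus per field is assumed; in multi-object fields the
#' largest object wins, with ties broken by the lowest (z, y, x) centroid.
#'
#' @param dapi numeric 3D intensity array (z, y, x).
#' @param grid the [grid_spec()] of the array.
#' @param smooth_sigma Gaussian smoothing sigma in um (default 0.25).
#' @param threshold threshold rule; currently `"otsu"`.
#' @param min_volume minimum nucleus volume in um^3 (default 20); smaller
#'   results raise an error.
#' @param close_radius radius (um) of the morphological closing ball.
#' @param seed_separation minimum physical separation (um) between watershed
#'   seeds (default 0.5).
#' @param cell_id identifier attached to the returned mask.
#' @return A [nuclear_mask()].
#' @examples
#' g <- grid_spec(c(32, 32, 32), c(0.25, 0.25, 0.25))
#' sc <- render_scene(scene_config(g, nucleus_shape_params(radius = 2),
#'                                 noise = list(gain = 0, read_sd = 0),
#'                                 channel_names = "dapi"), seed = 1)
#' m <- segment_nucleus(sc$data$dapi, g)
#' @export
segment_nucleus <- function(dapi, grid, smooth_sigma = 0.25,
                            threshold = "otsu", min_volume = 20,
                            close_radius = 0.3, seed_separation = 0.5,
                            cell_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  dapi <- array(as.numeric(dapi), grid$shape)
  if (max(dapi) <= min(dapi)) stop("no nucleus found: constant intensity image")
  sm <- gauss_blur(dapi, grid, smooth_sigma)
  thr <- switch(match.arg(threshold, "otsu"), otsu = otsu_threshold(sm))
  fg <- sm > thr
  if (!any(fg)) stop("no nucleus found: nothing above threshold")

  # watershed split of touching components on the distance transform
  dt <- distance_to_background(fg, grid)
  dts <- gauss_blur(dt, grid, max(grid$spacing))
  seeds <- .watershed_seeds(dts, fg, grid, seed_separation)
  if (max(seeds) > 1L) {
    lab <- cpp_watershed(as.numeric(dt), as.integer(seeds),
                         as.logical(fg), as.integer(grid$shape))
    dim(lab) <- grid$shape
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      cents <- t(vapply(best, function(l) colMeans(which_idx3(lab == l)),
                        numeric(3)))
      best <- best[do.call(order, as.data.frame(cents))[1]]
    }
    fg <- lab == best[1]
  }

  fg <- morph_close(fg, grid, close_radius)
  fg <- fill_holes(fg)
  fg <- largest_component(fg)
  vol <- sum(fg) * voxel_volume(grid)
  if (vol < min_volume)
    stop(sprintf("no nucleus found: largest object (%.2f um^3) below min_volume (%g um^3)",
                 vol, min_volume))
  nuclear_mask(fg, grid, cell_id = cell_id, check = FALSE)
}

# Watershed seed markers: local maxima (26-neighborhood) of the smoothed
# distance transform, thinned so kept seeds are at least sep_um apart
# (greedy, strongest first; ties by scan order).
.watershed_seeds <- function(dts, fg, grid, sep_um) {
  d <- dim(dts)
  is_max <- fg
  for (cz in -1:1) for (cy in -1:1) for (cx in -1:1) {
    if (cz == 0 && cy == 0 && cx == 0) next
    shifted <- array(-Inf, d)
    zi <- seq_len(d[1]) + cz; yi <- seq_len(d[2]) + cy; xi <- seq_len(d[3]) + cx
    okz <- zi >= 1 & zi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okx <- xi >= 1 & xi <= d[3]
    shifted[okz, oky, okx] <- dts[zi[okz], yi[oky], xi[okx]]
    is_max <- is_max & (dts >= shifted)
    if (!any(is_max)) break
  }
  idx <- which_idx3(is_max & fg & dts > 0)
  if (nrow(idx) == 0L) return(array(0L, d))
  val <- dts[idx]
  ord <- order(-val, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  pos <- voxel_centers(idx, grid)
  keep <- integer(0)
  for (i in seq_len(nrow(pos))) {
    if (length(keep) == 0L) { keep <- i; next }
    dmin <- min(sqrt(rowSums(sweep(pos[keep, , drop = FALSE], 2, pos[i, ])^2)))
    if (dmin >= sep_um) keep <- c(keep, i)
  }
  seeds <- array(0L, d)
  for (j in seq_along(keep))
    seeds[idx[keep[j], 1], idx[keep[j], 2], idx[keep[j], 3]] <- j
  seeds
}

#' Detect chromosome territories in a paint channel
#'
#' Thresholds the paint channel within the nucleus (Otsu on the within-mask
#' intensities), labels 26-connected components, drops objects below
#' `min_volume`, and returns up to `max_objects` territories ordered by
#' descending volume. Homolog pairs closer than the PSF scale merge into a
#' single object -- the expected behavior for tightly apposed homologs, not
#' a failure.
#'
#' @param paint numeric 3D intensity array on the nucleus grid.
#' @param nucleus a [nuclear_mask()].
#' @param threshold threshold rule; currently `"otsu"`.
#' @param min_volume minimum territory volume in um^3 (default 0.5).
#' @param max_objects maximum number of territories kept (default 2).
#' @param channel_name label recorded on the returned territories.
#' @return A list of `territory` objects (possibly empty), ordered by
#'   descending volume.
#' @export
detect_territories <- function(paint, nucleus, threshold = "otsu",
                               min_volume = 0.5, max_objects = 2L,
                               channel_name = "paint") {
  stopifnot(inherits(nucleus, "nuclear_mask"))
  grid <- nucleus$grid
  paint <- array(as.numeric(paint), grid$shape)
  inside <- paint[nucleus$mask]
  if (length(inside) == 0L || max(inside) <= min(inside)) return(list())
  thr <- switch(match.arg(threshold, "otsu"), otsu = otsu_threshold(inside))
  fg <- nucleus$mask & paint > thr
  if (!any(fg)) return(list())
  lab <- label_components(fg, connectivity = 26L)
  k <- max(lab)
  vv <- voxel_volume(grid)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(sizes * vv >= min_volume)
  if (length(keep) == 0L) return(list())
  keep <- keep[order(-sizes[keep])]
  keep <- head(keep, max_objects)
  lapply(keep, function(l) {
    idx <- which_idx3(lab == l)
    territory(idx, grid, channel_name = channel_name)
  })
}

#' Territory object
#'
#' A connected chromosome-paint object: its voxel set, centroid (unweighted
#' mean of voxel centres, physical units) and voxel-coverage volume.
#'
#' @param voxels n x 3 integer matrix of (z, y, x) voxel indices (1-based).
#' @param grid the [grid_spec()].
#' @param channel_name label of the originating channel.
#' @return An object of class `territory`.
#' @export
territory <- function(voxels, grid, channel_name = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("z", "y", "x")))
  if (nrow(voxels) == 0L) stop("territory voxel set is empty")
  structure(list(voxels = voxels, grid = grid,
                 centroid = colMeans(voxel_centers(voxels, grid)),
                 volume = nrow(voxels) * voxel_volume(grid),
                 channel_name = channel_name),
            class = "territory")
}

#' @export
print.territory <- function(x, ...) {
  cat(sprintf("territory: %d voxels, %.3f um^3, centroid (%.2f, %.2f, %.2f) um\n",
              nrow(x$voxels), x$volume, x$centroid[1], x$centroid[2],
              x$centroid[3]))
  invisible(x)
}
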