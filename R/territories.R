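# Homolog centroid distances, proximity classification, and mark--territory
# co-localization volume.

#' Territory centroid
#'
#' Unweighted mean of the voxel centres of a territory, in physical
#' micrometre coordinates per axis (z, y, x). A voxel with 1-based index
#' (k, j, i) has centre ((k - 0.5) dz, (j - 0.5) dy, (i - 0.5) dx).
#'
#' @param t a [territory()].
#' @return Numeric length-3 centroid (z, y, x) in um.
#' @export
centroid <- function(t) {
  stopifnot(inherits(t, "territory"))
  t$centroid
}

#' Centroid-to-centroid homolog distance
#'
#' Euclidean distance between two territory centroids in physical units.
#'
#' @param t1,t2 [territory()] objects.
#' @return Distance in um.
#' @export
homolog_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "territory"), inherits(t2, "territory"))
  sqrt(sum((t1$centroid - t2$centroid)^2))
}

#' Classify homolog proximity
#'
#' A cell is proximal when its two homolog paint objects are either merged
#' into a single detected object (homologs too close to resolve) or lie
#' within `d_prox` of each other (boundary inclusive: distance equal to
#' `d_prox` counts as proximal). With no detected object the call is
#' undefined (`NA`) and the cell is excluded from percentages.
#'
#' @param territories list of 0-2 [territory()] objects (from
#'   [detect_territories()]).
#' @param d_prox proximity threshold in um (default 2.0).
#' @return A list of class `homolog_pair` with fields `n_objects`,
#'   `distance` (um; `NA` unless two objects), `proximal` (logical, `NA`
#'   when no object), `territory_volumes`.
#' @export
classify_proximity <- function(territories, d_prox = 2.0) {
  if (length(territories) > 2L)
    stop("more than 2 territories: upstream max_objects violated")
  n <- length(territories)
  dist_um <- if (n == 2L)
    homolog_distance(territories[[1]], territories[[2]]) else NA_real_
  proximal <- if (n == 0L) NA
    else if (n == 1L) TRUE
    else dist_um <= d_prox
  structure(list(n_objects = n, distance = dist_um, proximal = proximal,
                 territory_volumes = vapply(territories, function(t) t$volume,
                                            numeric(1)),
                 d_prox = d_prox),
            class = "homolog_pair")
}

#' @export
print.homolog_pair <- function(x, ...) {
  cat(sprintf("homolog_pair: %d object(s), distance %s um, proximal = %s\n",
              x$n_objects,
              if (is.na(x$distance)) "NA" else sprintf("%.2f", x$distance),
              x$proximal))
  invisible(x)
}

#' Mark--territory co-localization volume
#'
#' Volume of the voxels that are both inside the territory and above the
#' mark channel's Otsu threshold (computed within the nucleus when a nucleus
#' mask is given, otherwise within the territory's grid).
#'
#' @param mark numeric 3D intensity array on the territory's grid.
#' @param t a [territory()].
#' @param nucleus optional [nuclear_mask()] restricting the threshold
#'   estimation; defaults to thresholding over the whole array.
#' @param threshold threshold rule; currently `"otsu"`.
#' @return A list of class `colocalization` with `overlap_volume`,
#'   `mark_volume`, `territory_volume`, `overlap_fraction_of_territory`.
#' @export
colocalization_volume <- function(mark, t, nucleus = NULL,
                                  threshold = "otsu") {
  stopifnot(inherits(t, "territory"))
  grid <- t$grid
  mark <- array(as.numeric(mark), grid$shape)
  domain <- if (!is.null(nucleus)) {
    stopifnot(inherits(nucleus, "nuclear_mask"))
    nucleus$mask
  } else array(TRUE, grid$shape)
  vals <- mark[domain]
  vv <- voxel_volume(grid)
  if (max(vals) <= min(vals) && max(vals) <= 0) {
    res <- list(overlap_volume = 0, mark_volume = 0,
                territory_volume = t$volume,
                overlap_fraction_of_territory = 0)
    class(res) <- "colocalization"
    return(res)
  }
  thr <- switch(match.arg(threshold, "otsu"), otsu = otsu_threshold(vals))
  mark_fg <- domain & mark > thr
  tmask <- array(FALSE, grid$shape)
  tmask[t$voxels] <- TRUE
  overlap <- sum(mark_fg & tmask) * vv
  res <- list(overlap_volume = overlap,
              mark_volume = sum(mark_fg) * vv,
              territory_volume = t$volume,
              overlap_fraction_of_territory = overlap / t$volume)
  class(res) <- "colocalization"
  res
}

#' @export
print.colocalization <- function(x, ...) {
  cat(sprintf("colocalization: overlap %.3f um^3 (%.1f%% of territory %.3f um^3)\n",
              x$overlap_volume, 100 * x$overlap_fraction_of_territory,
              x$territory_volume))
  invisible(x)
}
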