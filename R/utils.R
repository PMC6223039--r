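# Internal numeric utilities shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Otsu's threshold on an intensity vector (256-bin histogram between the
# observed min and max). Returns the threshold on the intensity scale;
# constant input returns that constant (so `> thr` selects nothing).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(lo)
  h <- tabulate(pmin(n_bins, 1L + floor((x - lo) / (hi - lo) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) / n_bins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-n_bins])
  # threshold between bin k and k+1
  lo + k / n_bins * (hi - lo)
}

# 3D connected-component labelling (wrapper around the compiled routine).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label(as.logical(mask), as.integer(d), as.integer(connectivity))
  dim(lab) <- d
  lab
}

# Separable Gaussian blur; sigma given in physical units per axis (um) and
# converted to voxels with the grid spacing.
gauss_blur <- function(vol, grid, sigma_um) {
  sigma_um <- rep_len(sigma_um, 3L)
  s_vox <- sigma_um / grid$spacing
  out <- cpp_gauss_blur(as.numeric(vol), as.integer(grid$shape), s_vox)
  dim(out) <- grid$shape
  out
}

# Euclidean distance (um) from each foreground voxel centre to the nearest
# background voxel centre; 0 on background.
distance_to_background <- function(mask, grid) {
  d2 <- cpp_edt_sq(as.logical(mask), as.integer(grid$shape),
                   as.numeric(grid$spacing))
  dim(d2) <- grid$shape
  sqrt(d2)
}

# Fill interior holes: background components (6-connectivity) that do not
# touch the array border become foreground.
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- label_components(!mask, connectivity = 6L)
  touched <- setdiff(unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ],
                              bg[, d[2], ], bg[, , 1], bg[, , d[3]])), 0L)
  mask | (bg != 0L & !(bg %in% touched))
}

# Morphological closing with a ball of the given physical radius, via two
# distance transforms (dilate to radius r, then erode by r).
morph_close <- function(mask, grid, radius_um) {
  if (radius_um <= 0) return(mask)
  r2 <- radius_um^2
  d2_out <- cpp_edt_sq(!mask, as.integer(grid$shape), as.numeric(grid$spacing))
  dilated <- mask | (array(d2_out, dim(mask)) <= r2 & !mask)
  d2_in <- cpp_edt_sq(dilated, as.integer(grid$shape), as.numeric(grid$spacing))
  eroded <- dilated & (array(d2_in, dim(mask)) > r2)
  # keep at least the original mask: closing never removes original voxels
  eroded | mask
}

# Retain the largest connected component; ties broken by the component whose
# centroid has the lexicographically lowest (z, y, x) coordinate.
largest_component <- function(mask, grid = NULL) {
  lab <- label_components(mask, connectivity = 26L)
  k <- max(lab)
  if (k == 0L) return(mask & FALSE)
  if (k == 1L) return(lab == 1L)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cents <- t(vapply(best, function(l) colMeans(which_idx3(lab == l)),
                      numeric(3)))
    best <- best[do.call(order, as.data.frame(cents))[1]]
  }
  lab == best[1]
}
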