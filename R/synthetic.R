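#' Nucleus shape parameters for the scene generator
#'
#' Parameterizes the generative nucleus model: an ellipsoid of given mean
#' radius and axis ratios, optionally roughened by a smooth random radial
#' perturbation, with invaginations carved as spherical pockets that
#' intersect the boundary (the "pocket-like" indentations seen in young
#' HSC nuclei).
#'
#' @param radius mean radius in micrometres.
#' @param axis_ratios three positive per-axis scale factors (z, y, x).
#' @param invagination_count integer >= 0, number of pockets.
#' @param invagination_depth pocket depth in um (how far the pocket reaches
#'   below the local surface); must be < `radius`.
#' @param invagination_radius pocket sphere radius in um, > 0.
#' @param boundary_roughness dimensionless amplitude of the smooth radial
#'   perturbation (fraction of the radius), >= 0.
#' @return An object of class `nucleus_shape_params`.
#' @export
nucleus_shape_params <- function(radius = 3, axis_ratios = c(1, 1, 1),
                                 invagination_count = 0L,
                                 invagination_depth = 1.5,
                                 invagination_radius = 1,
                                 boundary_roughness = 0) {
  stopifnot(radius > 0, length(axis_ratios) == 3, all(axis_ratios > 0),
            invagination_count >= 0, invagination_depth >= 0,
            invagination_radius > 0, boundary_roughness >= 0)
  if (invagination_count > 0 && invagination_depth >= radius)
    stop("invagination_depth must be smaller than the radius")
  structure(list(radius = radius, axis_ratios = as.numeric(axis_ratios),
                 invagination_count = as.integer(invagination_count),
                 invagination_depth = invagination_depth,
                 invagination_radius = invagination_radius,
                 boundary_roughness = boundary_roughness),
            class = "nucleus_shape_params")
}

# Smooth random radial modulation on the unit sphere: a few random cosine
# waves, normalized to roughly unit amplitude.
.roughness_field <- function(n_waves = 6L) {
  v <- matrix(rnorm(3 * n_waves), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  a <- rnorm(n_waves)
  phi <- runif(n_waves, 0, 2 * pi)
  a <- a / sqrt(sum(a^2) / 2)  # unit-ish RMS
  function(u) {
    # u: n x 3 unit directions
    s <- numeric(nrow(u))
    for (k in seq_len(n_waves))
      s <- s + a[k] * cos(4 * (u %*% v[k, ]) + phi[k])
    as.numeric(s)
  }
}

#' Generate a binary nucleus mask
#'
#' Renders the parameterized nucleus shape onto a voxel grid, carves the
#' requested invagination pockets, and returns the largest connected
#' component as a [nuclear_mask()]. Deterministic for a fixed seed.
#'
#' @param params a [nucleus_shape_params()].
#' @param grid a [grid_spec()]; the shape must fit with a margin of at least
#'   2 voxels on every face.
#' @param seed integer seed controlling the roughness field and pocket
#'   placement.
#' @return A [nuclear_mask()] whose attribute `"pockets"` records the carved
#'   pocket centres/radii.
#' @examples
#' g <- grid_spec(c(36, 36, 36), c(0.25, 0.25, 0.25))
#' m <- make_nucleus_mask(nucleus_shape_params(radius = 3), g, seed = 1)
#' nuclear_volume(m)  # ~ 4/3 * pi * 27
#' @export
make_nucleus_mask <- function(params, grid, seed = 1L) {
  stopifnot(inherits(params, "nucleus_shape_params"), inherits(grid, "grid_spec"))
  extent <- grid$shape * grid$spacing
  r_ax <- params$radius * params$axis_ratios *
    (1 + 2 * params$boundary_roughness)
  need <- 2 * (r_ax + 2 * grid$spacing)
  if (any(extent < need)) {
    bad <- which(extent < need)[1]
    stop(sprintf(paste0("nucleus (bounding radius %.2f um along %s) exceeds ",
                        "the grid: a margin of at least 2 voxels is required"),
                 r_ax[bad], c("z", "y", "x")[bad]))
  }
  with_seed(seed, {
    center <- extent / 2
    rough <- if (params$boundary_roughness > 0) .roughness_field() else NULL
    zc <- axis_coords(grid, 1) - center[1]
    yc <- axis_coords(grid, 2) - center[2]
    xc <- axis_coords(grid, 3) - center[3]
    d <- grid$shape
    Z <- array(zc, d)
    Y <- array(rep(yc, each = d[1]), d)
    X <- array(rep(xc, each = d[1] * d[2]), d)
    # per-axis scaled offsets: inside iff ||q|| <= r * (1 + rough(u))
    Q1 <- Z / params$axis_ratios[1]
    Q2 <- Y / params$axis_ratios[2]
    Q3 <- X / params$axis_ratios[3]
    qn <- sqrt(Q1^2 + Q2^2 + Q3^2)
    r_eff <- params$radius
    if (!is.null(rough)) {
      qs <- pmax(qn, 1e-12)
      u <- cbind(as.numeric(Q1 / qs), as.numeric(Q2 / qs), as.numeric(Q3 / qs))
      r_eff <- params$radius * (1 + params$boundary_roughness * rough(u))
      dim(r_eff) <- d
    }
    mask <- qn <= r_eff
    pockets <- NULL
    if (params$invagination_count > 0) {
      rho <- params$invagination_radius
      depth <- params$invagination_depth
      for (i in seq_len(params$invagination_count)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        # radius of the (unroughened) ellipsoid surface along u
        r_dir <- params$radius / sqrt(sum((u / params$axis_ratios)^2))
        pc <- center + u * (r_dir - depth + rho)
        dz <- Z + center[1] - pc[1]
        dy <- Y + center[2] - pc[2]
        dx <- X + center[3] - pc[3]
        mask <- mask & (dz^2 + dy^2 + dx^2 > rho^2)
        pockets <- rbind(pockets, c(pc, rho))
      }
    }
    mask <- largest_component(mask)
    out <- nuclear_mask(mask, grid, cell_id = "synthetic", check = FALSE)
    attr(out, "pockets") <- pockets
    out
  })
}

#' Scene configuration for the synthetic renderer
#'
#' Describes one synthetic cell: the grid, the nucleus shape, the directional
#' concentration of the histone-mark channel (von Mises-Fisher weight; 0 =
#' isotropic), the homolog blob pair, optics (Gaussian PSF), and the noise
#' model (Poisson-like photon term with `gain`, plus Gaussian read noise).
#'
#' @param grid a [grid_spec()].
#' @param nucleus a [nucleus_shape_params()].
#' @param mark_polarity_kappa concentration >= 0 of the directional intensity
#'   bias of the mark channel about a random unit direction.
#' @param homolog_separation centre-to-centre homolog distance in um (>= 0).
#' @param homolog_blob_sigma Gaussian blob sigma in um.
#' @param psf_sigma per-axis PSF sigma in um (recycled to length 3).
#' @param noise list with `gain` (photon-noise scale; 0 disables) and
#'   `read_sd` (additive Gaussian s.d. in counts).
#' @param channel_names ordered channel labels; defaults to
#'   `c("dapi", "mark", "paint")`. Channels may be omitted.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid, nucleus = nucleus_shape_params(),
                         mark_polarity_kappa = 0,
                         homolog_separation = 2,
                         homolog_blob_sigma = 0.4,
                         psf_sigma = c(0.4, 0.2, 0.2),
                         noise = list(gain = 4, read_sd = 20),
                         channel_names = c("dapi", "mark", "paint")) {
  stopifnot(inherits(grid, "grid_spec"), inherits(nucleus, "nucleus_shape_params"),
            mark_polarity_kappa >= 0, homolog_separation >= 0,
            homolog_blob_sigma > 0)
  psf_sigma <- rep_len(as.numeric(psf_sigma), 3L)
  structure(list(grid = grid, nucleus = nucleus,
                 mark_polarity_kappa = mark_polarity_kappa,
                 homolog_separation = homolog_separation,
                 homolog_blob_sigma = homolog_blob_sigma,
                 psf_sigma = psf_sigma, noise = noise,
                 channel_names = channel_names),
            class = "scene_config")
}

#' Render a synthetic multi-channel scene
#'
#' Produces a 16-bit multi-channel volume from a [scene_config()]: the DAPI
#' channel is the (PSF-blurred, noised) nucleus; the mark channel carries a
#' von Mises-Fisher intensity bias `exp(kappa * cos(theta))` about a random
#' polarity direction inside the nucleus; the paint channel holds two
#' Gaussian homolog blobs at the configured separation. The ground truth
#' (true mask, true homolog centroids, true polarity direction) is attached
#' as the `"ground_truth"` attribute.
#'
#' @param cfg a [scene_config()].
#' @param seed integer seed; identical (cfg, seed) give identical output.
#' @return A [multichannel_volume()] of integer-valued 16-bit intensities
#'   with attribute `"ground_truth"`.
#' @export
render_scene <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "scene_config"))
  grid <- cfg$grid
  gt_mask <- make_nucleus_mask(cfg$nucleus, grid, seed = seed)
  with_seed(seed + 1000003L, {
    d <- grid$shape
    amp <- 3000
    mask <- gt_mask$mask
    idx <- which_idx3(mask)
    ctr <- colMeans(voxel_centers(idx, grid))
    chans <- list()
    truth <- list(mask = gt_mask, nucleus_centroid = ctr)

    if ("dapi" %in% cfg$channel_names)
      chans$dapi <- array(amp * mask, d)

    if ("mark" %in% cfg$channel_names) {
      dir_ <- rnorm(3); dir_ <- dir_ / sqrt(sum(dir_^2))
      pos <- voxel_centers(idx, grid)
      rel <- sweep(pos, 2, ctr)
      rn <- pmax(sqrt(rowSums(rel^2)), 1e-12)
      cosang <- (rel %*% dir_) / rn
      inten <- amp * exp(cfg$mark_polarity_kappa * (cosang - 1))
      mk <- array(0, d)
      mk[mask] <- inten
      chans$mark <- mk
      truth$polarity_direction <- dir_
    }

    if ("paint" %in% cfg$channel_names) {
      half <- cfg$homolog_separation / 2
      centers <- NULL
      for (try in 1:200) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p1 <- ctr + half * u
        p2 <- ctr - half * u
        i1 <- pmin(pmax(round(p1 / grid$spacing + 0.5), 1), d)
        i2 <- pmin(pmax(round(p2 / grid$spacing + 0.5), 1), d)
        if (mask[i1[1], i1[2], i1[3]] && mask[i2[1], i2[2], i2[3]]) {
          centers <- rbind(p1, p2)
          break
        }
      }
      if (is.null(centers))
        stop("homolog separation too large for this nucleus")
      zc <- axis_coords(grid, 1); yc <- axis_coords(grid, 2); xc <- axis_coords(grid, 3)
      Z <- array(zc, d)
      Y <- array(rep(yc, each = d[1]), d)
      X <- array(rep(xc, each = d[1] * d[2]), d)
      s2 <- 2 * cfg$homolog_blob_sigma^2
      pt <- array(0, d)
      for (k in 1:2) {
        r2 <- (Z - centers[k, 1])^2 + (Y - centers[k, 2])^2 + (X - centers[k, 3])^2
        pt <- pt + amp * exp(-r2 / s2)
      }
      chans$paint <- pt
      truth$homolog_centroids <- centers
      truth$homolog_separation <- cfg$homolog_separation
    }

    for (nm in names(chans)) {
      v <- gauss_blur(chans[[nm]], grid, cfg$psf_sigma)
      g <- cfg$noise$gain
      if (!is.null(g) && g > 0)
        v <- array(rpois(length(v), pmax(v, 0) / g) * g, d)
      rs <- cfg$noise$read_sd
      if (!is.null(rs) && rs > 0)
        v <- v + rnorm(length(v), 0, rs)
      chans[[nm]] <- array(pmin(pmax(round(v), 0), 65535), d)
    }
    out <- multichannel_volume(chans[cfg$channel_names[cfg$channel_names %in% names(chans)]],
                               grid)
    truth$config <- cfg
    attr(out, "ground_truth") <- truth
    out
  })
}

#' Sample a synthetic peak table with per-chromosome fold enrichment
#'
#' Draws `n_peaks` genomic intervals: the chromosome of each peak follows a
#' multinomial with probability proportional to chromosome size times its
#' fold factor, and the start is uniform on `[0, size - width)`. This is the
#' generative inverse of the observed-versus-expected enrichment analysis,
#' so known fold maps can be recovered downstream.
#'
#' @param n_peaks number of peaks (>= 0).
#' @param chrom_sizes a [genome_table()] or data.frame with columns `chrom`,
#'   `size`.
#' @param fold_map named numeric vector of per-chromosome fold factors
#'   (default 1 for every chromosome); all > 0.
#' @param seed integer seed.
#' @param peak_width fixed peak width in bp (default 500).
#' @param directions optional character vector of direction labels to sample
#'   uniformly (e.g. `c("gain", "loss")`); `NULL` omits the column.
#' @return A [peak_table()] sorted by (chrom, start).
#' @export
sample_peak_table <- function(n_peaks, chrom_sizes, fold_map = NULL,
                              seed = 1L, peak_width = 500L,
                              directions = NULL) {
  if (n_peaks < 0) stop("n_peaks must be >= 0")
  gt <- as.data.frame(chrom_sizes)
  stopifnot(all(c("chrom", "size") %in% names(gt)), all(gt$size > 0))
  fold <- setNames(rep(1, nrow(gt)), gt$chrom)
  if (!is.null(fold_map)) {
    if (any(fold_map <= 0)) stop("all folds must be > 0")
    unknown <- setdiff(names(fold_map), gt$chrom)
    if (length(unknown))
      stop("fold_map names not in the genome table: ",
           paste(unknown, collapse = ", "))
    fold[names(fold_map)] <- fold_map
  }
  if (n_peaks == 0) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    if (!is.null(directions)) out$direction <- character()
    return(peak_table(out))
  }
  with_seed(seed, {
    w <- gt$size * fold[gt$chrom]
    chrom <- sample(gt$chrom, n_peaks, replace = TRUE, prob = w / sum(w))
    sz <- setNames(gt$size, gt$chrom)[chrom]
    start <- floor(runif(n_peaks) * pmax(sz - peak_width, 1))
    out <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(start + peak_width),
                      stringsAsFactors = FALSE)
    if (!is.null(directions))
      out$direction <- sample(directions, n_peaks, replace = TRUE)
    peak_table(out)
  })
}

#' Cohort configuration for the synthetic generator
#'
#' Defines named groups (e.g. young, aged, aged+CASIN), each with its own
#' distributions of generator parameters, a number of cells per group, and a
#' number of biological repeats over which group-level statistics are
#' summarized.
#'
#' @param groups named list; each element is a list with numeric entries
#'   `radius_mean`, `radius_sd`, `kappa`, `separation_mean`, `separation_sd`,
#'   and optionally `invagination_count`, `invagination_depth`,
#'   `axis_ratios`, `boundary_roughness`.
#' @param n_cells cells per group (>= 1).
#' @param n_repeats biological repeats per group (cells are split evenly).
#' @param seed root seed; all per-cell seeds derive from it.
#' @param grid the common [grid_spec()] for all scenes.
#' @param noise,psf_sigma shared renderer settings (see [scene_config()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups, n_cells = 30L, n_repeats = 3L, seed = 1L,
                          grid = grid_spec(c(40, 64, 64), c(0.5, 0.25, 0.25)),
                          noise = list(gain = 4, read_sd = 20),
                          psf_sigma = c(0.4, 0.2, 0.2)) {
  stopifnot(is.list(groups), length(groups) >= 1, n_cells >= 1, n_repeats >= 1)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("group names must be present and unique")
  structure(list(groups = groups, n_cells = as.integer(n_cells),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 grid = grid, noise = noise, psf_sigma = psf_sigma),
            class = "cohort_config")
}

#' Default two-group aging cohort settings
#'
#' Generator settings emulating the young vs aged contrast: young nuclei are
#' smaller, near-spherical but deeply invaginated, carry a concentrated
#' (polar) mark and nearly merged homologs; aged nuclei are larger,
#' odd-shaped (elongated and rough-surfaced, hence a lower shape factor),
#' apolar, with separated homologs.
#'
#' @param n_cells,n_repeats,seed,grid passed to [cohort_config()].
#' @return A [cohort_config()] with groups `young` and `aged`.
#' @export
aging_cohort_config <- function(n_cells = 30L, n_repeats = 3L, seed = 1L,
                                grid = grid_spec(c(40, 64, 64),
                                                 c(0.5, 0.25, 0.25))) {
  cohort_config(
    groups = list(
      young = list(radius_mean = 2.6, radius_sd = 0.15, kappa = 8,
                   separation_mean = 1.0, separation_sd = 0.2,
                   invagination_count = 2L, invagination_depth = 1.2),
      aged = list(radius_mean = 3.2, radius_sd = 0.15, kappa = 0.5,
                  separation_mean = 4.0, separation_sd = 0.4,
                  invagination_count = 0L, invagination_depth = 0,
                  axis_ratios = c(1.45, 1, 0.8), boundary_roughness = 0.05)
    ),
    n_cells = n_cells, n_repeats = n_repeats, seed = seed, grid = grid)
}

# Build the scene_config for one cell of a cohort group (seeded draws of the
# per-cell parameters).
.group_scene <- function(cohort, group_name, cell_seed) {
  g <- cohort$groups[[group_name]]
  with_seed(cell_seed, {
    radius <- max(1, rnorm(1, g$radius_mean, g$radius_sd %||% 0))
    sep <- max(0, rnorm(1, g$separation_mean %||% 2, g$separation_sd %||% 0))
    sep <- min(sep, 2 * radius * 0.85)  # keep homologs inside the nucleus
    nuc <- nucleus_shape_params(
      radius = radius,
      axis_ratios = g$axis_ratios %||% c(1, 1, 1),
      invagination_count = g$invagination_count %||% 0L,
      invagination_depth = g$invagination_depth %||% 0,
      invagination_radius = g$invagination_radius %||% 1,
      boundary_roughness = g$boundary_roughness %||% 0.02)
    scene_config(cohort$grid, nuc, mark_polarity_kappa = g$kappa %||% 0,
                 homolog_separation = sep,
                 psf_sigma = cohort$psf_sigma, noise = cohort$noise)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of synthetic cells
#'
#' Renders every cell of a [cohort_config()]. With `dir = NULL` the scenes
#' are returned in memory; otherwise each cell is written as a 16-bit
#' multi-channel TIFF with a YAML sidecar (see [write_scene()]) plus a
#' `ground_truth.csv`.
#'
#' @param cohort a [cohort_config()].
#' @param dir optional output directory.
#' @return Invisibly, a list with `scenes` (named list or file paths) and
#'   `truth` (data.frame of generating parameters per cell).
#' @export
simulate_cohort <- function(cohort, dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  scenes <- list()
  truth <- NULL
  cell_no <- 0L
  for (gname in names(cohort$groups)) {
    for (i in seq_len(cohort$n_cells)) {
      cell_no <- cell_no + 1L
      cell_seed <- (cohort$seed + 7919L * cell_no) %% 2000000000L
      cfg <- .group_scene(cohort, gname, cell_seed)
      sc <- render_scene(cfg, seed = cell_seed + 1L)
      gt <- attr(sc, "ground_truth")
      rep_id <- ((i - 1L) %% cohort$n_repeats) + 1L
      cid <- sprintf("%s_%03d", gname, i)
      truth <- rbind(truth, data.frame(
        cell_id = cid, group = gname, repeat_id = rep_id,
        radius = cfg$nucleus$radius,
        kappa = cfg$mark_polarity_kappa,
        separation = cfg$homolog_separation,
        true_volume_um3 = sum(gt$mask$mask) * voxel_volume(cohort$grid),
        stringsAsFactors = FALSE))
      if (is.null(dir)) {
        scenes[[cid]] <- sc
      } else {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        path <- file.path(dir, paste0(cid, ".tif"))
        write_scene(sc, path)
        scenes[[cid]] <- path
      }
    }
  }
  if (!is.null(dir))
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(list(scenes = scenes, truth = truth))
}
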