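# Independent brute-force oracles and small fixture builders. These mirror
# the definitions directly (explicit loops, all-pairs scans) and deliberately
# avoid the package's own code paths.

# Digital ball: voxel centres within radius r of a physical centre.
ball_array <- function(shape, spacing, center, r) {
  a <- array(FALSE, shape)
  for (z in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (x in seq_len(shape[3])) {
      p <- (c(z, y, x) - 0.5) * spacing
      a[z, y, x] <- sum((p - center)^2) <= r^2
    }
  a
}

# Random connected ellipsoid mask on a small grid.
rand_ellipsoid <- function(seed, shape = c(12, 12, 12),
                           spacing = c(0.4, 0.3, 0.3)) {
  set.seed(seed)
  ctr <- shape * spacing / 2 + runif(3, -0.3, 0.3)
  rr <- runif(3, 0.8, 1.6)
  a <- array(FALSE, shape)
  for (z in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (x in seq_len(shape[3])) {
      p <- (c(z, y, x) - 0.5) * spacing
      a[z, y, x] <- sum(((p - ctr) / rr)^2) <= 1
    }
  a
}

# Voxel count by an explicit triple loop.
brute_volume <- function(mask, spacing) {
  cnt <- 0
  d <- dim(mask)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (mask[z, y, x]) cnt <- cnt + 1
  cnt * prod(spacing)
}

# Centroid as the plain average of voxel-centre coordinates.
brute_centroid <- function(mask, spacing) {
  d <- dim(mask)
  acc <- c(0, 0, 0); n <- 0
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    if (mask[z, y, x]) {
      acc <- acc + (c(z, y, x) - 0.5) * spacing
      n <- n + 1
    }
  acc / n
}

# Peripherality by scanning, for every foreground voxel, its distance to the
# nearest background voxel centre.
brute_peripherality <- function(channel, mask, spacing, depth) {
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  fg_p <- sweep(fg - 0.5, 2, spacing, "*")
  bg_p <- sweep(bg - 0.5, 2, spacing, "*")
  shell_sum <- 0; total <- 0
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg_p[, 1] - fg_p[i, 1])^2 + (bg_p[, 2] - fg_p[i, 2])^2 +
      (bg_p[, 3] - fg_p[i, 3])^2
    w <- channel[fg[i, 1], fg[i, 2], fg[i, 3]]
    total <- total + w
    if (sqrt(min(d2)) <= depth) shell_sum <- shell_sum + w
  }
  shell_sum / total
}

# Per-chromosome tally by a per-record loop.
brute_counts <- function(peaks, chroms) {
  out <- setNames(rep(0L, length(chroms)), chroms)
  for (i in seq_len(nrow(peaks)))
    out[peaks$chrom[i]] <- out[peaks$chrom[i]] + 1L
  out
}

# Differential overlap by an all-pairs scan; the partner of an A peak is the
# first overlapping B peak in (chrom, start, end) order.
brute_overlap <- function(a, b, min_bp = 1L) {
  b <- b[order(b$chrom, b$start, b$end), ]
  n_overlap <- 0L; n_same <- 0L
  for (i in seq_len(nrow(a))) {
    partner <- NA
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) { partner <- j; break }
    }
    if (!is.na(partner)) {
      n_overlap <- n_overlap + 1L
      if (a$direction[i] == b$direction[partner]) n_same <- n_same + 1L
    }
  }
  list(n_overlap = n_overlap, n_same_direction = n_same)
}

# Random direction-bearing peak table on a toy 2-chromosome genome.
rand_peaks <- function(seed, n_max = 15L) {
  set.seed(seed)
  n <- sample.int(n_max, 1)
  start <- sample.int(5000, n, replace = TRUE)
  peak_table(data.frame(
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    start = start,
    end = start + sample.int(300, n, replace = TRUE),
    direction = sample(c("gain", "loss"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# Dense independent direction search for the polarity score (plain Fibonacci
# lattice, no octahedral closure): independent of the package lattice.
dense_polarity <- function(mark, mask_obj, n_dir = 5000L) {
  grid <- mask_obj$grid
  idx <- which(mask_obj$mask, arr.ind = TRUE)
  pos <- sweep(idx - 0.5, 2, grid$spacing, "*")
  ctr <- colMeans(pos)
  rel <- sweep(pos, 2, ctr)
  w <- mark[mask_obj$mask]
  gold <- (1 + sqrt(5)) / 2
  i <- seq_len(n_dir)
  zc <- (2 * i - 1) / n_dir - 1
  r <- sqrt(pmax(0, 1 - zc^2))
  th <- 2 * pi * i / gold
  dirs <- cbind(zc, r * cos(th), r * sin(th))
  best <- 0
  for (s in seq(1, n_dir, by = 100)) {
    e <- min(s + 99, n_dir)
    proj <- rel %*% t(dirs[s:e, , drop = FALSE])
    best <- max(best, max(colSums(w * (proj >= 0)) / sum(w)))
  }
  best
}

# Small noiseless rendering defaults shared across tests.
quiet_noise <- list(gain = 0, read_sd = 0)
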