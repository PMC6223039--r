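# Reproducible epipolarity scoring: replaces the visual "clear asymmetric
# distribution" call with a half-space mass maximization over a deterministic
# direction lattice.

# Deterministic direction lattice on the unit sphere: the 6 axis directions
# plus a Fibonacci point set closed under the full octahedral group (all 48
# signed axis permutations). Closure makes the score exactly invariant under
# 90-degree scene rotations; antipodal closure guarantees score >= 0.5.
polarity_directions <- function(n_directions = 200L) {
  stopifnot(n_directions >= 1L)
  m <- max(1L, ceiling((n_directions - 6L) / 48L))
  gold <- (1 + sqrt(5)) / 2
  i <- seq_len(m)
  zc <- (2 * i - 1) / m - 1
  r <- sqrt(pmax(0, 1 - zc^2))
  th <- 2 * pi * i / gold
  base <- cbind(zc, r * cos(th), r * sin(th))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- matrix(0, 0, 3)
  for (p in perms)
    for (s in seq_len(nrow(signs)))
      out <- rbind(out, sweep(base[, p, drop = FALSE], 2, signs[s, ], "*"))
  out <- rbind(diag(3), -diag(3), out)
  unique(round(out, 12))
}

#' Epipolarity score of a mark channel
#'
#' For every direction of a deterministic spherical lattice, the fraction of
#' the total within-mask mark intensity lying on the positive closed
#' half-space of the plane through the mask centroid is computed; the score
#' is the maximum fraction and the direction its argmax (ties broken by
#' lattice order). A uniform mark scores about 0.5, a fully one-sided mark
#' scores 1. The plane passes through the binary mask centroid -- the
#' "middle of the nucleus" -- not the intensity centroid.
#'
#' @param mark nonnegative 3D intensity array on the mask's grid, with some
#'   positive intensity inside the mask.
#' @param mask a [nuclear_mask()].
#' @param n_directions approximate number of lattice directions (default
#'   200; the octahedral closure rounds it up slightly).
#' @return A list of class `polarity_result` with `score` (in `[0.5, 1]`),
#'   `direction` (unit 3-vector, z/y/x), and `n_directions`.
#' @export
epipolarity_score <- function(mark, mask, n_directions = 200L) {
  stopifnot(inherits(mask, "nuclear_mask"))
  grid <- mask$grid
  mark <- array(as.numeric(mark), grid$shape)
  if (any(mark < 0)) stop("mark intensities must be nonnegative")
  idx <- which_idx3(mask$mask)
  w <- mark[mask$mask]
  total <- sum(w)
  if (total <= 0) stop("no signal: mark channel is zero within the mask")
  pos <- voxel_centers(idx, grid)
  ctr <- colMeans(pos)
  rel <- sweep(pos, 2, ctr)
  dirs <- polarity_directions(n_directions)
  best <- -Inf
  best_k <- 1L
  chunk <- 32L
  for (s in seq(1L, nrow(dirs), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(dirs))
    proj <- rel %*% t(dirs[s:e, , drop = FALSE])
    frac <- colSums(w * (proj >= 0)) / total
    k <- which.max(frac)
    if (frac[k] > best) { best <- frac[k]; best_k <- s + k - 1L }
  }
  structure(list(score = best, direction = dirs[best_k, ],
                 n_directions = nrow(dirs)),
            class = "polarity_result")
}

#' @export
print.polarity_result <- function(x, ...) {
  cat(sprintf("polarity: score %.3f along (%.2f, %.2f, %.2f) [%d directions]\n",
              x$score, x$direction[1], x$direction[2], x$direction[3],
              x$n_directions))
  invisible(x)
}

#' Classify a cell as polar
#'
#' @param score epipolarity score in `[0.5, 1]` (a `polarity_result` is also
#'   accepted).
#' @param tau decision threshold in (0.5, 1] (default 0.7); the call is
#'   `score >= tau`.
#' @return Logical.
#' @export
classify_polar <- function(score, tau = 0.7) {
  if (inherits(score, "polarity_result")) score <- score$score
  if (tau <= 0.5 || tau > 1) stop("tau must lie in (0.5, 1]")
  stopifnot(score >= 0.5 - 1e-9, score <= 1 + 1e-9)
  score >= tau
}

#' Percent polar cells, summarized across biological repeats
#'
#' Computes the percentage of polar cells within each biological repeat,
#' then the mean and standard error of those per-repeat percentages -- the
#' "mean values + 1 SE over n biological repeats" reporting convention.
#'
#' @param polar logical vector of per-cell polarity calls (`NA` cells are
#'   dropped).
#' @param repeat_id vector identifying the biological repeat of each cell.
#' @return A list with `percent` (mean across repeats), `sem`, `n_repeats`,
#'   and `per_repeat` (named percentages). With a single repeat the SEM is
#'   undefined and reported as 0 with a warning.
#' @export
percent_polar <- function(polar, repeat_id = rep(1L, length(polar))) {
  keep <- !is.na(polar)
  polar <- polar[keep]
  repeat_id <- repeat_id[keep]
  if (length(polar) == 0L) stop("no scored cells")
  per <- tapply(polar, repeat_id, function(v) 100 * mean(v))
  k <- length(per)
  sem <- if (k < 2L) {
    warning("single biological repeat: SEM undefined, reported as 0")
    0
  } else sd(per) / sqrt(k)
  list(percent = mean(per), sem = sem, n_repeats = k,
       per_repeat = per)
}
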