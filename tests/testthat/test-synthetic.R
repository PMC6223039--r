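# Synthetic-scene and peak-table generator.

test_that("digital sphere mask matches the analytic ball volume", {
  g <- grid_spec(c(36, 36, 36), c(0.25, 0.25, 0.25))
  m <- make_nucleus_mask(nucleus_shape_params(radius = 3), g, seed = 1)
  expect_lt(abs(nuclear_volume(m) - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.03)
  # ground-truth consistency: volume is exactly count x voxel volume
  expect_identical(nuclear_volume(m), sum(m$mask) * voxel_volume(g))
})

test_that("unperturbed masks are near-convex and pockets lower solidity", {
  g <- grid_spec(c(36, 36, 36), c(0.25, 0.25, 0.25))
  m0 <- make_nucleus_mask(nucleus_shape_params(radius = 3), g, seed = 3)
  expect_gte(solidity(m0), 0.98)
  m1 <- make_nucleus_mask(
    nucleus_shape_params(radius = 3, invagination_count = 1,
                         invagination_depth = 1.5, invagination_radius = 1),
    g, seed = 3)
  expect_lt(solidity(m1), solidity(m0))
})

test_that("shapes that do not fit the grid raise a margin error", {
  g <- grid_spec(c(16, 16, 16), c(0.25, 0.25, 0.25))
  expect_error(make_nucleus_mask(nucleus_shape_params(radius = 3), g, seed = 1),
               "margin")
})

test_that("rendering is deterministic and produces 16-bit integers", {
  g <- grid_spec(c(16, 24, 24), c(0.5, 0.25, 0.25))
  cfg <- scene_config(g, nucleus_shape_params(radius = 1.8),
                      mark_polarity_kappa = 3, homolog_separation = 1.5)
  s1 <- render_scene(cfg, seed = 9)
  s2 <- render_scene(cfg, seed = 9)
  expect_identical(s1$data, s2$data)
  s3 <- render_scene(cfg, seed = 10)
  expect_false(identical(s1$data, s3$data))
  for (ch in s1$data) {
    expect_true(all(ch == round(ch)))
    expect_true(all(ch >= 0 & ch <= 65535))
  }
  gt <- attr(s1, "ground_truth")
  expect_equal(sqrt(sum((gt$homolog_centroids[1, ] -
                           gt$homolog_centroids[2, ])^2)), 1.5)
})

test_that("isotropic mark renders score ~0.5 and concentrated mark scores high", {
  g <- grid_spec(c(20, 32, 32), c(0.4, 0.25, 0.25))
  cfg0 <- scene_config(g, nucleus_shape_params(radius = 2.6),
                       mark_polarity_kappa = 0, noise = quiet_noise,
                       channel_names = c("dapi", "mark"))
  s0 <- render_scene(cfg0, seed = 2)
  gt0 <- attr(s0, "ground_truth")
  sc0 <- epipolarity_score(s0$data$mark, gt0$mask)
  expect_lt(abs(sc0$score - 0.5), 0.05)

  cfg10 <- scene_config(g, nucleus_shape_params(radius = 2.6),
                        mark_polarity_kappa = 10, noise = quiet_noise,
                        channel_names = c("dapi", "mark"))
  s10 <- render_scene(cfg10, seed = 2)
  sc10 <- epipolarity_score(s10$data$mark, attr(s10, "ground_truth")$mask)
  # vMF oracle: mass of exp(kappa cos) on the aligned hemisphere
  k <- 10
  vmf_half <- (exp(k) - 1) / (exp(k) - exp(-k))
  expect_gt(vmf_half, 0.999)
  expect_gte(sc10$score, 0.9)
})

test_that("detected homolog distance matches the configured separation", {
  g <- grid_spec(c(32, 56, 56), c(0.5, 0.25, 0.25))
  cfg <- scene_config(g, nucleus_shape_params(radius = 3),
                      homolog_separation = 4, homolog_blob_sigma = 0.4,
                      noise = quiet_noise)
  s <- render_scene(cfg, seed = 5)
  nuc <- attr(s, "ground_truth")$mask
  terr <- detect_territories(s$data$paint, nuc)
  expect_length(terr, 2)
  vox_diag <- sqrt(sum(g$spacing^2))
  expect_lt(abs(homolog_distance(terr[[1]], terr[[2]]) - 4), 2 * vox_diag)
})

test_that("peak sampling honours sizes, folds and the empty edge case", {
  toy <- genome_table(paste0("chr", 1:5),
                      c(50e6, 40e6, 30e6, 20e6, 10e6))
  expect_error(sample_peak_table(-1, toy), "n_peaks")
  p0 <- sample_peak_table(0, toy)
  expect_s3_class(p0, "peak_table")
  expect_identical(nrow(p0), 0L)

  # folds all 1: observed/expected within multinomial error at n = 100,000
  pk <- sample_peak_table(100000, toy, seed = 11)
  obs <- count_peaks_per_chrom(pk, toy)
  exp_ <- expected_counts(100000, setNames(toy$size, toy$chrom))
  expect_true(all(obs / exp_ > 0.95 & obs / exp_ < 1.05))
  expect_true(all(pk$start >= 0 & pk$end <= toy$size[match(pk$chrom, toy$chrom)]))
  # sorted output
  expect_false(is.unsorted(order(pk$chrom, pk$start)))
})

test_that("a strong fold makes its chromosome the top enrichment in most seeds", {
  gt <- mouse_chrom_sizes()
  hits <- vapply(1:60, function(s) {
    pk <- sample_peak_table(118, gt, fold_map = c(chr11 = 5), seed = s)
    obs <- count_peaks_per_chrom(pk, gt)
    exp_ <- expected_counts(118, setNames(gt$size, gt$chrom))
    names(which.max(obs / exp_)) == "chr11"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
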