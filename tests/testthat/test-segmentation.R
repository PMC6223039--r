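# Nuclear segmentation and territory detection.

test_that("segmentation recovers a noiseless rendered nucleus", {
  g <- grid_spec(c(32, 48, 48), c(0.5, 0.25, 0.25))
  s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.8),
                                 noise = quiet_noise,
                                 channel_names = "dapi"), seed = 3)
  gt <- attr(s, "ground_truth")$mask
  nuc <- segment_nucleus(s$data$dapi, g)
  jac <- sum(nuc$mask & gt$mask) / sum(nuc$mask | gt$mask)
  expect_gte(jac, 0.95)
})

test_that("degenerate images raise 'no nucleus found'", {
  g <- grid_spec(c(12, 12, 12), c(0.25, 0.25, 0.25))
  expect_error(segment_nucleus(array(0, g$shape), g), "no nucleus found")
  expect_error(segment_nucleus(array(7, g$shape), g), "no nucleus found")
})

test_that("a two-nucleus field resolves to exactly one (the larger) mask", {
  g <- grid_spec(c(24, 56, 28), c(0.25, 0.25, 0.25))
  c1 <- c(3, 4.0, 3.5)   # larger nucleus
  c2 <- c(3, 9.6, 3.5)   # smaller, close enough to bridge after blur
  a <- 3000 * (ball_array(g$shape, g$spacing, c1, 2.2) |
                 ball_array(g$shape, g$spacing, c2, 1.6))
  dapi <- nucarch:::gauss_blur(a, g, c(0.3, 0.3, 0.3))
  nuc <- segment_nucleus(dapi, g)
  i1 <- round(c1 / g$spacing); i2 <- round(c2 / g$spacing)
  expect_true(nuc$mask[i1[1], i1[2], i1[3]])
  expect_false(nuc$mask[i2[1], i2[2], i2[3]])
  expect_equal(max(nucarch:::label_components(nuc$mask)), 1L)
})

test_that("the mask is invariant under intensity rescaling", {
  g <- grid_spec(c(20, 32, 32), c(0.5, 0.25, 0.25))
  s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.2),
                                 channel_names = "dapi"), seed = 8)
  m1 <- segment_nucleus(s$data$dapi, g)
  m2 <- segment_nucleus(s$data$dapi * 3.7, g)
  expect_identical(m1$mask, m2$mask)
})

test_that("segmentation is equivariant to whole-voxel translations", {
  g <- grid_spec(c(26, 40, 40), c(0.5, 0.25, 0.25))
  s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.2),
                                 noise = quiet_noise,
                                 channel_names = "dapi"), seed = 4)
  dapi <- s$data$dapi
  shift <- c(2, 3, -2)
  shifted <- array(0, g$shape)
  shifted[(1 + shift[1]):g$shape[1], (1 + shift[2]):g$shape[2],
          1:(g$shape[3] + shift[3])] <-
    dapi[1:(g$shape[1] - shift[1]), 1:(g$shape[2] - shift[2]),
         (1 - shift[3]):g$shape[3]]
  m1 <- segment_nucleus(dapi, g)$mask
  m2 <- segment_nucleus(shifted, g)$mask
  m1s <- array(FALSE, g$shape)
  m1s[(1 + shift[1]):g$shape[1], (1 + shift[2]):g$shape[2],
      1:(g$shape[3] + shift[3])] <-
    m1[1:(g$shape[1] - shift[1]), 1:(g$shape[2] - shift[2]),
       (1 - shift[3]):g$shape[3]]
  expect_identical(m2, m1s)
})

test_that("territory detection separates distant blobs and merges close ones", {
  g <- grid_spec(c(32, 56, 56), c(0.5, 0.25, 0.25))
  s_far <- render_scene(scene_config(g, nucleus_shape_params(radius = 3),
                                     homolog_separation = 4,
                                     noise = quiet_noise), seed = 6)
  nuc <- attr(s_far, "ground_truth")$mask
  expect_length(detect_territories(s_far$data$paint, nuc), 2)

  s_near <- render_scene(scene_config(g, nucleus_shape_params(radius = 3),
                                      homolog_separation = 0.3,
                                      psf_sigma = 0.25,
                                      noise = quiet_noise), seed = 6)
  nuc2 <- attr(s_near, "ground_truth")$mask
  expect_length(detect_territories(s_near$data$paint, nuc2), 1)

  expect_length(detect_territories(array(0, g$shape), nuc), 0)
})

test_that("territory count matches truth when separation exceeds 4x PSF", {
  g <- grid_spec(c(28, 48, 48), c(0.5, 0.25, 0.25))
  for (sep in c(1.5, 2.5, 3.5)) {
    s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.8),
                                   homolog_separation = sep,
                                   psf_sigma = 0.25,
                                   homolog_blob_sigma = 0.2,
                                   noise = quiet_noise), seed = 13)
    nuc <- attr(s, "ground_truth")$mask
    expect_length(detect_territories(s$data$paint, nuc, min_volume = 0.05), 2)
  }
})
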