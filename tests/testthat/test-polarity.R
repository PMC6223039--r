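# Epipolarity scoring, polarity calls, per-repeat percentages.

test_that("uniform marks score ~0.5 and one-sided marks score 1", {
  g <- grid_spec(c(26, 26, 26), rep(0.25, 3))
  ball <- ball_array(g$shape, g$spacing, rep(3.25, 3), 2.6)
  m <- nuclear_mask(ball, g)
  expect_lt(abs(epipolarity_score(array(1, g$shape), m)$score - 0.5), 0.05)

  # all intensity strictly on one side of an axis plane through the centroid
  half <- array(0, g$shape)
  ctr_x <- mean(which(ball, arr.ind = TRUE)[, 3])
  for (x in seq_len(g$shape[3])) if (x > ctr_x) half[, , x] <- 10
  half[!ball] <- 0
  expect_equal(epipolarity_score(half, m)$score, 1)
  expect_error(epipolarity_score(array(0, g$shape), m), "no signal")
})

test_that("the 200-direction lattice is within 0.02 of a 5000-direction search", {
  g <- grid_spec(c(20, 32, 32), c(0.4, 0.25, 0.25))
  for (kappa in c(2, 5)) {
    s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.6),
                                   mark_polarity_kappa = kappa,
                                   noise = quiet_noise,
                                   channel_names = c("dapi", "mark")),
                      seed = 40 + kappa)
    m <- attr(s, "ground_truth")$mask
    fast <- epipolarity_score(s$data$mark, m)$score
    dense <- dense_polarity(s$data$mark, m, 5000L)
    expect_lt(abs(fast - dense), 0.02)
  }
})

test_that("the score is exactly invariant under 90-degree rotations", {
  g <- grid_spec(c(24, 24, 24), rep(0.3, 3))
  s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.4),
                                 mark_polarity_kappa = 4,
                                 noise = quiet_noise,
                                 channel_names = c("dapi", "mark")),
                    seed = 17)
  m <- attr(s, "ground_truth")$mask
  mark <- s$data$mark
  s0 <- epipolarity_score(mark, m)$score
  # rotate 90 degrees about z: (z, y, x) -> (z, x, ny - y + 1)
  rot <- function(a) aperm(a[, dim(a)[2]:1, ], c(1, 3, 2))
  mark_r <- rot(mark)
  mask_r <- nuclear_mask(rot(m$mask), g, check = FALSE)
  expect_equal(epipolarity_score(mark_r, mask_r)$score, s0, tolerance = 1e-12)
})

test_that("the score is scale-invariant and offsets compress it toward 0.5", {
  g <- grid_spec(c(20, 32, 32), c(0.4, 0.25, 0.25))
  s <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.6),
                                 mark_polarity_kappa = 6,
                                 noise = quiet_noise,
                                 channel_names = c("dapi", "mark")),
                    seed = 23)
  m <- attr(s, "ground_truth")$mask
  mark <- s$data$mark
  base <- epipolarity_score(mark, m)$score
  expect_equal(epipolarity_score(mark * 4.2, m)$score, base, tolerance = 1e-12)
  expect_lte(epipolarity_score(mark + 500, m)$score, base)
})

test_that("the score rises monotonically with the generator concentration", {
  g <- grid_spec(c(18, 28, 28), c(0.4, 0.25, 0.25))
  kappas <- c(0, 1, 2, 5, 10)
  mean_score <- vapply(kappas, function(k) {
    mean(vapply(1:5, function(s) {
      sc <- render_scene(scene_config(g, nucleus_shape_params(radius = 2.2),
                                      mark_polarity_kappa = k,
                                      noise = quiet_noise,
                                      channel_names = c("dapi", "mark")),
                         seed = 300 + 10 * k + s)
      m <- attr(sc, "ground_truth")$mask
      epipolarity_score(sc$data$mark, m)$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_score) > 0))
})

test_that("polarity calls respect tau and the isotropic null is rarely polar", {
  expect_true(classify_polar(0.71, tau = 0.7))
  expect_true(classify_polar(0.7, tau = 0.7))
  expect_false(classify_polar(0.5, tau = 0.7))
  expect_false(classify_polar(0.5, tau = 0.51))
  expect_error(classify_polar(0.8, tau = 0.5), "tau")
  expect_error(classify_polar(0.8, tau = 1.2), "tau")
})

test_that("percent polar aggregates per repeat with the frozen SEM example", {
  # repeats at 50%, 70%, 60% -> mean 60, SEM 10/sqrt(3) = 5.7735
  polar <- c(rep(c(TRUE, FALSE), c(5, 5)),
             rep(c(TRUE, FALSE), c(7, 3)),
             rep(c(TRUE, FALSE), c(6, 4)))
  rep_id <- rep(1:3, each = 10)
  r <- percent_polar(polar, rep_id)
  expect_equal(r$percent, 60)
  expect_equal(r$sem, 10 / sqrt(3), tolerance = 1e-9)
  expect_equal(r$sem, 5.7735, tolerance = 1e-4)

  expect_warning(r1 <- percent_polar(c(TRUE, TRUE, TRUE, FALSE,
                                       FALSE, FALSE, FALSE, FALSE,
                                       FALSE, FALSE)), "SEM")
  expect_equal(r1$percent, 30)
  expect_equal(r1$sem, 0)

  r2 <- percent_polar(rep(TRUE, 9), rep(1:3, 3))
  expect_equal(r2$percent, 100)
  expect_equal(r2$sem, 0)
  expect_error(percent_polar(logical(0)), "no scored cells")
})
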