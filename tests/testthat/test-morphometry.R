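# Volume, NSF, solidity, channel volumes, peripherality.

test_that("volume is count times voxel volume and matches a brute-force count", {
  g <- grid_spec(c(10, 10, 10), c(0.5, 0.5, 0.5))
  a <- array(FALSE, g$shape); a[3:6, 3:7, 2:6] <- TRUE
  m <- nuclear_mask(a, g)
  expect_equal(nuclear_volume(m), sum(a) * 0.125)
  expect_equal(nuclear_volume(m), brute_volume(a, g$spacing))
  # 1000 voxels at 0.5 um isotropic -> 125 um^3
  b <- array(FALSE, c(12, 12, 12)); b[2:11, 2:11, 2:11] <- TRUE
  expect_equal(nuclear_volume(nuclear_mask(b, grid_spec(c(12, 12, 12),
                                                        rep(0.5, 3)))), 125)
})

test_that("NSF anchors at 1 for spheres and matches the spheroid closed form", {
  g <- grid_spec(c(36, 36, 36), rep(0.25, 3))
  m <- make_nucleus_mask(nucleus_shape_params(radius = 3), g, seed = 1)
  expect_lt(abs(nuclear_shape_factor(m) - 1), 0.02)

  g2 <- grid_spec(c(60, 36, 36), rep(0.25, 3))
  m2 <- make_nucleus_mask(nucleus_shape_params(radius = 3,
                                               axis_ratios = c(2, 1, 1)),
                          g2, seed = 1)
  a <- 6; b <- 3; e <- sqrt(1 - b^2 / a^2)
  A <- 2 * pi * b^2 * (1 + a / (b * e) * asin(e))
  V <- 4 / 3 * pi * a * b^2
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  expect_lt(abs(nuclear_shape_factor(m2) - psi) / psi, 0.03)
})

test_that("NSF is invariant to translation and decreases with pocket depth", {
  g <- grid_spec(c(40, 40, 40), rep(0.25, 3))
  a <- ball_array(g$shape, g$spacing, c(4, 4, 4), 2.2)
  b <- array(FALSE, g$shape)
  b[4:40, 3:39, 2:38] <- a[1:37, 1:37, 1:37]
  expect_equal(nuclear_shape_factor(nuclear_mask(a, g)),
               nuclear_shape_factor(nuclear_mask(b, g)), tolerance = 1e-10)

  gg <- grid_spec(c(36, 36, 36), rep(0.25, 3))
  nsf <- vapply(c(0, 0.7, 1.4, 2), function(dep) {
    m <- make_nucleus_mask(
      nucleus_shape_params(radius = 3,
                           invagination_count = if (dep > 0) 1L else 0L,
                           invagination_depth = dep,
                           invagination_radius = 1),
      gg, seed = 2)
    nuclear_shape_factor(m)
  }, numeric(1))
  expect_true(all(diff(nsf) < 0))
})

test_that("NSF refuses masks that are too small for a surface estimate", {
  g <- grid_spec(c(8, 8, 8), rep(0.25, 3))
  a <- array(FALSE, g$shape); a[4:5, 4:5, 4:5] <- TRUE
  expect_error(nuclear_shape_factor(nuclear_mask(a, g)), "100")
})

test_that("solidity decreases monotonically with pocket depth", {
  g <- grid_spec(c(36, 36, 36), rep(0.25, 3))
  sol <- vapply(c(0.8, 1.4, 2), function(dep) {
    m <- make_nucleus_mask(
      nucleus_shape_params(radius = 3, invagination_count = 1L,
                           invagination_depth = dep, invagination_radius = 1),
      g, seed = 2)
    solidity(m)
  }, numeric(1))
  expect_true(all(diff(sol) < 0))
  expect_true(classify_invaginated(0.9))
  expect_false(classify_invaginated(0.95))
  # degenerate planar mask
  gp <- grid_spec(c(6, 6, 6), rep(0.25, 3))
  pl <- array(FALSE, gp$shape); pl[3, 2:5, 2:5] <- TRUE
  expect_error(solidity(nuclear_mask(pl, gp)), "planar")
})

test_that("channel volume counts supra-threshold voxels within the mask", {
  g <- grid_spec(c(14, 14, 14), rep(0.5, 3))
  a <- ball_array(g$shape, g$spacing, c(3.5, 3.5, 3.5), 2.4)
  m <- nuclear_mask(a, g)
  expect_equal(channel_volume(array(0, g$shape), m), 0)
  # binary shell of known voxel count
  dt <- nucarch:::distance_to_background(a, g)
  shell <- a & dt <= 0.75
  expect_equal(channel_volume(array(1000 * shell, g$shape), m),
               sum(shell) * voxel_volume(g))
  # doubling the shell thickness roughly doubles the measured volume
  shell2 <- a & dt <= 1.5
  v1 <- channel_volume(array(1000 * shell, g$shape), m)
  v2 <- channel_volume(array(1000 * shell2, g$shape), m)
  expect_lt(abs(v2 / v1 - sum(shell2) / sum(shell)), 1e-9)
})

test_that("peripherality matches its definition, its oracle and the edges", {
  # spacings and depth chosen so no voxel distance ties the threshold exactly
  g <- grid_spec(c(12, 12, 12), c(0.37, 0.29, 0.31))
  a <- rand_ellipsoid(21, g$shape, g$spacing)
  m <- nuclear_mask(a, g, check = FALSE)
  uni <- array(1, g$shape)
  p <- peripherality_index(uni, m, shell_depth = 0.45)
  expect_equal(p, brute_peripherality(uni, a, g$spacing, 0.45),
               tolerance = 1e-12)
  # uniform intensity: shell fraction + core fraction = 1 exactly
  dt <- nucarch:::distance_to_background(a, g)
  core_frac <- sum(a & dt > 0.45) / sum(a)
  expect_equal(p + core_frac, 1)

  # all intensity in the shell -> 1; all at the centre of a big ball -> 0
  gg <- grid_spec(c(26, 26, 26), rep(0.25, 3))
  ball <- ball_array(gg$shape, gg$spacing, c(3.25, 3.25, 3.25), 3)
  mb <- nuclear_mask(ball, gg)
  dtb <- nucarch:::distance_to_background(ball, gg)
  shell_ch <- array(0, gg$shape); shell_ch[ball & dtb <= 0.5] <- 5
  expect_equal(peripherality_index(shell_ch, mb, 0.5), 1)
  centre_ch <- array(0, gg$shape); centre_ch[13, 13, 13] <- 9
  expect_equal(peripherality_index(centre_ch, mb, 0.5), 0)
  expect_error(peripherality_index(uni, m, shell_depth = 0), "shell_depth")
})
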