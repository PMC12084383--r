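test_that("the ten-step walk is calibrated to the requested mean module", {
  expect_equal(random_walk_vector(0), cbind(dx = 0, dy = 0))
  set.seed(9); a <- random_walk_vector(c(5, 5))
  set.seed(9); b <- random_walk_vector(c(5, 5))
  expect_identical(a, b)                       # deterministic under a seed
  expect_error(random_walk_vector(-1), "non-negative")
  set.seed(10)
  v <- random_walk_vector(rep(8.7, 1e5))
  m <- mean(sqrt(v[, 1]^2 + v[, 2]^2))
  expect_lt(abs(m - 8.7), 0.05)                # Monte-Carlo mean oracle
  # resultant directions are isotropic
  ang <- atan2(v[, 2], v[, 1])
  expect_lt(sqrt(mean(cos(ang))^2 + mean(sin(ang))^2), 0.02)
})

test_that("displacements compose by vector sum", {
  expect_equal(compose_displacement(c(1, 0), c(1, 0), c(1, 0)), c(3, 0))
  expect_equal(compose_displacement(c(0, 0), c(0, 0), c(0, 0)), c(0, 0))
})

test_that("effective components rescale so the fractions sum to one", {
  prm <- nih3t3_like_params(r_frac = 0.5, p_frac = 0.3, b_frac = 0.2,
                            bias_angle = 0)
  # immobile cell: everything zero
  z <- effective_components(prm, 0)
  expect_equal(z$rand, 0); expect_equal(z$pers, 0)
  expect_equal(unname(z$bias_vec), matrix(0, 1, 2))
  # no extra bias: the plain fractions of d_tot
  e <- effective_components(prm, 1)
  d_tot <- prm$d_ref
  expect_equal(e$rand, 0.5 * d_tot)
  expect_equal(e$pers, 0.3 * d_tot)
  expect_equal(unname(e$bias_vec[1, ]), c(0.2 * d_tot, 0))
  # extra bias doubling |bias|: r', p' shrink, shares still sum to 1
  eb <- matrix(c(0.2 * d_tot, 0), 1, 2)
  e2 <- effective_components(prm, 1, eb)
  b2 <- sqrt(sum(e2$bias_vec^2)) / d_tot
  expect_equal(b2, 0.4)
  expect_equal(e2$rand / d_tot + e2$pers / d_tot + b2, 1)
  expect_equal(e2$rand / e2$pers, 0.5 / 0.3)
  # bias beyond d_tot is capped and r' = p' = 0
  e3 <- effective_components(prm, 1, matrix(c(5 * d_tot, 0), 1, 2))
  expect_equal(e3$rand, 0); expect_equal(e3$pers, 0)
  expect_equal(sqrt(sum(e3$bias_vec^2)), d_tot)
})

test_that("repulsion follows the linear falloff and its symmetries", {
  prm <- nih3t3_like_params()
  R <- prm$repulsion_radius
  # no neighbours in radius
  expect_equal(repulsion_bias(c(0, 1000), c(0, 0), prm),
               matrix(0, 2, 2))
  # one neighbour due east at half radius pushes due west
  v <- repulsion_bias(c(0, R / 2), c(0, 0), prm)
  expect_equal(v[1, 1], -prm$repulsion_sensitivity * prm$d_ref / 2)
  expect_equal(v[1, 2], 0)
  expect_equal(v[2, 1], -v[1, 1])              # equal and opposite
  # two equidistant neighbours at +-45 degrees: resultant bisects away
  x <- c(0, 12, 12); y <- c(0, 12, -12)
  v3 <- repulsion_bias(x, y, prm)
  expect_lt(v3[1, 1], 0)
  expect_equal(v3[1, 2], 0, tolerance = 1e-12)  # y components cancel
})

test_that("gradient bias points uphill, is capped, and vanishes off-field", {
  prm <- nih3t3_like_params()
  flat <- uniform_field(400, 400, 2, bias_gain = 10)
  g <- gradient_bias(flat, c(100, 300), c(100, 300), prm)
  expect_equal(g, cbind(c(0, 0), c(0, 0)))
  # linear ramp along +x
  nx <- 41; ny <- 41
  ramp <- scalar_field(outer(seq_len(nx), seq_len(ny),
                             function(i, j) 0.01 * i * 10), 10,
                       bias_gain = 5)
  g2 <- gradient_bias(ramp, 200, 200, prm)
  expect_gt(g2[1, 1], 0)
  expect_equal(g2[1, 2], 0)
  expect_equal(g2[1, 1], 5 * 0.01 * prm$sensing_distance)
  # a steep ramp saturates exactly at the cap
  steep <- scalar_field(outer(seq_len(nx), seq_len(ny),
                              function(i, j) 5 * i), 10, bias_gain = 50)
  g3 <- gradient_bias(steep, 200, 200, prm)
  expect_equal(sqrt(sum(g3^2)), prm$gradient_cap)
})

test_that("constraints stop cells at walls and block-region boundaries", {
  plate <- new_plate(500, 500)
  # free move
  p <- apply_constraints(100, 100, 30, -20, plate)
  expect_equal(c(p$x, p$y), c(130, 80))
  # stop at the plate edge
  p2 <- apply_constraints(480, 250, 100, 0, plate)
  expect_equal(c(p2$x, p2$y), c(500, 250))
  # blocked region halts entry at its boundary
  plate$constraints$wall <- list(id = "wall", type = "block",
                                 x0 = 200, x1 = 300, y0 = 0, y1 = 500)
  p3 <- apply_constraints(150, 100, 100, 0, plate)
  expect_equal(p3$x, 200, tolerance = 1e-6)
  # slowing region scales the displacement
  plate$constraints$mud <- list(id = "mud", type = "slow",
                                x0 = 0, x1 = 180, y0 = 0, y1 = 500,
                                factor = 0.25)
  p4 <- apply_constraints(100, 100, 40, 0, plate)
  expect_equal(p4$x, 110)
})

test_that("G0 cells move less than cycling cells, random paths are isotropic", {
  prm <- nih3t3_like_params()
  plate <- test_plate(400, width = 20000, height = 20000, seed = 4,
                      params = prm)
  plate$cells$phase <- rep(c("G1", "G0"), 200)
  set.seed(8)
  plate <- step_motion(plate, prm, 20)
  d <- sqrt(plate$cells$pdx^2 + plate$cells$pdy^2)
  expect_gt(mean(d[plate$cells$phase == "G1"]),
            1.5 * mean(d[plate$cells$phase == "G0"]))
  # no bias configured: displacement directions are uniform (R ~ 0)
  circ <- circular_R(cbind(plate$cells$pdx, plate$cells$pdy))
  expect_lt(circ$R, 0.12)
})
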