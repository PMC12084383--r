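test_that("field decay is an exact exponential semigroup", {
  f <- uniform_field(100, 100, 8, half_life = 60)
  expect_equal(decay_field(f, 60)$lattice, f$lattice / 2)
  inf_f <- uniform_field(100, 100, 8, half_life = Inf)
  expect_identical(decay_field(inf_f, 500)$lattice, inf_f$lattice)
  two_half <- decay_field(decay_field(f, 35), 35)
  one_full <- decay_field(f, 70)
  expect_equal(two_half$lattice, one_full$lattice)
})

test_that("cells dig local pits that steer neighbours away", {
  prm <- nih3t3_like_params()
  f <- uniform_field(400, 400, 1, cell_size = 10, degradable_by_cells = TRUE,
                     bias_gain = 20)
  expect_equal(degrade_locally(f, numeric(0), numeric(0), 20, 0.002, 15),
               f)                                     # no cells: identity
  g <- f
  for (i in 1:10) g <- degrade_locally(g, 200, 200, 20, 0.002, 15)
  # pit centred on the cell
  expect_lt(sample_field(g, 200, 200), sample_field(g, 260, 200))
  expect_equal(sample_field(g, 390, 390), 1)
  # a second cell nearby is pushed away from the pit
  bias <- gradient_bias(g, 230, 200, prm)
  expect_gt(bias[1, 1], 0)
  # concentrations never go negative no matter how long degradation runs
  for (i in 1:500) g <- degrade_locally(g, c(200, 210), c(200, 200), 20,
                                        0.01, 15)
  expect_true(all(g$lattice >= 0))
  expect_error(degrade_locally(uniform_field(50, 50, 1), 10, 10, 20,
                               0.01, 15), "degradable")
})

test_that("local confluence equals the brute-force computation", {
  set.seed(14)
  prm <- nih3t3_like_params()
  plate <- test_plate(250, width = 700, height = 700, params = prm)
  conf <- local_confluence(plate, 60)
  want <- brute_confluence(plate$cells$x, plate$cells$y,
                           plate$cells$surface, 60)
  expect_equal(conf, want)
  # empty neighbourhood and clamping
  lone <- test_plate(1, params = prm)
  expect_equal(local_confluence(lone, 60), numeric(1))
  heap <- new_plate(100, 100)
  heap$cells <- seed_cells(60, prm, 100, 100, init = "staggered",
                           x = rep(50, 60), y = rep(50, 60))
  expect_equal(max(local_confluence(heap, 60)), 1)
})

test_that("medium, molecule and gradient events reshape the plate", {
  prm <- nih3t3_like_params()
  plate <- test_plate(5, params = prm)
  plate <- apply_event(plate, event_spec(0, "moleculeAddition",
                                         name = "antibiotic",
                                         concentration = 1.5), prm)
  expect_equal(plate$medium$molecules$antibiotic, 1.5)
  plate <- apply_event(plate, event_spec(0, "mediumChange",
                                         serum_type = "cs",
                                         serum_level = 2.5), prm)
  expect_equal(plate$medium$serum_level, 2.5)
  expect_length(plate$medium$molecules, 0)     # medium change washes drugs out
  plate <- apply_event(plate, event_spec(0, "gradientAddition",
                                         name = "attract", value = 3,
                                         region = list(x0 = 0, x1 = 100,
                                                       y0 = 0, y1 = 500),
                                         bias_gain = 10), prm)
  expect_equal(sample_field(plate$fields$attract, 50, 250), 3)
  expect_equal(sample_field(plate$fields$attract, 400, 250), 0)
  plate <- apply_event(plate, event_spec(0, "constraintAddition", id = "w1",
                                         type = "block", x0 = 0, x1 = 10,
                                         y0 = 0, y1 = 10), prm)
  expect_length(plate$constraints, 1)
  plate <- apply_event(plate, event_spec(0, "constraintRemoval", id = "w1"),
                       prm)
  expect_length(plate$constraints, 0)
})

test_that("a scratch damages exactly the cells in the band and seeds debris", {
  prm <- nih3t3_like_params()
  plate <- new_plate(600, 400)
  set.seed(15)
  plate$cells <- seed_cells(100, prm, 600, 400, init = "staggered")
  inside <- plate$cells$x >= 250 & plate$cells$x <= 350
  plate <- apply_event(plate, event_spec(0, "scratchOnPlate",
                                         x0 = 250, x1 = 350, y0 = 0,
                                         y1 = 400, debris_value = 2,
                                         debris_half_life = 240), prm)
  expect_equal(sum(plate$cells$phase == "DAMAGED"), sum(inside))
  expect_true(all(plate$cells$damage[inside] == 1))
  expect_equal(sample_field(plate$fields$debris, 300, 200), 2)
  expect_equal(sample_field(plate$fields$debris, 100, 200), 0)
  expect_equal(plate$fields$debris$half_life, 240)
})

test_that("transfection marks cells at the stated efficiency", {
  prm <- nih3t3_like_params()
  plate <- test_plate(800, width = 5000, height = 5000, params = prm)
  none <- apply_event(plate, event_spec(0, "transfection", gene = "gfp",
                                        efficiency = 0), prm)
  expect_false(any(vapply(none$cells$genes, function(g) "gfp" %in% g, TRUE)))
  set.seed(16)
  some <- apply_event(plate, event_spec(0, "transfection", gene = "gfp",
                                        efficiency = 0.3), prm)
  k <- sum(vapply(some$cells$genes, function(g) "gfp" %in% g, TRUE))
  sigma <- sqrt(800 * 0.3 * 0.7)
  expect_lt(abs(k - 240), 4 * sigma)
})

test_that("viral infection sets timers and spreads on lysis", {
  prm <- vero_e6_like_params()
  plate <- make_fixture("confluent_layer",
                        list(width = 400, height = 400, pitch = 40,
                             cell_params = prm), seed = 17)
  plate <- apply_event(plate, event_spec(0, "viralInfection", n_initial = 1,
                                         lysis_time = 540, radius = 55,
                                         prob = 0.9), prm)
  expect_equal(sum(!is.na(plate$cells$infect)), 1)
  expect_equal(plate$infection$lysis_time, 540)
  # march time forward: the infected cell lyses and infects neighbours
  set.seed(18)
  for (i in 1:28) plate <- update_vitality(plate, prm, 20)
  expect_gt(sum(plate$cells$phase == "DEAD"), 0)
  expect_gt(sum(!is.na(plate$cells$infect) & plate$cells$phase != "DEAD"), 0)
})

test_that("unknown event kinds are rejected at validation", {
  cfg <- scenario_config("growth_24h", days = 1)
  raw <- unclass(cfg)
  raw$events <- list(list(time = 10, kind = "earthquake"))
  class(raw) <- "list"
  raw$cell_params <- NULL
  expect_error(validate_config(raw), "unknown kind")
  raw$events <- list(list(time = 1e9, kind = "mediumChange",
                          serum_level = 5))
  expect_error(validate_config(raw), "duration")
})
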