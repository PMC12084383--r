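test_that("track sets validate their structure", {
  f <- data.frame(cell = c(1, 1, 1), time = c(0, 20, 40), x = 0:2, y = 0:2)
  ts <- track_set(f, 20)
  expect_s3_class(ts, "track_set")
  bad <- f; bad$time <- c(0, 20, 20)
  expect_error(track_set(bad, 20), "strictly increasing")
  expect_error(track_set(f, 20, origin = c("1" = "teleported")), "origin")
})

test_that("the component estimator round-trips the generator", {
  # pure random at the packaged module
  tr <- simulate_tracks(50, 72, rand = 8.7, pers = 0, bias = 0, seed = 21)
  e <- estimate_components(tr)
  expect_lt(abs(e$rand - 8.7), 0.5)
  expect_lt(e$pers, 0.5)
  expect_lt(e$bias, 0.5)
  # mixed movement: persistence and bias of 4 um on top of the random walk
  tm <- simulate_tracks(50, 72, rand = 8.7, pers = 4, bias = 4,
                        bias_angle = 0, seed = 22)
  em <- estimate_components(tm)
  expect_lt(abs(em$pers - 4), 0.5)
  expect_lt(abs(em$bias - 4), 0.5)
  expect_lt(abs(em$bias_angle), 15 * pi / 180)
})

test_that("round-trip recovery holds across a grid of settings", {
  for (cfg in list(c(6, 0, 0), c(6, 3, 0), c(6, 0, 3), c(9, 3, 3))) {
    tr <- simulate_tracks(50, 72, rand = cfg[1], pers = cfg[2],
                          bias = cfg[3], seed = sum(cfg) * 7)
    e <- estimate_components(tr)
    for (k in 1:3) {
      est <- c(e$rand, e$pers, e$bias)[k]
      if (cfg[k] > 0) expect_lt(abs(est - cfg[k]) / cfg[k], 0.1)
      else expect_lt(est, 0.5)
    }
  }
})

test_that("identical displacements are read as pure bias", {
  f <- data.frame(cell = rep(1:3, each = 5), time = rep(0:4 * 10, 3))
  f$x <- 2 * (f$time / 10); f$y <- 1 * (f$time / 10)
  e <- estimate_components(track_set(f, 10))
  expect_equal(e$bias, sqrt(5), tolerance = 1e-9)
  expect_equal(e$pers, 0)
  expect_equal(e$rand, 0, tolerance = 1e-9)
})

test_that("MSD curves average over cells and all start frames", {
  # stationary cells: MSD identically zero
  f <- data.frame(cell = rep(1:2, each = 4), time = rep(0:3 * 10, 2),
                  x = 0, y = 0)
  m <- msd_curve(track_set(f, 10))
  expect_true(all(m$msd == 0))
  # ballistic motion at speed s: MSD(tau) = (s tau)^2
  s <- 0.7
  fb <- data.frame(cell = 1, time = 0:10 * 10, x = s * 0:10 * 10, y = 0)
  mb <- msd_curve(track_set(fb, 10))
  expect_equal(mb$msd, (s * mb$lag)^2)
  expect_equal(mb$n_pairs, 10:1)               # overlapping window counts
  # a 2-point path yields a single lag entry
  f2 <- data.frame(cell = 1, time = c(0, 10), x = c(0, 3), y = c(0, 4))
  m2 <- msd_curve(track_set(f2, 10))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$msd, 25)
})

test_that("the anomalous-diffusion fit recovers known exponents", {
  # exact self-fit on k t^1.5
  lag <- 10 * 1:20
  syn <- data.frame(lag = lag, msd = 3 * lag^1.5, n_pairs = 21 - 1:20)
  fit <- fit_alpha(syn)
  expect_equal(fit$alpha, 1.5, tolerance = 1e-6)
  expect_equal(fit$k, 3, tolerance = 1e-6)
  # ballistic fixture: alpha ~ 2
  st <- make_fixture("straight_paths", seed = 2)
  expect_equal(fit_alpha(msd_curve(st))$alpha, 2, tolerance = 1e-6)
  # Brownian fixture: alpha ~ 1 (diffusion theory)
  br <- make_fixture("brownian_paths", list(n_cells = 150), seed = 3)
  expect_lt(abs(fit_alpha(msd_curve(br, max_lag = 30))$alpha - 1), 0.1)
})

test_that("the persistence fit recovers the Fuerth parameters", {
  S <- 1; P <- 30
  lag <- 5 * 1:40
  msd <- data.frame(lag = lag,
                    msd = 2 * S^2 * P * (lag - P * (1 - exp(-lag / P))),
                    n_pairs = 41 - 1:40)
  fit <- fit_persistence(msd)
  expect_equal(fit$S, 1, tolerance = 1e-5)
  expect_equal(fit$P, 30, tolerance = 1e-4)
  expect_false(fit$at_bound)
  # OU-velocity tracks have the same MSD law: recover P within 10%
  ou <- make_fixture("ou_persistent_paths",
                     list(n_cells = 200, n_frames = 80, S = 1, P = 30),
                     seed = 4)
  ofit <- fit_persistence(msd_curve(ou, max_lag = 40))
  expect_lt(abs(ofit$P - 30) / 30, 0.1)
  # small-lag ballistic limit of the fitted law
  expect_equal(2 * S^2 * P * (1 - P * (1 - exp(-1 / P))) / 1,
               S^2 * 1, tolerance = 0.02)
})

test_that("linearity, coherence and circular statistics match hand geometry", {
  st <- make_fixture("straight_paths", seed = 5)
  expect_equal(linearity(st), 1)
  # out-and-back path: linearity 0
  ob <- track_set(data.frame(cell = 1, time = c(0, 10, 20),
                             x = c(0, 5, 0), y = 0), 10)
  expect_equal(linearity(ob), 0)
  # two legs (1,0) then (0,1): net sqrt(2) over length 2
  l2 <- track_set(data.frame(cell = 1, time = c(0, 10, 20),
                             x = c(0, 1, 1), y = c(0, 0, 1)), 10)
  expect_equal(linearity(l2), sqrt(2) / 2, tolerance = 1e-9)

  # coherence: parallel nets = 1; opposite nets = 0; orthogonal = sqrt(2)/2
  par <- track_set(data.frame(cell = rep(1:2, each = 2),
                              time = rep(c(0, 10), 2),
                              x = c(0, 4, 1, 5), y = 0), 10)
  expect_equal(coherence(par), 1)
  opp <- track_set(data.frame(cell = rep(1:2, each = 2),
                              time = rep(c(0, 10), 2),
                              x = c(0, 4, 4, 0), y = 0), 10)
  expect_equal(coherence(opp), 0)
  ort <- track_set(data.frame(cell = rep(1:2, each = 2),
                              time = rep(c(0, 10), 2),
                              x = c(0, 3, 0, 0), y = c(0, 0, 0, 3)), 10)
  expect_equal(coherence(ort), sqrt(2) / 2)

  expect_equal(circular_R(cbind(c(1, 2, 3), c(1, 2, 3)))$R, 1)
  expect_equal(circular_R(cbind(c(1, -1), c(0, 0)))$R, 0)
  set.seed(6)
  th <- runif(20000, 0, 2 * pi)
  expect_lt(circular_R(cbind(cos(th), sin(th)))$R, 0.02)
})

test_that("component contributions project onto displacement and sum to it", {
  # pure-bias straight motion: bias contribution ~ displacement, others ~ 0
  tb <- simulate_tracks(20, 40, rand = 0, pers = 0, bias = 5, seed = 7)
  cc <- component_contributions(tb, window = 200)
  expect_gt(nrow(cc), 5)
  expect_equal(cc$bias, cc$displacement, tolerance = 1e-6)
  expect_equal(max(abs(cc$random)), 0, tolerance = 1e-6)
  # pure-random: random dominates, bias negligible
  trd <- simulate_tracks(40, 72, rand = 8, seed = 8)
  ccr <- component_contributions(trd, window = 720)
  expect_gt(mean(ccr$random), 10 * abs(mean(ccr$bias)))
  # the three contributions reconstruct the mean displacement module
  expect_equal(ccr$random + ccr$persistence + ccr$bias, ccr$displacement,
               tolerance = 1e-6)
  # a window longer than the track yields an empty series
  expect_equal(nrow(component_contributions(tb, window = 1e6)), 0)
})

test_that("displacement densities integrate to one and sit where expected", {
  trd <- simulate_tracks(40, 60, rand = 8, seed = 9)
  den <- displacement_density(trd, lag = 20)
  dx <- diff(den$x[1:2]); dy <- diff(den$y[1:2])
  expect_equal(sum(den$z) * dx * dy, 1, tolerance = 0.05)
  mode_idx <- which(den$z == max(den$z), arr.ind = TRUE)
  expect_lt(abs(den$x[mode_idx[1]]), 4)        # mode near the origin
  tb <- simulate_tracks(40, 60, rand = 4, bias = 6, seed = 10)
  denb <- displacement_density(tb, lag = 20)
  mb <- which(denb$z == max(denb$z), arr.ind = TRUE)
  expect_gt(denb$x[mb[1]], 2)                  # mode shifted along the bias
})

test_that("rMSD never exceeds the observed MSD when order is present", {
  tm <- simulate_tracks(50, 72, rand = 6, pers = 3, bias = 3, seed = 11)
  e <- estimate_components(tm)
  m <- msd_curve(tm, max_lag = 30)
  rm <- rmsd_random(e$rand, m$lag, tm$interval)
  expect_true(all(rm <= m$msd))
  # alpha grows with persistence/bias and stays in the physical range
  a_rand <- fit_alpha(msd_curve(simulate_tracks(50, 72, rand = 8.7,
                                                seed = 12),
                                max_lag = 30))$alpha
  a_mix <- fit_alpha(msd_curve(tm, max_lag = 30))$alpha
  expect_gt(a_mix, a_rand)
  expect_gt(a_rand, 0.9); expect_lt(a_mix, 2.05)
})

test_that("the motion summary carries the full parameter column set", {
  tm <- simulate_tracks(30, 50, rand = 7, pers = 2, bias = 2, seed = 13)
  s <- motion_summary(tm)
  expect_true(all(c("rand_module", "pers_module", "bias_module", "alpha",
                    "persistence_time", "linearity", "coherence", "R",
                    "msd_final", "rmsd_final") %in% names(s)))
  sn <- motion_summary(tm, normalise_modules = TRUE)
  expect_equal(sn$pers_module, s$pers_module / s$rand_module)
})
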