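test_that("an inert cell yields identical frames at every interval", {
  prm <- nih3t3_like_params(
    transition_edges = list(transition_edge("G1", "G1c", 0, factors = list())),
    phase_motility = c(G1 = 0, G1c = 0, S = 0, G2 = 0, M = 0, G0 = 0,
                       APO = 0, DAMAGED = 0, DEAD = 0),
    alpha_growth = 0)
  cfg <- list(plate = list(width = 200, height = 200, serum_level = 10),
              cell_type = prm,
              seeding = list(list(positions = data.frame(x = 100, y = 100),
                                  init = "staggered")),
              events = list(),
              run = list(duration_min = 200, interval_min = 20, seed = 5))
  run <- run_experiment(cfg)
  expect_equal(nrow(run$frames), 11)
  expect_equal(unique(run$frames$x), 100)
  expect_equal(unique(run$frames$y), 100)
  expect_equal(unique(run$frames$phase), run$frames$phase[1])
  expect_equal(unique(run$history$n_live), 1L)
})

test_that("runs are bit-identical for a fixed seed", {
  cfg <- scenario_config("growth_24h", seed = 33, days = 1, count = 40)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$frames, b$frames)
  expect_identical(a$paths, b$paths)
  expect_identical(a$divisions, b$divisions)
})

test_that("cell bookkeeping balances births and deaths exactly", {
  run <- cached_run("growth3d", function() {
    run_experiment(scenario_config("growth_24h", seed = 1, days = 3))
  })
  h <- run$history
  p <- run$paths
  for (i in seq(2, nrow(h), by = 17)) {
    t0 <- h$time[i - 1]; t1 <- h$time[i]
    births <- sum(p$origin == "newborn" & p$t_birth > t0 & p$t_birth <= t1)
    deaths <- sum(p$destiny == "dead" & p$t_end > t0 & p$t_end <= t1)
    splits <- sum(p$destiny == "split" & p$t_end > t0 & p$t_end <= t1)
    expect_equal(h$n_live[i] - h$n_live[i - 1], births - deaths - splits)
  }
  # history counts equal frame-derived counts
  fr <- run$frames
  for (tt in unique(fr$time)[c(10, 100, 200)]) {
    i <- which(h$time == tt)
    expect_equal(h$n_live[i], sum(fr$time == tt))
    expect_equal(h$n_G1[i], sum(fr$time == tt & fr$phase == "G1"))
  }
  # every id in frames appears in paths; labels stay in vocabulary
  expect_true(all(unique(fr$cell) %in% p$id))
  expect_true(all(p$origin %in% ORIGIN_LABELS))
  expect_true(all(p$destiny %in% DESTINY_LABELS))
})

test_that("replication time summarises ages at mitosis", {
  run <- cached_run("growth3d", function() {
    run_experiment(scenario_config("growth_24h", seed = 1, days = 3))
  })
  expect_equal(replication_time(run), mean(run$divisions$age))
  none <- run
  none$divisions <- none$divisions[0, ]
  expect_error(replication_time(none), "no divisions")
})

test_that("apparent doubling time is at least the replication time", {
  run <- cached_run("growth3d", function() {
    run_experiment(scenario_config("growth_24h", seed = 1, days = 3))
  })
  h <- run$history
  fit <- stats::lm(log(n_live) ~ time, data = h)
  doubling <- log(2) / stats::coef(fit)[["time"]]
  expect_gte(doubling, replication_time(run))
})

test_that("runs convert to track sets and export tables", {
  cfg <- scenario_config("growth_24h", seed = 9, days = 0.5, count = 20)
  run <- run_experiment(cfg)
  tr <- as_tracks(run)
  expect_s3_class(tr, "track_set")
  expect_equal(tr$interval, 20)
  dir <- tempfile("runout")
  export_run(run, dir, tracks = TRUE)
  expect_true(all(file.exists(file.path(dir,
    c("history.csv", "paths.csv", "frames.csv", "setup.json",
      "tracks.txt")))))
  rt <- read_tracks(file.path(dir, "tracks.txt"))
  expect_equal(sort(unique(rt$frames$cell)),
               sort(unique(as.character(run$frames$cell))))
})

test_that("the engine honours other update intervals", {
  cfg <- scenario_config("growth_24h", seed = 10, days = 1, count = 50)
  cfg$run$interval_min <- 60
  run <- run_experiment(cfg, record_frames = FALSE)
  expect_equal(nrow(run$history), 25)
  expect_gt(run$counters$final_live, 50)   # still grows at a 1 h interval
})
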