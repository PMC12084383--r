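test_that("volume grows exponentially", {
  expect_equal(grow_volume(1000, 0, 20), 1000)
  expect_equal(grow_volume(1000, log(2) / 1440, 1440), 2000)
  expect_equal(grow_volume(1000, log(2) / 1440, 720), 1000 * sqrt(2))
  expect_error(grow_volume(-5, 1e-4, 20), "volume")
})

test_that("transition counts match the binomial oracle", {
  p_edge <- 0.12
  prm <- single_edge_params("G1", "G1c", p_edge)
  plate <- new_plate(2000, 2000)
  set.seed(11)
  plate$cells <- seed_cells(500, prm, 2000, 2000, init = "fresh")
  plate <- step_cycle(plate, prm, dt = 20)   # dt equals prob_time: no adaptation
  k <- sum(plate$cells$phase == "G1c")
  sigma <- sqrt(500 * p_edge * (1 - p_edge))
  expect_lt(abs(k - 500 * p_edge), 4 * sigma)
})

test_that("hard gates hold: rfdDNA for S entry, full duplication for G2", {
  prm <- single_edge_params("G1c", "S", 1)
  plate <- test_plate(10, params = prm)
  plate$cells$phase <- rep("G1c", 10)
  plate$cells$rfd <- rep(c(TRUE, FALSE), 5)
  plate <- step_cycle(plate, prm, 20)
  expect_true(all(plate$cells$phase[c(1, 3, 5, 7, 9)] == "S"))
  expect_true(all(plate$cells$phase[c(2, 4, 6, 8, 10)] == "G1c"))

  prm2 <- single_edge_params("S", "G2", 1)
  plate2 <- test_plate(10, params = prm2)
  plate2$cells$phase <- rep("S", 10)
  plate2$cells$dna <- seq(0, 0.9, length.out = 10)
  plate2 <- step_cycle(plate2, prm2, 20)
  expect_true(all(plate2$cells$phase == "S"))  # forced draw cannot pass the gate
  # DNA advances linearly at 1 / s_duration
  expect_equal(plate2$cells$dna,
               pmin(seq(0, 0.9, length.out = 10) + 20 / prm2$s_duration, 1))
})

test_that("DEAD is absorbing and ignored by updates", {
  prm <- nih3t3_like_params()
  plate <- test_plate(5, params = prm)
  plate$cells$phase <- rep("DEAD", 5)
  vol <- plate$cells$volume
  for (i in 1:5) plate <- step_cycle(plate, prm, 20)
  expect_true(all(plate$cells$phase == "DEAD"))
  expect_equal(plate$cells$volume, vol)
})

test_that("division conserves volume and resets the daughters", {
  prm <- nih3t3_like_params()
  plate <- test_plate(6, params = prm)
  plate$cells$phase <- rep("M", 6)
  plate$cells$age <- rep(1400, 6)
  parent_vol <- sum(plate$cells$volume)
  parent_vols <- plate$cells$volume
  parent_genes <- list(c("mCherry"))
  plate$cells$genes <- rep(parent_genes, 6)
  set.seed(3)
  res <- divide(plate$cells, 1:6, prm, plate, next_id = 100L)
  pop <- res$pop
  expect_length(pop$id, 12)
  expect_equal(sum(pop$volume), parent_vol)
  expect_true(all(pop$phase == "G1"))
  expect_true(all(pop$attach == "SPREADING"))
  expect_true(all(pop$age == 0))
  expect_true(all(vapply(pop$genes, function(g) "mCherry" %in% g, TRUE)))
  expect_true(all(pop$pdx == 0 & pop$pdy == 0))
  # per-pair conservation against each parent and fresh growth modifiers
  v <- matrix(pop$volume, nrow = 2)
  expect_equal(colSums(v), parent_vols)
  expect_gt(length(unique(pop$grm)), 6)
})

test_that("vitality: apoptosis decays to death, drugs kill, genes protect", {
  prm <- nih3t3_like_params()
  plate <- test_plate(4, params = prm)
  plate$cells$phase <- c("APO", "APO", "G1", "G1")
  plate$cells$vitality <- c(0.05, 0.9, 1, 1)
  plate$cells$genes <- list(character(), character(),
                            "antibiotic_res", character())
  plate$medium$molecules$antibiotic <- 2
  plate <- update_vitality(plate, prm, dt = 20)
  expect_equal(plate$cells$phase[1], "DEAD")   # vitality hit zero
  expect_equal(plate$cells$phase[2], "APO")
  expect_lt(plate$cells$vitality[2], 0.9)
  expect_equal(plate$cells$vitality[3], 1)     # resistance gene protects
  expect_equal(plate$cells$vitality[4],
               1 - prm$drug_sensitivity$antibiotic$rate * 2 * 20)
})

test_that("damaged cells mostly recover at low damage and die at high", {
  prm <- nih3t3_like_params()
  set.seed(5)
  outcome <- function(dmg) {
    plate <- test_plate(300, width = 5000, height = 5000, params = prm)
    plate$cells$phase <- rep("DAMAGED", 300)
    plate$cells$damage <- rep(dmg, 300)
    for (i in 1:40) plate <- update_vitality(plate, prm, 20)
    table(factor(plate$cells$phase, levels = CYCLE_PHASES))
  }
  low <- outcome(0.05)
  expect_gt(low[["G1"]], low[["DEAD"]])       # recovery dominates
  high <- outcome(1)
  expect_gt(high[["DEAD"]], high[["G1"]])     # death dominates
})

test_that("reporters relax to their phase steady states", {
  prm <- nih3t3_like_params()
  rr <- prm$reporter_rates
  plate <- test_plate(2, params = prm)
  plate$cells$phase <- c("G0", "S")
  plate$cells$cdt1 <- c(0, 150)
  plate$cells$p27 <- c(0, 150)
  for (i in 1:400) plate <- update_reporters(plate, prm, 20)
  ss <- function(rep, ph) rr[[rep]]$synth[[ph]] / rr[[rep]]$decay[[ph]]
  expect_equal(plate$cells$p27[1], ss("p27", "G0"), tolerance = 1e-3)
  expect_equal(plate$cells$cdt1[2], ss("cdt1", "S"), tolerance = 1e-3)
  # quiescent steady state is far above the cycling one
  expect_gt(ss("p27", "G0"), 10 * ss("p27", "G1"))
})

test_that("volume roughly doubles between birth and mitosis", {
  run <- cached_run("growth3d", function() {
    run_experiment(scenario_config("growth_24h", seed = 1, days = 3))
  })
  div <- run$divisions
  expect_gt(nrow(div), 100)
  # volume at a cell's own birth: its first recorded frame
  fr <- data.table::as.data.table(run$frames)
  first <- fr[order(time), list(v0 = volume[1]), by = "cell"]
  newborn <- run$paths$id[run$paths$origin == "newborn"]
  m <- merge(div, as.data.frame(first), by.x = "id", by.y = "cell")
  m <- m[m$id %in% newborn, ]
  expect_gt(nrow(m), 50)
  ratio <- mean(m$volume / m$v0)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})
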