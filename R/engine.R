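# Experiment runner: plate construction, seeding, the per-interval update
# loop and History/Path/Frame recording.

# ---- population helpers -----------------------------------------------------

POP_FIELDS <- c("id", "x", "y", "volume", "surface", "phase", "attach",
                "age", "vitality", "dna", "rfd", "pdx", "pdy", "spread",
                "cdt1", "p27", "grm", "damage", "infect", "genes",
                "confluence", "divide", "newborn")

pop_subset <- function(pop, idx) {
  out <- lapply(pop, function(col) col[idx])
  out
}

pop_bind <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- c(a[[nm]], b[[nm]])
  a
}

#' Create an empty plate
#'
#' @param width,height plate size, um.
#' @param serum_type serum label (e.g. `"FBS"`, `"cs"`).
#' @param serum_level percent serum.
#' @param molecules named list of dissolved molecule concentrations.
#' @return a plate state (list with geometry, medium, fields, constraints,
#'   cells and clock).
#' @export
new_plate <- function(width, height, serum_type = "FBS", serum_level = 10,
                      molecules = list()) {
  stopifnot(width > 0, height > 0, serum_level >= 0)
  list(width = width, height = height,
       medium = list(serum_type = serum_type, serum_level = serum_level,
                     molecules = molecules),
       fields = list(), constraints = list(), infection = NULL,
       cells = empty_pop(), time = 0)
}

empty_pop <- function() {
  list(id = integer(), x = numeric(), y = numeric(), volume = numeric(),
       surface = numeric(), phase = character(), attach = character(),
       age = numeric(), vitality = numeric(), dna = numeric(),
       rfd = logical(), pdx = numeric(), pdy = numeric(),
       spread = numeric(), cdt1 = numeric(), p27 = numeric(),
       grm = numeric(), damage = numeric(), infect = numeric(),
       genes = list(), confluence = numeric(), divide = logical(),
       newborn = logical())
}

#' Seed a cell population
#'
#' `init = "fresh"` mimics just-trypsinised cells: all in G1 at the birth
#' volume, detached, age 0. `init = "staggered"` scatters cells across the
#' nominal cycle timeline (uniform cycle position) with matching volumes and
#' DNA progress, fully spread — an asynchronous exponentially growing
#' culture.
#'
#' @param n number of cells.
#' @param params a [cell_type_params()].
#' @param width,height plate size, um.
#' @param init `"staggered"` or `"fresh"`.
#' @param x,y optional explicit positions (length `n`).
#' @param cycle_minutes nominal cycle length used to stagger, minutes.
#' @return a population list.
#' @export
seed_cells <- function(n, params, width, height,
                       init = c("staggered", "fresh"), x = NULL, y = NULL,
                       cycle_minutes = 1440) {
  init <- match.arg(init)
  if (is.null(x)) x <- stats::runif(n, 0, width)
  if (is.null(y)) y <- stats::runif(n, 0, height)
  stopifnot(length(x) == n, length(y) == n)
  pop <- empty_pop()
  t_m <- 50; t_g2 <- 160; t_s <- params$s_duration; t_g1c <- 40
  t_g1 <- max(cycle_minutes - t_m - t_g2 - t_s - t_g1c, 60)
  bounds <- cumsum(c(t_g1, t_g1c, t_s, t_g2, t_m))
  if (init == "staggered") {
    age <- stats::runif(n, 0, bounds[5] * 0.999)
    phase <- as.character(cut(age, c(0, bounds),
                              labels = c("G1", "G1c", "S", "G2", "M"),
                              include.lowest = TRUE))
    volume <- params$v_birth * 2^(age / bounds[5])
    dna <- ifelse(phase == "S", (age - bounds[2]) / t_s,
                  ifelse(phase %in% c("G2", "M"), 1, 0))
    rfd <- phase == "G1c"
    attach <- rep("SPREAD", n)
    spread <- rep(1, n)
  } else {
    age <- rep(0, n)
    phase <- rep("G1", n)
    volume <- rep(params$v_birth, n)
    dna <- rep(0, n); rfd <- rep(FALSE, n)
    attach <- rep("DETACHED", n)
    spread <- rep(0, n)
  }
  pop$id <- seq_len(n)
  pop$x <- pmin(pmax(x, 0), width); pop$y <- pmin(pmax(y, 0), height)
  pop$volume <- volume
  pop$phase <- phase
  pop$attach <- attach
  pop$age <- age
  pop$vitality <- rep(1, n)
  pop$dna <- pmin(pmax(dna, 0), 1)
  pop$rfd <- rfd
  pop$pdx <- rep(0, n); pop$pdy <- rep(0, n)
  pop$spread <- spread
  pop$cdt1 <- rep(60, n); pop$p27 <- rep(5, n)
  pop$grm <- exp(stats::rnorm(n, 0, params$growth_modifier_sd))
  pop$damage <- rep(0, n)
  pop$infect <- rep(NA_real_, n)
  pop$genes <- replicate(n, character(), simplify = FALSE)
  pop$confluence <- rep(0, n)
  pop$divide <- rep(FALSE, n)
  pop$newborn <- rep(FALSE, n)
  pop$surface <- projected_surface(pop$volume, pop$spread, params)
  pop
}

# ---- the run ----------------------------------------------------------------

#' Run a simulation experiment
#'
#' Executes a validated setup: for each interval, due events fire, the
#' neighbour index and local confluence are rebuilt from the previous
#' interval's positions, every cell steps through cycle, vitality,
#' reporters, attachment and motion, fields decay and are degraded by
#' cells, divisions and removals are resolved, and a frame is recorded.
#' Runs are deterministic for a fixed seed.
#'
#' @param config a setup list (see [validate_config()]) or a path to a
#'   JSON/YAML config file.
#' @param seed integer seed overriding `config$run$seed`.
#' @param record_frames keep per-interval per-cell frames (default TRUE).
#' @return an object of class `culture_run` with elements `history`,
#'   `frames`, `paths`, `divisions`, `params`, `setup` and `counters`.
#' @export
run_experiment <- function(config, seed = NULL, record_frames = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  config <- validate_config(config)
  if (is.null(seed)) seed <- config$run$seed
  if (!is.null(seed)) set.seed(seed)
  params <- config$cell_params
  dt <- config$run$interval_min
  n_steps <- ceiling(config$run$duration_min / dt)
  plate <- build_plate(config)
  pop <- empty_pop()
  next_id <- 1L
  for (s in config$seeding) {
    ns <- if (!is.null(s$positions)) nrow(s$positions) else s$count
    newp <- seed_cells(ns, params, plate$width, plate$height,
                       init = if (is.null(s$init)) "staggered" else s$init,
                       x = s$positions$x, y = s$positions$y)
    newp$id <- newp$id + next_id - 1L
    next_id <- next_id + ns
    pop <- pop_bind(pop, newp)
  }
  plate$cells <- pop
  events <- config$events
  ev_fired <- rep(FALSE, length(events))
  paths <- data.table::data.table(
    id = pop$id, parent = NA_integer_, origin = "start",
    destiny = NA_character_, t_birth = 0, t_end = NA_real_)
  divisions <- list()
  history <- vector("list", n_steps + 1L)
  frames <- if (record_frames) vector("list", n_steps + 1L) else NULL
  snapshot <- function(plate, step) {
    pop <- plate$cells
    live <- pop$phase != "DEAD"
    ph <- table(factor(pop$phase[live], levels = CYCLE_PHASES))
    at <- table(factor(pop$attach[live], levels = ATTACH_PHASES))
    history[[step]] <<- data.frame(
      time = plate$time, n_live = sum(live),
      as.list(stats::setNames(as.integer(ph), paste0("n_", names(ph)))),
      as.list(stats::setNames(as.integer(at), paste0("n_", names(at)))),
      mean_volume = if (any(live)) mean(pop$volume[live]) else NA_real_,
      mean_surface = if (any(live)) mean(pop$surface[live]) else NA_real_,
      n_infected = sum(!is.na(pop$infect[live])))
    if (record_frames && any(live))
      frames[[step]] <<- data.frame(
        time = plate$time, cell = pop$id[live], x = pop$x[live],
        y = pop$y[live], phase = pop$phase[live],
        attach = pop$attach[live], volume = pop$volume[live],
        surface = pop$surface[live], cdt1 = pop$cdt1[live],
        p27 = pop$p27[live])
  }
  snapshot(plate, 1L)
  radius_max <- max(params$confluence_radius, params$repulsion_radius,
                    if (is.null(plate$infection)) 0 else
                      plate$infection$radius)
  for (step in seq_len(n_steps)) {
    # 1. events due at or before the current clock
    due <- which(!ev_fired & vapply(events, `[[`, 0, "time") <=
                 plate$time + 1e-9)
    for (k in due) {
      plate <- apply_event(plate, events[[k]], params)
      ev_fired[k] <- TRUE
      if (!is.null(plate$infection))
        radius_max <- max(radius_max, plate$infection$radius)
    }
    pop <- plate$cells
    n <- length(pop$id)
    live_before <- sum(pop$phase != "DEAD")
    # 2. neighbour index and local confluence from current positions
    grid <- neighbor_grid(pop$x, pop$y, radius_max)
    pairs <- grid_pairs(grid, radius_max)
    pop$confluence <- compute_confluence(
      n, pop$surface, pairs[pairs$dist <= params$confluence_radius],
      params$confluence_radius)
    pop$newborn <- rep(FALSE, n)
    plate$cells <- pop
    # 3. per-cell updates (vectorised, synchronous w.r.t. the grid/fields)
    plate <- step_cycle(plate, params, dt)
    plate <- update_vitality(plate, params, dt, grid = grid)
    plate <- update_reporters(plate, params, dt)
    plate <- step_attachment(plate, params, dt)
    moved <- plate$cells
    pre_x <- moved$x; pre_y <- moved$y
    plate <- step_motion(plate, params, dt,
                         pairs = pairs[pairs$dist <=
                                       params$repulsion_radius])
    # 4. field decay and cell-driven degradation (healthy cells only:
    # damaged and apoptotic cells no longer consume attractants)
    live_idx <- !plate$cells$phase %in% c("DEAD", "DAMAGED", "APO")
    for (fn in names(plate$fields)) {
      f <- decay_field(plate$fields[[fn]], dt)
      if (f$degradable_by_cells && any(live_idx))
        f <- degrade_locally(f, plate$cells$x[live_idx],
                             plate$cells$y[live_idx], dt,
                             params$attractant_degradation_rate,
                             params$sensing_distance)
      plate$fields[[fn]] <- f
    }
    plate$time <- plate$time + dt
    # 5. divisions resolved at the end of the interval
    pop <- plate$cells
    div_idx <- which(pop$divide & pop$phase != "DEAD")
    if (length(div_idx)) {
      divisions[[length(divisions) + 1L]] <- data.frame(
        time = plate$time, id = pop$id[div_idx], age = pop$age[div_idx],
        volume = pop$volume[div_idx])
      paths[match(pop$id[div_idx], paths$id),
            `:=`(destiny = "split", t_end = plate$time)]
      res <- divide(pop, div_idx, params, plate, next_id)
      pop <- res$pop
      next_id <- res$next_id
      paths <- data.table::rbindlist(list(paths, data.table::data.table(
        id = res$daughters$id, parent = res$daughters$parent,
        origin = "newborn", destiny = NA_character_,
        t_birth = plate$time, t_end = NA_real_)))
    }
    # 6. remove cells that died this interval
    dead_idx <- which(pop$phase == "DEAD")
    if (length(dead_idx)) {
      paths[match(pop$id[dead_idx], paths$id),
            `:=`(destiny = "dead", t_end = plate$time)]
      pop <- pop_subset(pop, setdiff(seq_along(pop$id), dead_idx))
    }
    plate$cells <- pop
    snapshot(plate, step + 1L)
  }
  open_p <- is.na(paths$destiny)
  paths[open_p, `:=`(destiny = "lost", t_end = plate$time)]
  history <- data.table::rbindlist(history, fill = TRUE)
  frames <- if (record_frames)
    as.data.frame(data.table::rbindlist(frames, fill = TRUE))
  divisions <- if (length(divisions))
    as.data.frame(data.table::rbindlist(divisions))
  else data.frame(time = numeric(), id = integer(), age = numeric(),
                  volume = numeric())
  structure(list(
    history = as.data.frame(history), frames = frames,
    paths = as.data.frame(paths), divisions = divisions,
    params = params, setup = config, plate = plate,
    counters = list(steps = n_steps,
                    final_live = utils::tail(history$n_live, 1),
                    elapsed_sec = proc.time()[["elapsed"]] - t_start)),
    class = "culture_run")
}

#' @export
print.culture_run <- function(x, ...) {
  h <- x$history
  cat("<culture_run>", x$counters$steps, "steps,",
      sprintf("%.0f min", utils::tail(h$time, 1)), "simulated\n")
  cat("  cells:", h$n_live[1], "->", utils::tail(h$n_live, 1),
      " divisions:", nrow(x$divisions), "\n")
  cat(sprintf("  elapsed %.1f s\n", x$counters$elapsed_sec))
  invisible(x)
}

#' Mean cell age at mitosis
#'
#' The calculated replication time of a run: the average age at division
#' over all split cells.
#'
#' @param run a `culture_run`.
#' @return minutes.
#' @export
replication_time <- function(run) {
  if (!nrow(run$divisions))
    stop("no divisions recorded; replication time undefined")
  mean(run$divisions$age)
}

#' Convert a run's frames to a track set
#'
#' @param run a `culture_run` recorded with frames.
#' @return a [track_set()].
#' @export
as_tracks <- function(run) {
  if (is.null(run$frames)) stop("run was recorded without frames")
  ori <- stats::setNames(run$paths$origin, run$paths$id)
  des <- stats::setNames(run$paths$destiny, run$paths$id)
  track_set(run$frames[, c("cell", "time", "x", "y")],
            interval = run$setup$run$interval_min,
            origin = ori, destiny = des)
}

#' Cycle-phase composition of a run at a time point
#'
#' @param run a `culture_run`.
#' @param at time in minutes (defaults to the final time point); the nearest
#'   recorded time point is used.
#' @param collapse_g1 count the committed `G1c` sub-state within G1.
#' @return named fractions over live cells (they sum to 1).
#' @export
phase_fractions <- function(run, at = NULL, collapse_g1 = TRUE) {
  h <- run$history
  if (is.null(at)) at <- max(h$time)
  row <- h[which.min(abs(h$time - at)), ]
  ph <- setdiff(CYCLE_PHASES, "DEAD")
  counts <- stats::setNames(as.numeric(row[paste0("n_", ph)]), ph)
  if (collapse_g1) {
    counts["G1"] <- counts["G1"] + counts["G1c"]
    counts <- counts[setdiff(names(counts), "G1c")]
  }
  counts / max(sum(counts), 1)
}
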