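# Packaged, reproducible simulation scenarios. Sizes are scaled to run on a
# desk machine in minutes; the methods vignette documents each choice.

#' Build a packaged scenario config
#'
#' Named, self-contained setups covering the standard experiment types:
#'
#' * `growth_24h` - 100 NIH3T3-like cells, ample space, 10% serum, 3 days:
#'   exponential growth with ~24 h replication.
#' * `serum_panel` - one population per serum level (default 10% and 2.5%
#'   cs), 0.58 mm^2 field, multi-day growth to confluence.
#' * `seeding_panel` - 1/4/10/50 cells per 0.58 mm^2 at 5% cs, run to the
#'   stationary state.
#' * `starvation_rescue` - grow 1 day at 10% FBS, step down to 0.5% FBS for
#'   3 days, restore 10% for the rest of the run.
#' * `random_vs_mixed` - two motility-only track generations (use
#'   [simulate_tracks()] directly for these parameters).
#' * `wound_healing` - confluent layer, scratch at 4 h, flat long-lived
#'   serum attractant plus short-lived debris attractant, both degradable
#'   (self-generated gradients).
#' * `antibiotic_selection` - antibiotic added at 6 h; optional prior
#'   transfection of a resistance gene.
#' * `ras_foci` - transfection of a constitutively active Ras gene at 12 h,
#'   serum step-down to 1% FBS at 24 h.
#' * `lytic_plaque` - confluent VeroE6-like layer, central infection with a
#'   lytic virus (9 h replication).
#'
#' @param name scenario name (see above).
#' @param seed RNG seed stored in the config.
#' @param days simulated days (each scenario has a sensible default).
#' @param ... scenario-specific overrides: `serum_level`, `count`,
#'   `transfect` (antibiotic_selection), `efficiency`.
#' @return a validated config, ready for [run_experiment()].
#' @export
scenario_config <- function(name = c("growth_24h", "serum_panel",
                                     "seeding_panel", "starvation_rescue",
                                     "random_vs_mixed", "wound_healing",
                                     "antibiotic_selection", "ras_foci",
                                     "lytic_plaque"),
                            seed = 1, days = NULL, ...) {
  name <- match.arg(name)
  opt <- list(...)
  set.seed(seed)      # jittered seeding layouts are part of the scenario
  d <- function(x, def) if (is.null(x)) def else x
  cfg <- switch(name,
    growth_24h = list(
      plate = list(width = 3000, height = 3000, serum_type = "cs",
                   serum_level = 10),
      seeding = list(list(count = d(opt$count, 100), init = "staggered")),
      events = list(),
      run = list(duration_min = d(days, 3) * 1440, interval_min = 20)),
    serum_panel = list(
      plate = list(width = 762, height = 762, serum_type = "cs",
                   serum_level = d(opt$serum_level, 10)),
      seeding = list(list(count = d(opt$count, 10), init = "staggered")),
      events = list(),
      run = list(duration_min = d(days, 3) * 1440, interval_min = 20)),
    seeding_panel = list(
      plate = list(width = 762, height = 762, serum_type = "cs",
                   serum_level = 5),
      seeding = list(list(count = d(opt$count, 10), init = "staggered")),
      events = list(),
      run = list(duration_min = d(days, 15) * 1440, interval_min = 20)),
    starvation_rescue = list(
      plate = list(width = 3000, height = 3000, serum_type = "FBS",
                   serum_level = 10),
      seeding = list(list(count = d(opt$count, 100), init = "staggered")),
      events = list(
        list(time = 1440, kind = "mediumChange", serum_type = "FBS",
             serum_level = 0.5),
        list(time = 4 * 1440, kind = "mediumChange", serum_type = "FBS",
             serum_level = 10)),
      run = list(duration_min = d(days, 7) * 1440, interval_min = 20)),
    random_vs_mixed = list(
      plate = list(width = 2000, height = 2000, serum_level = 10),
      seeding = list(list(count = 50, init = "staggered")),
      events = list(),
      run = list(duration_min = 71 * 20, interval_min = 20),
      tracks = list(
        random = list(n_cells = 50, n_frames = 72, rand = 8.7, pers = 0,
                      bias = 0),
        mixed = list(n_cells = 50, n_frames = 72, rand = 8.7, pers = 4,
                     bias = 4, bias_angle = 0))),
    wound_healing = {
      w <- 900; h <- 600; band <- 150
      list(
        plate = list(width = w, height = h, serum_type = "cs",
                     serum_level = 10,
                     fields = list(list(name = "serum_attract", value = 1,
                                        half_life = Inf, degradable = TRUE,
                                        bias_gain = 40))),
        seeding = list(list(count = NULL, init = "staggered",
                            positions = confluent_positions(w, h, 40))),
        events = list(list(time = 240, kind = "scratchOnPlate",
                           x0 = w / 2 - band / 2, x1 = w / 2 + band / 2,
                           y0 = 0, y1 = h, debris_value = 2,
                           debris_half_life = 240, debris_gain = 40)),
        run = list(duration_min = d(days, 1.25) * 1440, interval_min = 20))
    },
    antibiotic_selection = {
      evs <- list(list(time = 360, kind = "moleculeAddition",
                       name = "antibiotic", concentration = 1))
      if (isTRUE(opt$transfect))
        evs <- c(list(list(time = 0, kind = "transfection",
                           gene = "antibiotic_res",
                           efficiency = d(opt$efficiency, 0.1))), evs)
      list(
        plate = list(width = 1500, height = 1500, serum_level = 10),
        seeding = list(list(count = d(opt$count, 100), init = "staggered")),
        events = evs,
        run = list(duration_min = d(days, 8) * 1440, interval_min = 20))
    },
    ras_foci = list(
      plate = list(width = 1200, height = 1200, serum_type = "FBS",
                   serum_level = 10),
      cell_type = ras_responsive_params(),
      seeding = list(list(count = d(opt$count, 100), init = "staggered")),
      events = list(
        list(time = 720, kind = "transfection", gene = "RasV12",
             efficiency = d(opt$efficiency, 0.05)),
        list(time = 1440, kind = "mediumChange", serum_type = "FBS",
             serum_level = 1)),
      run = list(duration_min = d(days, 8) * 1440, interval_min = 20)),
    lytic_plaque = {
      w <- 800; h <- 800
      list(
        plate = list(width = w, height = h, serum_level = 10),
        cell_type = "vero_e6_like",
        seeding = list(list(count = NULL, init = "staggered",
                            positions = confluent_positions(w, h, 40))),
        events = list(list(time = 720, kind = "viralInfection",
                           n_initial = 1, lysis_time = 540, radius = 55,
                           prob = 0.7)),
        run = list(duration_min = d(days, 4) * 1440, interval_min = 20))
    })
  cfg$run$seed <- seed
  # short runs simply truncate the event schedule
  cfg$events <- Filter(function(e) e$time <= cfg$run$duration_min,
                       cfg$events)
  validate_config(cfg)
}

# Jittered monolayer positions at the given pitch (um).
confluent_positions <- function(width, height, pitch) {
  gx <- seq(pitch / 2, width - pitch / 2, by = pitch)
  gy <- seq(pitch / 2, height - pitch / 2, by = pitch)
  pos <- expand.grid(x = gx, y = gy)
  jit <- pitch * 0.2
  pos$x <- pmin(pmax(pos$x + stats::runif(nrow(pos), -jit, jit), 0), width)
  pos$y <- pmin(pmax(pos$y + stats::runif(nrow(pos), -jit, jit), 0), height)
  pos
}

# NIH3T3-like cells whose commitment responds to a constitutively active
# Ras gene: a parallel serum-independent commitment route and
# serum-independent growth once the gene is present.
ras_responsive_params <- function() {
  base <- nih3t3_like_params()
  extra <- list(
    transition_edge("G1", "G1c", 0.5, factors = list(
      factor_spec("gene_presence", 0.5, 12, "enhancing", name = "RasV12"),
      factor_spec("volume", 1300, 0.012, "enhancing"))),
    transition_edge("G0", "G1c", 0.2, factors = list(
      factor_spec("gene_presence", 0.5, 12, "enhancing", name = "RasV12"))))
  nih3t3_like_params(name = "nih3t3_ras_responsive",
                     transition_edges = c(base$transition_edges, extra),
                     gene_growth_rescue = list(gene = "RasV12", floor = 0.9))
}

#' Wound-front subpopulation analysis of a wound-healing run
#'
#' Splits the cells present at scratch time into front / middle / inner
#' groups by their distance from the nearest wound edge, mirrors the
#' right-hand side of the wound so both fronts share a bias direction, and
#' averages the windowed component contributions per group. In a healing
#' culture the bias contribution is strongest at the front and fades with
#' depth into the layer.
#'
#' @param run a `culture_run` of the `wound_healing` scenario (with frames).
#' @param scratch_time minutes at which the scratch fired.
#' @param band wound band `c(x0, x1)` in um.
#' @param depths group boundaries (um from the wound edge) for front /
#'   middle / inner.
#' @param window minutes per overlapping analysis window.
#' @return data.frame with one row per group: `group`, `n_cells`, `bias`,
#'   `random`, `persistence`, `displacement` (um per interval).
#' @export
wound_bias_profile <- function(run, scratch_time = 240,
                               band = NULL, depths = c(60, 150),
                               window = 720) {
  if (is.null(run$frames)) stop("run must be recorded with frames")
  w <- run$setup$plate$width
  if (is.null(band)) band <- c(w / 2 - 75, w / 2 + 75)
  ctr <- mean(band)
  fr <- run$frames
  f0 <- fr[fr$time == scratch_time, ]
  if (!nrow(f0)) stop("no frame recorded at the scratch time")
  dist_edge <- ifelse(f0$x < band[1], band[1] - f0$x,
                      ifelse(f0$x > band[2], f0$x - band[2], 0))
  grp <- cut(dist_edge, c(0, depths, Inf),
             labels = c("front", "middle", "inner"))
  right <- f0$x > ctr
  post <- fr[fr$time >= scratch_time, c("cell", "time", "x", "y")]
  out <- lapply(levels(grp), function(g) {
    ids <- f0$cell[!is.na(grp) & grp == g & dist_edge > 0]
    ids_r <- intersect(ids, f0$cell[right])
    sub <- post[post$cell %in% ids, , drop = FALSE]
    sub$x[sub$cell %in% ids_r] <- 2 * ctr - sub$x[sub$cell %in% ids_r]
    cc <- component_contributions(track_set(sub, run$setup$run$interval_min),
                                  window = window)
    data.frame(group = g, n_cells = length(ids), bias = mean(cc$bias),
               random = mean(cc$random), persistence = mean(cc$persistence),
               displacement = mean(cc$displacement))
  })
  do.call(rbind, out)
}
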