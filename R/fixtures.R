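# Analytic track fixtures and the standalone three-component track
# generator used for estimator validation and round-trip testing.

#' Generate tracks under the plain three-component model
#'
#' Produces per-cell paths in which every displacement is the sum of a
#' ten-step random walk vector (mean resultant length `rand`), a persistence
#' vector of module `pers` along the previous displacement (zero on the
#' first step) and a constant bias vector of module `bias` along
#' `bias_angle`. This is the generator whose parameters
#' [estimate_components()] recovers.
#'
#' @param n_cells number of cells.
#' @param n_frames frames per cell (so `n_frames - 1` displacements).
#' @param rand,pers,bias component modules, um per interval.
#' @param bias_angle bias direction, radians.
#' @param interval frame interval, minutes.
#' @param seed optional RNG seed.
#' @param spread um of uniform scatter of the starting positions.
#' @return a [track_set()].
#' @export
simulate_tracks <- function(n_cells, n_frames, rand, pers = 0, bias = 0,
                            bias_angle = 0, interval = 20, seed = NULL,
                            spread = 500) {
  stopifnot(n_cells >= 1, n_frames >= 2, rand >= 0, pers >= 0, bias >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, n_cells, n_frames)
  y <- matrix(0, n_cells, n_frames)
  x[, 1] <- stats::runif(n_cells, 0, spread)
  y[, 1] <- stats::runif(n_cells, 0, spread)
  bv <- c(bias * cos(bias_angle), bias * sin(bias_angle))
  pdx <- numeric(n_cells); pdy <- numeric(n_cells)
  for (t in seq_len(n_frames - 1L)) {
    rw <- random_walk_vector(rep(rand, n_cells))
    pm <- sqrt(pdx^2 + pdy^2)
    ok <- pm > 1e-12
    ux <- ifelse(ok, pdx / pm, 0); uy <- ifelse(ok, pdy / pm, 0)
    dx <- rw[, 1] + pers * ux + bv[1]
    dy <- rw[, 2] + pers * uy + bv[2]
    x[, t + 1L] <- x[, t] + dx
    y[, t + 1L] <- y[, t] + dy
    pdx <- dx; pdy <- dy
  }
  frames <- data.frame(cell = rep(seq_len(n_cells), each = n_frames),
                       time = rep((seq_len(n_frames) - 1L) * interval,
                                  n_cells),
                       x = as.vector(t(x)), y = as.vector(t(y)))
  track_set(frames, interval,
            origin = stats::setNames(rep("start", n_cells),
                                     seq_len(n_cells)),
            destiny = stats::setNames(rep("lost", n_cells),
                                      seq_len(n_cells)))
}

#' Analytic fixtures with known ground truth
#'
#' Deterministically seeded track sets (or plate states) whose true motion
#' statistics are known in closed form, for validating estimators and fits:
#' * `straight_paths` - constant-velocity motion (linearity 1, alpha 2);
#' * `brownian_paths` - i.i.d. Gaussian steps (alpha 1);
#' * `ou_persistent_paths` - Ornstein-Uhlenbeck velocity process whose MSD
#'   follows the Fuerth persistence law with the requested `S` and `P`;
#' * `confluent_layer` - a plate covered by a jittered monolayer of spread
#'   cells (for wound and infection scenarios);
#' * `sparse_seeding` - a plate with uniformly scattered cells.
#'
#' @param kind fixture name (see above).
#' @param params named list of kind-specific parameters (sensible defaults):
#'   `n_cells`, `n_frames`, `interval`, `speed` (straight), `step_sd`
#'   (brownian), `S`, `P` (OU), `width`, `height`, `density` or `n`
#'   (plates).
#' @param seed RNG seed.
#' @return a [track_set()] or a plate state, depending on `kind`.
#' @export
make_fixture <- function(kind = c("straight_paths", "brownian_paths",
                                  "ou_persistent_paths", "confluent_layer",
                                  "sparse_seeding"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  p <- function(name, default) if (is.null(params[[name]])) default
                               else params[[name]]
  n <- p("n_cells", 50L); nf <- p("n_frames", 60L); iv <- p("interval", 10)
  if (kind == "straight_paths") {
    sp <- p("speed", 0.5)                      # um/min
    th <- stats::runif(n, 0, 2 * pi)
    t <- (seq_len(nf) - 1L) * iv
    frames <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(cell = i, time = t,
                 x = sp * t * cos(th[i]), y = sp * t * sin(th[i]))))
    return(track_set(frames, iv))
  }
  if (kind == "brownian_paths") {
    sd <- p("step_sd", 4)
    frames <- do.call(rbind, lapply(seq_len(n), function(i) {
      dx <- stats::rnorm(nf - 1L, 0, sd); dy <- stats::rnorm(nf - 1L, 0, sd)
      data.frame(cell = i, time = (seq_len(nf) - 1L) * iv,
                 x = cumsum(c(0, dx)), y = cumsum(c(0, dy)))
    }))
    return(track_set(frames, iv))
  }
  if (kind == "ou_persistent_paths") {
    S <- p("S", 1); P <- p("P", 30); dt <- p("euler_dt", iv / 8)
    nsub <- round(iv / dt)
    rho <- exp(-dt / P)
    sdv <- sqrt((S^2 / 2) * (1 - rho^2))       # per-component stationary kick
    frames <- do.call(rbind, lapply(seq_len(n), function(i) {
      vx <- stats::rnorm(1, 0, S / sqrt(2)); vy <- stats::rnorm(1, 0, S / sqrt(2))
      xs <- numeric(nf); ys <- numeric(nf)
      for (f in 2:nf) {
        x0 <- xs[f - 1L]; y0 <- ys[f - 1L]
        for (s in seq_len(nsub)) {
          x0 <- x0 + vx * dt; y0 <- y0 + vy * dt
          vx <- vx * rho + stats::rnorm(1, 0, sdv)
          vy <- vy * rho + stats::rnorm(1, 0, sdv)
        }
        xs[f] <- x0; ys[f] <- y0
      }
      data.frame(cell = i, time = (seq_len(nf) - 1L) * iv, x = xs, y = ys)
    }))
    return(track_set(frames, iv))
  }
  # plate fixtures
  w <- p("width", 600); h <- p("height", 400)
  prm <- p("cell_params", nih3t3_like_params())
  if (kind == "confluent_layer") {
    pitch <- p("pitch", 28)
    gx <- seq(pitch / 2, w - pitch / 2, by = pitch)
    gy <- seq(pitch / 2, h - pitch / 2, by = pitch)
    pos <- expand.grid(x = gx, y = gy)
    jit <- pitch * 0.25
    pos$x <- pmin(pmax(pos$x + stats::runif(nrow(pos), -jit, jit), 0), w)
    pos$y <- pmin(pmax(pos$y + stats::runif(nrow(pos), -jit, jit), 0), h)
    plate <- new_plate(w, h, serum_level = p("serum_level", 10))
    plate$cells <- seed_cells(nrow(pos), prm, w, h, init = "staggered",
                              x = pos$x, y = pos$y)
    plate$cells$attach <- rep("SPREAD", length(plate$cells$id))
    plate$cells$spread <- rep(1, length(plate$cells$id))
    return(plate)
  }
  plate <- new_plate(w, h, serum_level = p("serum_level", 10))
  plate$cells <- seed_cells(p("n", 50L), prm, w, h, init = "staggered")
  plate
}
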