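# Movement statistics for simulated or experimental track sets: component
# decomposition, MSD curves with power-law and persistence fits, linearity,
# coherence, circular statistics, windowed component contributions.

#' Create a track set
#'
#' A track set holds per-cell time-stamped positions at a fixed frame
#' interval, with origin/destiny labels describing how each path begins and
#' ends. It is both the analysis module's input and the simulation engine's
#' exportable output.
#'
#' @param frames data.frame with columns `cell`, `time` (minutes), `x`, `y`
#'   (um); times must be strictly increasing within each cell.
#' @param interval frame interval in minutes.
#' @param origin,destiny optional named character vectors (by cell id) drawn
#'   from [ORIGIN_LABELS] / [DESTINY_LABELS].
#' @return an object of class `track_set`.
#' @export
track_set <- function(frames, interval, origin = NULL, destiny = NULL) {
  stopifnot(all(c("cell", "time", "x", "y") %in% names(frames)),
            interval > 0)
  frames <- frames[order(frames$cell, frames$time), , drop = FALSE]
  bad <- unlist(tapply(frames$time, frames$cell,
                       function(t) any(diff(t) <= 0)), use.names = FALSE)
  if (any(bad)) stop("track times must be strictly increasing within a cell")
  if (!is.null(origin) && !all(origin %in% ORIGIN_LABELS))
    stop("unknown origin label")
  if (!is.null(destiny) && !all(destiny %in% DESTINY_LABELS))
    stop("unknown destiny label")
  structure(list(frames = frames, interval = interval,
                 origin = origin, destiny = destiny),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat("<track_set>", length(unique(x$frames$cell)), "cells,",
      nrow(x$frames), "points, interval", x$interval, "min\n")
  invisible(x)
}

# Per-cell consecutive displacements; returns data.table with cell, step
# index, dx, dy.
track_displacements <- function(tracks) {
  f <- data.table::as.data.table(tracks$frames)
  f <- f[order(f$cell, f$time)]
  f[, list(step = seq_len(.N - 1L),
           dx = diff(x), dy = diff(y),
           dt = diff(time)), by = "cell"]
}

#' Estimate random, persistence and bias components from tracks
#'
#' Moment-based decomposition of per-interval displacements under the
#' three-component model. With `u_t` the unit vector of displacement `d_t`,
#' the model implies `E[d] = b_vec + p m_vec` and
#' `E[d_t . u_(t-1)] = p + b_vec . m_vec`, where `m_vec = E[u]` is the mean
#' unit displacement vector (observable). Solving this linear system for `p`
#' and `b_vec` removes the persistence/bias coupling that would otherwise
#' inflate the naive mean-displacement bias estimate; the random module is
#' the mean length of the residual vectors, matching the generator's
#' mean-resultant calibration, so generated populations round-trip.
#'
#' @param tracks a [track_set()].
#' @return list with `rand`, `pers`, `bias` modules (um per interval),
#'   `bias_angle` (radians) and `bias_vec`.
#' @export
estimate_components <- function(tracks) {
  d <- track_displacements(tracks)
  if (!nrow(d)) stop("track set contains no displacements")
  d[, `:=`(pdx = data.table::shift(dx), pdy = data.table::shift(dy)),
    by = "cell"]
  cur <- d[!is.na(d$pdx)]
  if (nrow(cur) < 2) stop("need at least two consecutive displacements")
  pm <- sqrt(cur$pdx^2 + cur$pdy^2)
  keep <- pm > 1e-12
  cur <- cur[keep]; pm <- pm[keep]
  ux <- cur$pdx / pm; uy <- cur$pdy / pm
  m_vec <- c(mean(ux), mean(uy))
  A_vec <- c(mean(cur$dx), mean(cur$dy))
  C1 <- mean(cur$dx * ux + cur$dy * uy)
  m2 <- sum(m_vec^2)
  if (m2 > 0.999) {            # degenerate: all directions identical
    p <- 0
    b_vec <- A_vec
  } else {
    p <- (C1 - sum(A_vec * m_vec)) / (1 - m2)
    p <- max(p, 0)
    b_vec <- A_vec - p * m_vec
  }
  res_x <- cur$dx - p * ux - b_vec[1]
  res_y <- cur$dy - p * uy - b_vec[2]
  list(rand = mean(sqrt(res_x^2 + res_y^2)),
       pers = p,
       bias = sqrt(sum(b_vec^2)),
       bias_angle = atan2(b_vec[2], b_vec[1]),
       bias_vec = b_vec)
}

#' Mean squared displacement versus lag time
#'
#' MSD is averaged over all cells and all start frames (overlapping
#' windows); the number of averaged squared displacements per lag is
#' recorded for use as fit weights.
#'
#' @param tracks a [track_set()].
#' @param max_lag maximum lag in frames (default: longest track minus one).
#' @return data.frame with columns `lag` (minutes), `msd` (um^2), `n_pairs`.
#' @export
msd_curve <- function(tracks, max_lag = NULL) {
  f <- data.table::as.data.table(tracks$frames)
  f <- f[order(f$cell, f$time)]
  lens <- f[, .N, by = "cell"]$N
  if (all(lens < 2)) stop("need at least one track with two points")
  if (is.null(max_lag)) max_lag <- max(lens) - 1L
  per_cell <- split(f, by = "cell")
  acc_s <- numeric(max_lag); acc_n <- integer(max_lag)
  for (p in per_cell) {
    np <- nrow(p)
    if (np < 2) next
    for (L in seq_len(min(max_lag, np - 1L))) {
      i <- seq_len(np - L)
      sq <- (p$x[i + L] - p$x[i])^2 + (p$y[i + L] - p$y[i])^2
      acc_s[L] <- acc_s[L] + sum(sq)
      acc_n[L] <- acc_n[L] + length(sq)
    }
  }
  keep <- acc_n > 0
  data.frame(lag = seq_len(max_lag)[keep] * tracks$interval,
             msd = acc_s[keep] / acc_n[keep],
             n_pairs = acc_n[keep])
}

#' Fit the anomalous-diffusion law MSD = k * t^alpha
#'
#' Weighted nonlinear least squares with weights proportional to the number
#' of averaged squared displacements per lag. `alpha` near 1 indicates
#' diffusive, near 2 ballistic and values in between superdiffusive motion.
#'
#' @param msd data.frame from [msd_curve()] (columns `lag`, `msd`,
#'   `n_pairs`).
#' @return list with `k`, `alpha` and the fit object.
#' @export
fit_alpha <- function(msd) {
  stopifnot(nrow(msd) >= 3)
  pos <- msd$msd > 0 & msd$lag > 0
  if (sum(pos) < 3) stop("not enough positive MSD values to fit")
  ll <- stats::lm(log(msd$msd[pos]) ~ log(msd$lag[pos]))
  start <- list(k = exp(stats::coef(ll)[[1]]), alpha = stats::coef(ll)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ k * lag^alpha, data = msd, start = start,
                      weights = n_pairs,
                      lower = c(k = 1e-12, alpha = 0.01),
                      upper = c(k = Inf, alpha = 4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  list(k = unname(co["k"]), alpha = unname(co["alpha"]), fit = fit)
}

#' Fit the Fuerth persistence model to an MSD curve
#'
#' Fits \deqn{MSD(t) = 2 S^2 P [t - P (1 - e^{-t/P})]} by weighted nonlinear
#' least squares, where `S` is the root-mean-squared speed (um/min) and `P`
#' the directional persistence time (minutes). At small `t` the model is
#' ballistic (`S^2 t^2`), at large `t` diffusive with slope `2 S^2 P`.
#'
#' @param msd data.frame from [msd_curve()].
#' @return list with `S`, `P`, logical `at_bound` (persistence time pinned at
#'   a box constraint, i.e. not identifiable) and the fit object.
#' @export
fit_persistence <- function(msd) {
  stopifnot(nrow(msd) >= 4)
  # diffusive-limit starts: slope ~ 2 S^2 P, early curvature ~ S^2 t^2
  slope <- max(msd$msd[nrow(msd)] / msd$lag[nrow(msd)], 1e-8)
  S0 <- sqrt(max(msd$msd[1], 1e-8)) / msd$lag[1]
  P0 <- max(slope / (2 * S0^2), msd$lag[1] / 2)
  P_hi <- 50 * max(msd$lag)
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ 2 * S^2 * P * (lag - P * (1 - exp(-lag / P))),
                      data = msd, start = list(S = S0, P = P0),
                      weights = n_pairs,
                      lower = c(S = 1e-9, P = 1e-3),
                      upper = c(S = Inf, P = P_hi),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("persistence fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  list(S = unname(co["S"]), P = unname(co["P"]),
       at_bound = unname(co["P"] >= P_hi * 0.999 | co["P"] <= 2e-3),
       fit = fit)
}

#' MSD expected from the random component alone (rMSD)
#'
#' The mean squared displacement of a pure random walker whose per-interval
#' module equals `rand`: for the ten-step walk,
#' `E|d|^2 = 10 (rand / c)^2` with `c` the walk's mean-resultant constant,
#' and independent steps give `rMSD(t) = (t / interval) * E|d|^2`.
#'
#' @param rand estimated random module, um per interval.
#' @param lag lag times, minutes.
#' @param interval frame interval, minutes.
#' @return rMSD values, um^2.
#' @export
rmsd_random <- function(rand, lag, interval) {
  (lag / interval) * 10 * (rand / RW10_MEAN)^2
}

#' Per-cell path linearity
#'
#' Ratio of the net displacement (start-to-end distance) to the total path
#' length, averaged (unweighted) over cells. Zero-length paths are excluded
#' with a warning.
#'
#' @param tracks a [track_set()].
#' @return population mean linearity in `(0, 1]`.
#' @export
linearity <- function(tracks) {
  d <- track_displacements(tracks)
  per <- d[, list(net = sqrt(sum(dx)^2 + sum(dy)^2),
                  len = sum(sqrt(dx^2 + dy^2))), by = "cell"]
  zero <- per$len == 0
  if (any(zero)) {
    warning(sum(zero), " zero-length path(s) excluded from linearity")
    per <- per[!zero]
  }
  if (!nrow(per)) stop("no usable paths for linearity")
  mean(per$net / per$len)
}

#' Population coherence
#'
#' Length of the vector sum of all per-cell net displacements divided by the
#' sum of their lengths; 1 when all cells travel in the same direction, 0
#' when their net displacements cancel.
#'
#' @param tracks a [track_set()].
#' @return coherence in `[0, 1]`.
#' @export
coherence <- function(tracks) {
  d <- track_displacements(tracks)
  per <- d[, list(nx = sum(dx), ny = sum(dy)), by = "cell"]
  lens <- sqrt(per$nx^2 + per$ny^2)
  if (all(lens == 0)) stop("all net displacements are zero")
  sqrt(sum(per$nx)^2 + sum(per$ny)^2) / sum(lens)
}

#' Circular statistics of displacement directions
#'
#' Unit displacement-direction vectors are averaged; the mean vector's
#' length is the linear dispersion coefficient R (0 = uniform directions,
#' 1 = identical directions) and its direction the mean angle.
#'
#' @param displacements 2-column matrix of displacement vectors, or a
#'   [track_set()] whose consecutive displacements are used.
#' @return list with `mean_angle` (radians) and `R`.
#' @export
circular_R <- function(displacements) {
  if (inherits(displacements, "track_set")) {
    d <- track_displacements(displacements)
    displacements <- cbind(d$dx, d$dy)
  }
  mod <- sqrt(displacements[, 1]^2 + displacements[, 2]^2)
  keep <- mod > 0
  if (!any(keep)) stop("no nonzero displacements")
  ux <- displacements[keep, 1] / mod[keep]
  uy <- displacements[keep, 2] / mod[keep]
  mx <- mean(ux); my <- mean(uy)
  list(mean_angle = atan2(my, mx), R = sqrt(mx^2 + my^2))
}

#' Windowed component contributions to displacement
#'
#' For overlapping windows (stride of one frame interval), the components
#' are re-estimated within the window and each component vector is projected
#' onto the realised displacement directions; the averaged projections are
#' the scalar contributions of random, persistence and bias to displacement
#' length, and they sum to the mean displacement module of the window.
#'
#' @param tracks a [track_set()].
#' @param window window length in minutes (>= 2 frame intervals).
#' @return data.frame with `t_mid`, `random`, `persistence`, `bias`,
#'   `displacement` (all um per interval); zero rows if the window exceeds
#'   the track length.
#' @export
component_contributions <- function(tracks, window) {
  iv <- tracks$interval
  if (window < 2 * iv) stop("window must cover at least 2 frame intervals")
  times <- sort(unique(tracks$frames$time))
  if (length(times) < 2) stop("not enough frames")
  starts <- times[times + window <= max(times) + 1e-9]
  out <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    t0 <- starts[s]; t1 <- t0 + window
    sub <- tracks$frames[tracks$frames$time >= t0 - 1e-9 &
                         tracks$frames$time <= t1 + 1e-9, , drop = FALSE]
    cnt <- table(sub$cell)
    sub <- sub[sub$cell %in% names(cnt)[cnt >= 3], , drop = FALSE]
    if (!nrow(sub)) next
    ts <- track_set(sub, iv)
    est <- tryCatch(estimate_components(ts), error = function(e) NULL)
    if (is.null(est)) next
    d <- track_displacements(ts)
    d[, `:=`(pdx = data.table::shift(dx), pdy = data.table::shift(dy)),
      by = "cell"]
    cur <- d[!is.na(d$pdx)]
    pm <- sqrt(cur$pdx^2 + cur$pdy^2)
    cur <- cur[pm > 1e-12]; pm <- pm[pm > 1e-12]
    dm <- sqrt(cur$dx^2 + cur$dy^2)
    ok <- dm > 1e-12
    cur <- cur[ok]; pm <- pm[ok]; dm <- dm[ok]
    if (!nrow(cur)) next
    ex <- cur$dx / dm; ey <- cur$dy / dm
    pux <- cur$pdx / pm; puy <- cur$pdy / pm
    pers_proj <- est$pers * (pux * ex + puy * ey)
    bias_proj <- est$bias_vec[1] * ex + est$bias_vec[2] * ey
    rand_proj <- (cur$dx - est$pers * pux - est$bias_vec[1]) * ex +
      (cur$dy - est$pers * puy - est$bias_vec[2]) * ey
    out[[s]] <- data.frame(t_mid = t0 + window / 2,
                           random = mean(rand_proj),
                           persistence = mean(pers_proj),
                           bias = mean(bias_proj),
                           displacement = mean(dm))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(t_mid = numeric(), random = numeric(),
                               persistence = numeric(), bias = numeric(),
                               displacement = numeric())
  else out
}

#' Two-dimensional kernel density of displacements
#'
#' Gaussian-kernel density (normal-reference bandwidth) of displacement
#' endpoints relative to their origin, for a stated lag.
#'
#' @param tracks a [track_set()].
#' @param lag lag in minutes (multiple of the frame interval).
#' @param n grid size per axis.
#' @return the [MASS::kde2d()] result (list `x`, `y`, `z`).
#' @export
displacement_density <- function(tracks, lag = tracks$interval, n = 25) {
  L <- round(lag / tracks$interval)
  stopifnot(L >= 1)
  f <- data.table::as.data.table(tracks$frames)
  f <- f[order(f$cell, f$time)]
  sh <- f[, if (.N > L) list(dx = x[(L + 1):.N] - x[1:(.N - L)],
                             dy = y[(L + 1):.N] - y[1:(.N - L)]),
          by = "cell"]
  if (nrow(sh) < 10) stop("need at least 10 shifts for a density")
  lims <- c(range(sh$dx), range(sh$dy)) * 1.2
  MASS::kde2d(sh$dx, sh$dy, n = n, lims = lims)
}

#' Full motion summary of a track set
#'
#' Computes the column set used when comparing simulated and experimental
#' populations: component modules, bias angle, mean displacement, final MSD
#' and random MSD, diffusion exponent, persistence time, rms speed,
#' linearity, coherence and the circular R parameter.
#'
#' @param tracks a [track_set()].
#' @param normalise_modules report persistence/bias modules divided by the
#'   random module instead of in um.
#' @return one-row data.frame.
#' @export
motion_summary <- function(tracks, normalise_modules = FALSE) {
  est <- estimate_components(tracks)
  msd <- msd_curve(tracks)
  al <- fit_alpha(msd)
  pf <- tryCatch(fit_persistence(msd), error = function(e) NULL)
  d <- track_displacements(tracks)
  circ <- circular_R(cbind(d$dx, d$dy))
  pers <- est$pers; bias <- est$bias
  if (normalise_modules && est$rand > 0) {
    pers <- pers / est$rand; bias <- bias / est$rand
  }
  data.frame(
    rand_module = est$rand, pers_module = pers, bias_module = bias,
    bias_angle = est$bias_angle,
    mean_displacement = mean(sqrt(d$dx^2 + d$dy^2)),
    msd_final = msd$msd[nrow(msd)],
    rmsd_final = rmsd_random(est$rand, msd$lag[nrow(msd)], tracks$interval),
    alpha = al$alpha, k_msd = al$k,
    persistence_time = if (is.null(pf)) NA_real_ else pf$P,
    rms_speed = if (is.null(pf)) NA_real_ else pf$S,
    linearity = linearity(tracks), coherence = coherence(tracks),
    R = circ$R)
}
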