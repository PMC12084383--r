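# Displacement generation: three-component model (random + persistence + bias)
# extended with cell-cell repulsion, attractant gradients and constraints.

# Mean resultant length of a 10-step unit Pearson walk, E|R| / step length.
# Computed once by quadrature of the Kluyver integral and cross-checked by
# large Monte Carlo; the asymptotic sqrt(10*pi)/2 = 2.8025 underestimates the
# finite-walk mean by ~0.6%, which would bias the module calibration.
RW10_MEAN <- 2.82033

#' Ten-step random walk vector(s)
#'
#' Each vector is the resultant of 10 steps of equal length with independent
#' uniform directions. The step length is calibrated so the mean resultant
#' length equals `module`; the resultant direction is uniform and its length
#' has the long-tailed near-Rayleigh distribution characteristic of the walk.
#'
#' @param module requested mean resultant length(s), um; non-negative. One
#'   vector is drawn per element.
#' @return a matrix with columns `dx`, `dy` and one row per module.
#' @export
random_walk_vector <- function(module) {
  if (any(module < 0)) stop("`module` must be non-negative")
  n <- length(module)
  step <- module / RW10_MEAN
  th <- matrix(stats::runif(10L * n, 0, 2 * pi), n, 10L)
  cbind(dx = rowSums(cos(th)) * step, dy = rowSums(sin(th)) * step)
}

#' Compose a displacement from its three components
#'
#' Plain vector sum of the random, persistence and bias vectors. The
#' persistence vector must already point along the cell's previous
#' displacement (the first step of a path has zero persistence).
#'
#' @param rand_vec,pers_vec,bias_vec length-2 vectors or 2-column matrices, um.
#' @return the summed displacement(s), same shape as the inputs.
#' @export
compose_displacement <- function(rand_vec, pers_vec, bias_vec) {
  rand_vec + pers_vec + bias_vec
}

#' Condition-scaled movement components
#'
#' Computes the effective random/persistence modules and the bias vector for
#' cells under the extended motion model. The maximum displacement is
#' `d_tot = k_total * d_ref` (scaled to the step length); the global bias
#' (`b_frac * d_tot` along `bias_angle`) is vector-summed with all extra bias
#' vectors (repulsion, gradients); the resulting bias share
#' `b' = |bias| / d_tot` replaces `b_frac`, and the random and persistence
#' fractions are rescaled so `r' + p' + b' = 1`. When the summed bias exceeds
#' `d_tot` it is capped at `d_tot` and `r' = p' = 0`.
#'
#' @param params a [cell_type_params()].
#' @param k_total per-cell cumulative movement coefficient (>= 0).
#' @param extra_bias 2-column matrix of summed extra bias vectors, um per
#'   step (zero matrix when absent).
#' @param dt step length in minutes; modules scale as `dt / interval_ref`.
#' @return list with vectors `rand`, `pers` (um) and matrix `bias_vec`.
#' @export
effective_components <- function(params, k_total, extra_bias = NULL,
                                 dt = params$interval_ref) {
  n <- length(k_total)
  if (any(k_total < 0)) stop("k_total must be non-negative")
  if (is.null(extra_bias)) extra_bias <- matrix(0, n, 2)
  d_tot <- k_total * params$d_ref * (dt / params$interval_ref)
  gb <- params$b_frac * d_tot
  B <- cbind(gb * cos(params$bias_angle), gb * sin(params$bias_angle)) +
    extra_bias
  nb <- sqrt(B[, 1]^2 + B[, 2]^2)
  ok <- d_tot > 0
  bprime <- ifelse(ok, pmin(nb / pmax(d_tot, 1e-300), 1), 0)
  over <- ok & nb > d_tot
  if (any(over)) {          # cap the bias at the maximum displacement
    sc <- d_tot[over] / nb[over]
    B[over, ] <- B[over, , drop = FALSE] * sc
  }
  rp <- params$r_frac + params$p_frac
  scale <- if (rp > 0) (1 - bprime) / rp else rep(0, n)
  rand <- ifelse(ok, params$r_frac * scale * d_tot, 0)
  pers <- ifelse(ok, params$p_frac * scale * d_tot, 0)
  B[!ok, ] <- 0
  list(rand = rand, pers = pers, bias_vec = B)
}

#' Cell-cell repulsion bias vectors
#'
#' For every cell, neighbours within `repulsion_radius` push it away along the
#' line connecting the two cells, with module
#' `repulsion_sensitivity * d_ref * (1 - dist / radius)` (linear falloff,
#' zero at the radius). Coincident cells push in a uniformly random direction.
#'
#' @param x,y cell positions, um.
#' @param params a [cell_type_params()].
#' @param pairs optional precomputed directed pair table from [grid_pairs()]
#'   at `repulsion_radius` (built on demand otherwise).
#' @return 2-column matrix of repulsion vectors, um.
#' @export
repulsion_bias <- function(x, y, params, pairs = NULL) {
  n <- length(x)
  out <- matrix(0, n, 2)
  if (n < 2) return(out)
  R <- params$repulsion_radius
  if (is.null(pairs)) {
    pairs <- grid_pairs(neighbor_grid(x, y, R), R)
  } else {
    pairs <- pairs[pairs$dist <= R]
  }
  if (!nrow(pairs)) return(out)
  dx <- x[pairs$i] - x[pairs$j]
  dy <- y[pairs$i] - y[pairs$j]
  d <- pairs$dist
  coin <- d < 1e-9
  if (any(coin)) {            # documented tie-break: random direction
    th <- stats::runif(sum(coin), 0, 2 * pi)
    dx[coin] <- cos(th); dy[coin] <- sin(th); d[coin] <- 1
  }
  mod <- params$repulsion_sensitivity * params$d_ref * (1 - pairs$dist / R)
  vx <- mod * dx / d
  vy <- mod * dy / d
  sx <- rowsum(vx, pairs$i)
  out[as.integer(rownames(sx)), 1] <- sx
  sy <- rowsum(vy, pairs$i)
  out[as.integer(rownames(sy)), 2] <- sy
  out
}

#' Attractant gradient bias vectors
#'
#' Samples the field at `+- sensing_distance / 2` along x and y around each
#' cell; the bias vector is the finite-difference concentration gradient
#' scaled by the field's `bias_gain`, capped at `params$gradient_cap`.
#' Cells outside the field feel nothing (sampling clamps to the lattice
#' border, so the difference vanishes there).
#'
#' @param field a [scalar_field()].
#' @param x,y cell positions, um.
#' @param params a [cell_type_params()].
#' @return 2-column matrix of bias vectors, um.
#' @export
gradient_bias <- function(field, x, y, params) {
  h <- params$sensing_distance / 2
  bx <- (sample_field(field, x + h, y) - sample_field(field, x - h, y)) *
    field$bias_gain
  by <- (sample_field(field, x, y + h) - sample_field(field, x, y - h)) *
    field$bias_gain
  mod <- sqrt(bx^2 + by^2)
  over <- mod > params$gradient_cap
  if (any(over)) {
    sc <- params$gradient_cap / mod[over]
    bx[over] <- bx[over] * sc
    by[over] <- by[over] * sc
  }
  cbind(unname(bx), unname(by))
}

#' Truncate displacements at constraints and plate borders
#'
#' Movement stops at the plate edge and at the boundary of blocking regions
#' (no reflection); slowing regions scale the displacement of cells starting
#' inside them by their factor.
#'
#' @param x,y start positions, um.
#' @param dx,dy proposed displacements, um.
#' @param plate a plate state (list with `width`, `height`, `constraints`).
#' @return list with final `x`, `y`.
#' @export
apply_constraints <- function(x, y, dx, dy, plate) {
  for (cns in plate$constraints) {
    if (identical(cns$type, "slow")) {
      inside <- x >= cns$x0 & x <= cns$x1 & y >= cns$y0 & y <= cns$y1
      dx[inside] <- dx[inside] * cns$factor
      dy[inside] <- dy[inside] * cns$factor
    }
  }
  tmax <- rep(1, length(x))
  clip_axis <- function(tmax, p, d, lo, hi) {
    pos <- d > 0; neg <- d < 0
    tmax[pos] <- pmin(tmax[pos], (hi - p[pos]) / d[pos])
    tmax[neg] <- pmin(tmax[neg], (lo - p[neg]) / d[neg])
    tmax
  }
  tmax <- clip_axis(tmax, x, dx, 0, plate$width)
  tmax <- clip_axis(tmax, y, dy, 0, plate$height)
  for (cns in plate$constraints) {
    if (!identical(cns$type, "block")) next
    inside0 <- x > cns$x0 & x < cns$x1 & y > cns$y0 & y < cns$y1
    # slab entry time of the segment into the rectangle
    with_d <- function(p, d, lo, hi) {
      t0 <- ifelse(d != 0, (lo - p) / d, ifelse(p >= lo, -Inf, Inf))
      t1 <- ifelse(d != 0, (hi - p) / d, ifelse(p <= hi, Inf, -Inf))
      cbind(pmin(t0, t1), pmax(t0, t1))
    }
    tx <- with_d(x, dx, cns$x0, cns$x1)
    ty <- with_d(y, dy, cns$y0, cns$y1)
    t_in <- pmax(tx[, 1], ty[, 1])
    t_out <- pmin(tx[, 2], ty[, 2])
    hit <- !inside0 & t_in < t_out & t_in >= 0 & t_in <= 1
    tmax[hit] <- pmin(tmax[hit], pmax(t_in[hit] - 1e-9, 0))
  }
  tmax <- pmax(tmax, 0)
  list(x = pmin(pmax(x + dx * tmax, 0), plate$width),
       y = pmin(pmax(y + dy * tmax, 0), plate$height))
}

# Cumulative movement coefficient k for every live cell.
motion_k_total <- function(pop, params, confluence) {
  k <- params$phase_motility[pop$phase] *
    params$attach_motility[pop$attach] * pop$vitality
  if (!is.null(params$confluence_motility)) {
    f <- params$confluence_motility
    kk <- if (f$direction == "enhancing") -f$k_steep else f$k_steep
    k <- k * logistic_effect(confluence, f$x_ref, kk)
  }
  unname(k)
}

#' Advance cell positions by one motion step
#'
#' Builds the per-cell movement coefficient `k` from cycle phase, attachment
#' state, vitality and local confluence; sums extra bias vectors from
#' cell-cell repulsion and every attractant gradient; derives the effective
#' components; draws the ten-step random walk; composes the displacement;
#' truncates it at constraints; and updates positions and previous
#' displacements. Dead cells do not move.
#'
#' @param plate plate state containing the cell population `plate$cells`.
#' @param params a [cell_type_params()].
#' @param dt step length, minutes.
#' @param pairs optional precomputed pair table at `repulsion_radius`.
#' @return the plate with updated cell positions.
#' @export
step_motion <- function(plate, params, dt = params$interval_ref,
                        pairs = NULL) {
  pop <- plate$cells
  n <- length(pop$id)
  if (!n) return(plate)
  conf <- if (is.null(pop$confluence)) rep(0, n) else pop$confluence
  k <- motion_k_total(pop, params, conf)
  k[pop$phase == "DEAD"] <- 0
  extra <- repulsion_bias(pop$x, pop$y, params, pairs = pairs)
  for (f in plate$fields) extra <- extra + gradient_bias(f, pop$x, pop$y,
                                                         params)
  comp <- effective_components(params, k, extra, dt = dt)
  rw <- random_walk_vector(comp$rand)
  pm <- sqrt(pop$pdx^2 + pop$pdy^2)
  has_prev <- pm > 1e-12
  ux <- ifelse(has_prev, pop$pdx / pm, 0)
  uy <- ifelse(has_prev, pop$pdy / pm, 0)
  d <- compose_displacement(rw, cbind(comp$pers * ux, comp$pers * uy),
                            comp$bias_vec)
  newpos <- apply_constraints(pop$x, pop$y, d[, 1], d[, 2], plate)
  # persistence follows the realised (post-constraint) displacement
  pop$pdx <- newpos$x - pop$x
  pop$pdy <- newpos$y - pop$y
  pop$x <- newpos$x
  pop$y <- newpos$y
  plate$cells <- pop
  plate
}
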