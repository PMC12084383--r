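# Scalar-field dynamics, local confluence and the scheduled event types.

EVENT_KINDS <- c("update", "mediumChange", "moleculeAddition",
                 "gradientAddition", "constraintRemoval",
                 "constraintAddition", "scratchOnPlate", "transfection",
                 "viralInfection")

#' Exponential decay of a scalar field
#'
#' Every lattice node is multiplied by `2^(-dt / half_life)`; fields with an
#' infinite half-life are returned unchanged. The decay is an exact
#' exponential, so two half-steps equal one full step.
#'
#' @param field a [scalar_field()].
#' @param dt minutes.
#' @return the decayed field.
#' @export
decay_field <- function(field, dt) {
  if (is.infinite(field$half_life)) return(field)
  field$lattice <- field$lattice * 2^(-dt / field$half_life)
  field
}

#' Local degradation of an attractant by cells
#'
#' Lattice nodes within the sensing radius of each live cell lose
#' `rate * dt` concentration (floored at zero). Overlapping cells deepen the
#' local pit, which is how dense regions self-generate steeper gradients
#' from a shallow or flat field.
#'
#' @param field a degradable [scalar_field()].
#' @param x,y positions of live cells, um.
#' @param dt minutes.
#' @param rate concentration removed per minute per cell
#'   (`attractant_degradation_rate`).
#' @param radius sensing radius, um.
#' @return the locally degraded field.
#' @export
degrade_locally <- function(field, x, y, dt, rate, radius) {
  if (!field$degradable_by_cells)
    stop("field is not degradable by cells")
  n <- length(x)
  if (!n || rate <= 0) return(field)
  cs <- field$cell_size
  nx <- nrow(field$lattice); ny <- ncol(field$lattice)
  rr <- ceiling(radius / cs)
  offs <- expand.grid(di = -rr:rr, dj = -rr:rr)
  offs <- offs[offs$di^2 + offs$dj^2 <= (radius / cs)^2, , drop = FALSE]
  i0 <- round((x - field$origin[1]) / cs) + 1L
  j0 <- round((y - field$origin[2]) / cs) + 1L
  ii <- rep(i0, each = nrow(offs)) + offs$di
  jj <- rep(j0, each = nrow(offs)) + offs$dj
  ok <- ii >= 1L & ii <= nx & jj >= 1L & jj <= ny
  lin <- (jj[ok] - 1L) * nx + ii[ok]
  hits <- tabulate(lin, nbins = nx * ny)
  field$lattice <- matrix(pmax(as.vector(field$lattice) -
                               rate * dt * hits, 0), nx, ny)
  field
}

# Per-cell confluence from a directed pair table (positional indices).
compute_confluence <- function(n, surface, pairs, radius) {
  conf <- numeric(n)
  if (nrow(pairs)) {
    s <- rowsum(surface[pairs$j], pairs$i)
    conf[as.integer(rownames(s))] <- s / (pi * radius^2)
  }
  pmin(conf, 1)
}

#' Local confluence around every cell
#'
#' Sum of the projected surfaces of the neighbours within `radius`, divided
#' by the disc area and clamped to 1.
#'
#' @param plate plate state.
#' @param radius neighbourhood radius, um.
#' @return per-cell confluence fractions in `[0, 1]`.
#' @export
local_confluence <- function(plate, radius) {
  pop <- plate$cells
  n <- length(pop$id)
  if (n < 2) return(numeric(n))
  pairs <- grid_pairs(neighbor_grid(pop$x, pop$y, radius), radius)
  compute_confluence(n, pop$surface, pairs, radius)
}

#' Build an event specification
#'
#' @param time minutes from the start of the run.
#' @param kind one of `update`, `mediumChange`, `moleculeAddition`,
#'   `gradientAddition`, `constraintAddition`, `constraintRemoval`,
#'   `scratchOnPlate`, `transfection`, `viralInfection`.
#' @param ... kind-specific payload fields (see [apply_event()]).
#' @return an object of class `event_spec`.
#' @export
event_spec <- function(time, kind, ...) {
  kind <- match.arg(kind, EVENT_KINDS)
  stopifnot(time >= 0)
  structure(list(time = time, kind = kind, payload = list(...)),
            class = "event_spec")
}

#' Apply a scheduled event to the plate
#'
#' Payloads by kind:
#' * `update` - none (scheduled marker; the engine updates every interval).
#' * `mediumChange` - `serum_type`, `serum_level`, optional `molecules`
#'   (named concentrations; replaces the molecule map).
#' * `moleculeAddition` - `name`, `concentration` (added to the medium).
#' * `gradientAddition` - `name`, `value`, optional `region`
#'   (`x0`,`x1`,`y0`,`y1`; value outside is 0), `cell_size` (default 10),
#'   `half_life` (default `Inf`), `degradable` (default TRUE), `bias_gain`.
#' * `constraintAddition` - `id`, `type` (`"block"` or `"slow"`),
#'   `x0`,`x1`,`y0`,`y1`, `factor` (slow regions).
#' * `constraintRemoval` - `id`.
#' * `scratchOnPlate` - `x0`,`x1`,`y0`,`y1` band: cells inside become
#'   DAMAGED at damage level 1 and a short-lived degradable "debris"
#'   attractant field is deposited in the band (`debris_value`,
#'   `debris_half_life` default 240 min, `debris_gain`).
#' * `transfection` - `gene`, `efficiency`: each live cell independently
#'   acquires the gene with the stated efficiency.
#' * `viralInfection` - `n_initial` (or `region`), `lysis_time` (default
#'   540 min), `radius`, `prob`: inoculated cells start an infection timer;
#'   on expiry they lyse and infect neighbours within `radius` with
#'   probability `prob`.
#'
#' @param plate plate state.
#' @param event an [event_spec()].
#' @param params the experiment's [cell_type_params()] (used for surfaces
#'   and field defaults).
#' @return the perturbed plate.
#' @export
apply_event <- function(plate, event, params = NULL) {
  p <- event$payload
  pop <- plate$cells
  switch(event$kind,
    update = plate,
    mediumChange = {
      if (!is.null(p$serum_type)) plate$medium$serum_type <- p$serum_type
      if (!is.null(p$serum_level)) plate$medium$serum_level <- p$serum_level
      plate$medium$molecules <- if (is.null(p$molecules)) list()
        else as.list(p$molecules)
      plate
    },
    moleculeAddition = {
      cur <- plate$medium$molecules[[p$name]]
      plate$medium$molecules[[p$name]] <-
        (if (is.null(cur)) 0 else cur) + p$concentration
      plate
    },
    gradientAddition = {
      cs <- if (is.null(p$cell_size)) 10 else p$cell_size
      f <- uniform_field(plate$width, plate$height, 0, cell_size = cs,
                         half_life = if (is.null(p$half_life)) Inf
                                     else p$half_life,
                         degradable_by_cells =
                           if (is.null(p$degradable)) TRUE else p$degradable,
                         bias_gain = if (is.null(p$bias_gain)) 1
                                     else p$bias_gain,
                         name = p$name)
      xs <- (seq_len(nrow(f$lattice)) - 1L) * cs
      ys <- (seq_len(ncol(f$lattice)) - 1L) * cs
      inside <- if (is.null(p$region)) matrix(TRUE, length(xs), length(ys))
        else outer(xs >= p$region$x0 & xs <= p$region$x1,
                   ys >= p$region$y0 & ys <= p$region$y1, `&`)
      f$lattice[inside] <- p$value
      plate$fields[[p$name]] <- f
      plate
    },
    constraintAddition = {
      plate$constraints[[p$id]] <- p
      plate
    },
    constraintRemoval = {
      plate$constraints[[p$id]] <- NULL
      plate
    },
    scratchOnPlate = {
      if (length(pop$id)) {
        inside <- pop$x >= p$x0 & pop$x <= p$x1 &
          pop$y >= p$y0 & pop$y <= p$y1 & pop$phase != "DEAD"
        pop$phase[inside] <- "DAMAGED"
        pop$damage[inside] <- 1
        plate$cells <- pop
      }
      dv <- if (is.null(p$debris_value)) 2 else p$debris_value
      if (dv > 0) {
        ev <- event_spec(event$time, "gradientAddition", name = "debris",
                         value = dv,
                         region = list(x0 = p$x0, x1 = p$x1,
                                       y0 = p$y0, y1 = p$y1),
                         half_life = if (is.null(p$debris_half_life)) 240
                                     else p$debris_half_life,
                         degradable = TRUE,
                         bias_gain = if (is.null(p$debris_gain)) 1
                                     else p$debris_gain)
        plate <- apply_event(plate, ev, params)
      }
      plate
    },
    transfection = {
      stopifnot(p$efficiency >= 0, p$efficiency <= 1)
      if (length(pop$id)) {
        live <- pop$phase != "DEAD"
        hit <- live & stats::runif(length(pop$id)) < p$efficiency
        pop$genes[hit] <- lapply(pop$genes[hit], function(g)
          unique(c(g, p$gene)))
        plate$cells <- pop
      }
      plate
    },
    viralInfection = {
      lt <- if (is.null(p$lysis_time)) 540 else p$lysis_time
      plate$infection <- list(
        lysis_time = lt,
        radius = if (is.null(p$radius)) 25 else p$radius,
        prob = if (is.null(p$prob)) 0.7 else p$prob)
      if (length(pop$id)) {
        live <- which(pop$phase != "DEAD")
        tgt <- if (!is.null(p$region)) {
          live[pop$x[live] >= p$region$x0 & pop$x[live] <= p$region$x1 &
               pop$y[live] >= p$region$y0 & pop$y[live] <= p$region$y1]
        } else {
          nini <- if (is.null(p$n_initial)) 1L else p$n_initial
          cx <- plate$width / 2; cy <- plate$height / 2
          live[order((pop$x[live] - cx)^2 +
                     (pop$y[live] - cy)^2)][seq_len(min(nini, length(live)))]
        }
        pop$infect[tgt] <- lt
        plate$cells <- pop
      }
      plate
    },
    stop("unknown event kind: ", event$kind))
}
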