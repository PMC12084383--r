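# Attachment Markov chain and the volume -> projected surface relation.

#' Projected surface of a cell
#'
#' A detached cell presents a sphere-like footprint proportional to
#' `V^(2/3)`; spreading enlarges the footprint up to `spread_gain`-fold:
#' \deqn{S = c V^{2/3} (1 + (s_{max} - 1) f_{spread})}
#' Monotone in both volume and spread fraction.
#'
#' @param volume cell volume(s), um^3 (> 0).
#' @param spread_fraction spread fraction(s) in `[0, 1]`.
#' @param params a [cell_type_params()] supplying `surface_coef` and
#'   `spread_gain`.
#' @return projected surface(s), um^2.
#' @export
projected_surface <- function(volume, spread_fraction, params) {
  stopifnot(all(volume > 0), all(spread_fraction >= 0),
            all(spread_fraction <= 1))
  params$surface_coef * volume^(2 / 3) *
    (1 + (params$spread_gain - 1) * spread_fraction)
}

#' Advance the attachment chain by one step
#'
#' `DETACHED -> ATTACHED -> SPREADING -> SPREAD` transitions are drawn with
#' interval-adapted probabilities; `SPREADING` advances the spread fraction
#' linearly, `DESPREADING` runs it back to the mitotic minimum. Entering M
#' or apoptosis forces a cell into `DESPREADING`; recovered or re-cycling
#' cells resume spreading. The projected surface is refreshed at the end of
#' the step.
#'
#' @param plate plate state.
#' @param params a [cell_type_params()].
#' @param dt step length, minutes.
#' @return updated plate.
#' @export
step_attachment <- function(plate, params, dt = params$interval_ref) {
  pop <- plate$cells
  n <- length(pop$id)
  if (!n) return(plate)
  forced <- pop$phase %in% c("M", "APO")
  pop$attach[forced] <- "DESPREADING"
  # attached cells whose forcing phase ended resume spreading
  resume <- !forced & pop$attach == "DESPREADING" & pop$phase != "DEAD"
  pop$attach[resume] <- "SPREADING"
  det <- which(pop$attach == "DETACHED" & pop$phase != "DEAD")
  if (length(det)) {
    p <- adapt_probability(params$attach_probs[["attach"]],
                           params$interval_ref, dt)
    hit <- det[stats::runif(length(det)) < p]
    pop$attach[hit] <- "ATTACHED"
  }
  att <- which(pop$attach == "ATTACHED" & pop$phase != "DEAD")
  if (length(att)) {
    p <- adapt_probability(params$attach_probs[["spread_start"]],
                           params$interval_ref, dt)
    hit <- att[stats::runif(length(att)) < p]
    pop$attach[hit] <- "SPREADING"
  }
  spr <- pop$attach == "SPREADING"
  pop$spread[spr] <- pmin(pop$spread[spr] + dt / params$spread_time, 1)
  done <- spr & pop$spread >= 1
  pop$attach[done] <- "SPREAD"
  dsp <- pop$attach == "DESPREADING"
  pop$spread[dsp] <- pmax(pop$spread[dsp] - dt / params$despread_time,
                          params$spread_min)
  pop$surface <- projected_surface(pop$volume, pop$spread, params)
  plate$cells <- pop
  plate
}
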