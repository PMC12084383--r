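# Cycle-progression Markov chain: phase transitions, exponential volume
# growth, division, quiescence, apoptosis, damage, and reporter kinetics.

#' Exponential volume growth
#'
#' \deqn{V_{t+\Delta t} = V_t e^{\alpha \Delta t}} with `alpha` the phase- and
#' cell-specific per-minute growth rate (already including the per-cell
#' growth modifier and any serum scaling).
#'
#' @param volume current volume(s), um^3.
#' @param alpha per-minute growth rate(s).
#' @param dt minutes.
#' @return grown volume(s).
#' @export
grow_volume <- function(volume, alpha, dt) {
  stopifnot(all(volume > 0), dt >= 0)
  volume * exp(alpha * dt)
}

# Effective per-minute growth rate for each cell.
growth_rate <- function(pop, params, serum_level) {
  mult <- params$phase_growth_mult[pop$phase]
  s <- 1
  if (!is.null(params$serum_growth)) {
    f <- params$serum_growth
    k <- if (f$direction == "enhancing") -f$k_steep else f$k_steep
    s <- logistic_effect(serum_level, f$x_ref, k)
  }
  s <- rep(s, length.out = length(pop$id))
  gr <- params$gene_growth_rescue
  if (!is.null(gr)) {
    has <- vapply(pop$genes, function(g) gr$gene %in% g, TRUE)
    s[has] <- pmax(s[has], gr$floor)
  }
  unname(params$alpha_growth * mult * pop$grm * s)
}

# Factor-effect context shared by cycle transitions.
cycle_ctx <- function(pop, plate, idx) {
  list(serum_level = plate$medium$serum_level,
       molecules = plate$medium$molecules,
       volume = pop$volume[idx], vitality = pop$vitality[idx],
       confluence = pop$confluence[idx], attach = pop$attach[idx],
       genes = pop$genes[idx])
}

#' Advance the cell cycle chain by one step
#'
#' For every live cell, at most one phase transition is drawn. Each outgoing
#' edge's probability is its base probability attenuated by the logistic
#' effects of its factors ([combine_factor_effects()]) and adapted to the
#' step length ([adapt_probability()]). Hard gates apply on top of the
#' probabilities: `G1c -> S` requires DNA ready for duplication (rfdDNA) and
#' `S -> G2` requires complete DNA duplication. DNA replication advances
#' linearly through S; volumes grow exponentially; ages increase. Cells
#' whose `M -> DIVIDE` draw succeeds are flagged in `plate$cells$divide` and
#' split by the engine at the end of the interval.
#'
#' @param plate plate state with cell population.
#' @param params a [cell_type_params()].
#' @param dt step length, minutes.
#' @return the updated plate.
#' @export
step_cycle <- function(plate, params, dt = params$interval_ref) {
  pop <- plate$cells
  n <- length(pop$id)
  if (!n) return(plate)
  if (is.null(pop$confluence)) pop$confluence <- rep(0, n)
  pop$divide <- rep(FALSE, n)
  in_S_before <- pop$phase == "S"
  edges <- params$transition_edges
  from_set <- unique(vapply(edges, `[[`, "", "from"))
  new_phase <- pop$phase
  for (ph in from_set) {
    idx <- which(pop$phase == ph)
    if (!length(idx)) next
    es <- edges[vapply(edges, function(e) e$from == ph, TRUE)]
    ctx <- cycle_ctx(pop, plate, idx)
    probs <- matrix(0, length(idx), length(es))
    for (k in seq_along(es)) {
      e <- es[[k]]
      p <- rep(e$base_prob, length(idx))
      for (f in e$factors) p <- p * eval_factor(f, ctx, length(idx))
      p <- adapt_probability(pmin(p, 1), e$prob_time, dt)
      if (ph == "G1c" && e$to == "S") p[!pop$rfd[idx]] <- 0
      if (ph == "S" && e$to == "G2") p[pop$dna[idx] < 1] <- 0
      probs[, k] <- p
    }
    tot <- rowSums(probs)
    over <- tot > 1
    if (any(over)) probs[over, ] <- probs[over, , drop = FALSE] / tot[over]
    u <- stats::runif(length(idx))
    acc <- rep(0, length(idx))
    chosen <- integer(length(idx))
    for (k in seq_along(es)) {
      sel <- chosen == 0L & u < acc + probs[, k]
      chosen[sel] <- k
      acc <- acc + probs[, k]
    }
    for (k in seq_along(es)) {
      sel <- idx[chosen == k]
      if (!length(sel)) next
      to <- es[[k]]$to
      if (to == "DIVIDE") {
        pop$divide[sel] <- TRUE
      } else {
        new_phase[sel] <- to
        if (to == "G1c") pop$rfd[sel] <- TRUE
        if (to == "S") { pop$dna[sel] <- 0; pop$rfd[sel] <- FALSE }
      }
    }
  }
  pop$phase <- new_phase
  alive <- pop$phase != "DEAD"
  # DNA advances for cells that started the step in S
  adv <- in_S_before & pop$phase %in% c("S", "G2")
  pop$dna[adv] <- pmin(pop$dna[adv] + dt / params$s_duration, 1)
  al <- growth_rate(pop, params, plate$medium$serum_level)
  pop$volume[alive] <- grow_volume(pop$volume[alive], al[alive], dt)
  pop$age[alive] <- pop$age[alive] + dt
  plate$cells <- pop
  plate
}

#' Split flagged mitotic cells into daughter pairs
#'
#' Each parent produces two G1 daughters of age 0 whose volumes sum to the
#' parent volume (optionally asymmetric), positioned one cell radius apart
#' in a random direction, both inheriting the parent's genes and starting to
#' re-spread; each daughter draws a fresh growth-rate modifier.
#'
#' @param pop cell population list.
#' @param idx indices of parents to split.
#' @param params a [cell_type_params()].
#' @param plate plate state (for clamping daughter positions).
#' @param next_id first id to assign to daughters.
#' @return list with the updated `pop` (parents removed, daughters appended),
#'   `daughters` (data.frame id/parent) and `next_id`.
#' @export
divide <- function(pop, idx, params, plate, next_id) {
  nd <- length(idx)
  if (!nd) return(list(pop = pop, daughters = NULL, next_id = next_id))
  frac <- 0.5
  if (params$division_asym > 0)
    frac <- pmin(pmax(stats::rnorm(nd, 0.5, params$division_asym), 0.3), 0.7)
  vol <- pop$volume[idx]
  v1 <- vol * frac; v2 <- vol - v1
  r <- (3 * vol / (4 * pi))^(1 / 3)
  th <- stats::runif(nd, 0, 2 * pi)
  x1 <- pmin(pmax(pop$x[idx] + r * cos(th), 0), plate$width)
  y1 <- pmin(pmax(pop$y[idx] + r * sin(th), 0), plate$height)
  x2 <- pmin(pmax(pop$x[idx] - r * cos(th), 0), plate$width)
  y2 <- pmin(pmax(pop$y[idx] - r * sin(th), 0), plate$height)
  ids <- next_id + seq_len(2L * nd) - 1L
  parent_ids <- pop$id[idx]
  daught <- list(
    id = ids,
    x = as.vector(rbind(x1, x2)), y = as.vector(rbind(y1, y2)),
    volume = as.vector(rbind(v1, v2)),
    phase = rep("G1", 2L * nd), attach = rep("SPREADING", 2L * nd),
    age = rep(0, 2L * nd), vitality = rep(pop$vitality[idx], each = 2L),
    dna = rep(0, 2L * nd), rfd = rep(FALSE, 2L * nd),
    pdx = rep(0, 2L * nd), pdy = rep(0, 2L * nd),
    spread = rep(params$spread_min, 2L * nd),
    cdt1 = rep(pop$cdt1[idx], each = 2L),
    p27 = rep(pop$p27[idx], each = 2L),
    grm = exp(stats::rnorm(2L * nd, 0, params$growth_modifier_sd)),
    damage = rep(pop$damage[idx], each = 2L),
    infect = rep(pop$infect[idx], each = 2L),
    genes = rep(pop$genes[idx], each = 2L),
    confluence = rep(pop$confluence[idx], each = 2L),
    divide = rep(FALSE, 2L * nd),
    newborn = rep(TRUE, 2L * nd))
  daught$surface <- projected_surface(daught$volume, daught$spread, params)
  keep <- setdiff(seq_along(pop$id), idx)
  pop <- pop_subset(pop, keep)
  pop <- pop_bind(pop, daught)
  list(pop = pop,
       daughters = data.frame(id = ids, parent = rep(parent_ids, each = 2L)),
       next_id = next_id + 2L * nd)
}

#' Update vitality, apoptosis, damage and infection state
#'
#' Apoptotic cells lose vitality linearly and die at zero. Drug molecules in
#' the medium drain vitality according to the cell type's sensitivity unless
#' a protective gene is present. Damaged cells die or recover with
#' probabilities shaped by the damage level through the logistic effect
#' (recovery dominates below damage 0.5); otherwise the damage decays.
#' Infected cells count down to lysis, upon which they die and expose their
#' neighbours within the infection radius to new infection.
#'
#' @param plate plate state.
#' @param params a [cell_type_params()].
#' @param dt step length, minutes.
#' @param grid optional prebuilt [neighbor_grid()] for infection spread.
#' @return updated plate.
#' @export
update_vitality <- function(plate, params, dt = params$interval_ref,
                            grid = NULL) {
  pop <- plate$cells
  n <- length(pop$id)
  if (!n) return(plate)
  apo <- pop$phase == "APO"
  pop$vitality[apo] <- pop$vitality[apo] - dt / params$apo_decay_time
  for (mol in names(params$drug_sensitivity)) {
    conc <- plate$medium$molecules[[mol]]
    if (is.null(conc) || conc <= 0) next
    ds <- params$drug_sensitivity[[mol]]
    immune <- if (is.null(ds$resistance_gene)) rep(FALSE, n)
      else vapply(pop$genes, function(g) ds$resistance_gene %in% g, TRUE)
    hit <- !immune & pop$phase != "DEAD"
    pop$vitality[hit] <- pop$vitality[hit] - ds$rate * conc * dt
  }
  pop$vitality <- pmin(pmax(pop$vitality, 0), 1)
  dead_now <- pop$vitality <= 0 & pop$phase != "DEAD"
  pop$phase[dead_now] <- "DEAD"
  dmg <- which(pop$phase == "DAMAGED")
  if (length(dmg)) {
    eff_die <- logistic_effect(pop$damage[dmg], 0.5, -params$damage_steepness)
    p_die <- adapt_probability(params$damage_death_prob * eff_die,
                               params$interval_ref, dt)
    p_rec <- adapt_probability(params$damage_death_prob * (1 - eff_die),
                               params$interval_ref, dt)
    u <- stats::runif(length(dmg))
    die <- u < p_die
    rec <- !die & u < p_die + p_rec
    pop$phase[dmg[die]] <- "DEAD"
    pop$vitality[dmg[die]] <- 0
    pop$phase[dmg[rec]] <- "G1"
    pop$damage[dmg[rec]] <- 0
    rest <- dmg[!die & !rec]
    pop$damage[rest] <- pmax(pop$damage[rest] -
                             params$damage_decay_rate * dt, 0)
  }
  if (!is.null(plate$infection)) {
    inf <- which(!is.na(pop$infect) & pop$phase != "DEAD")
    if (length(inf)) {
      pop$infect[inf] <- pop$infect[inf] - dt
      burst <- inf[pop$infect[inf] <= 0]
      if (length(burst)) {
        pop$phase[burst] <- "DEAD"
        pop$vitality[burst] <- 0
        if (is.null(grid))
          grid <- neighbor_grid(pop$x, pop$y,
                                max(plate$infection$radius, 1))
        for (b in burst) {
          nb <- grid_query(grid, pop$x[b], pop$y[b], plate$infection$radius)
          nb <- nb[pop$phase[nb] != "DEAD" & is.na(pop$infect[nb])]
          if (!length(nb)) next
          newly <- nb[stats::runif(length(nb)) < plate$infection$prob]
          pop$infect[newly] <- plate$infection$lysis_time
        }
      }
    }
  }
  plate$cells <- pop
  plate
}

#' Default cdt1 / p27 reporter kinetics
#'
#' First-order synthesis/decay rates per cycle phase, calibrated so that p27
#' accumulates to a high steady state only in quiescent cells while cdt1 is
#' high through G1/G0 and degraded during S — the joint pattern used to read
#' cycle state off a (cdt1, p27) scatter.
#'
#' @return list with `cdt1` and `p27`, each holding named per-phase `synth`
#'   (units/min) and `decay` (1/min) vectors.
#' @export
default_reporter_rates <- function() {
  ph <- CYCLE_PHASES
  mk <- function(...) {
    v <- c(...)
    stopifnot(all(ph %in% names(v)))
    v[ph]
  }
  list(
    cdt1 = list(
      synth = mk(G1 = 1, G1c = 1, S = 0, G2 = 0.15, M = 0.15, G0 = 1,
                 APO = 0, DAMAGED = 0.5, DEAD = 0),
      decay = mk(G1 = 0.01, G1c = 0.01, S = 0.05, G2 = 0.01, M = 0.01,
                 G0 = 0.008, APO = 0.02, DAMAGED = 0.01, DEAD = 0.01)),
    p27 = list(
      synth = mk(G1 = 0.06, G1c = 0.03, S = 0.03, G2 = 0.03, M = 0.03,
                 G0 = 1.2, APO = 0.1, DAMAGED = 0.3, DEAD = 0),
      decay = mk(G1 = 0.012, G1c = 0.012, S = 0.012, G2 = 0.012, M = 0.012,
                 G0 = 0.006, APO = 0.012, DAMAGED = 0.012, DEAD = 0.012)))
}

#' Update cdt1 and p27 reporter concentrations
#'
#' Exact update of the linear synthesis-degradation kinetics over one step:
#' each reporter relaxes exponentially towards its phase-dependent steady
#' state `synth / decay`.
#'
#' @param plate plate state.
#' @param params a [cell_type_params()].
#' @param dt step length, minutes.
#' @return updated plate.
#' @export
update_reporters <- function(plate, params, dt = params$interval_ref) {
  pop <- plate$cells
  if (!length(pop$id)) return(plate)
  for (rep_name in c("cdt1", "p27")) {
    rr <- params$reporter_rates[[rep_name]]
    synth <- rr$synth[pop$phase]
    decay <- rr$decay[pop$phase]
    ss <- ifelse(decay > 0, synth / decay, 0)
    pop[[rep_name]] <- unname(ss + (pop[[rep_name]] - ss) * exp(-decay * dt))
  }
  plate$cells <- pop
  plate
}
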