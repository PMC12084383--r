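# Core vocabulary and elementary primitives shared by all modules.

#' Cell cycle phase labels
#'
#' The nine states of the cycle-progression Markov chain: the main loop
#' `G1 -> G1c -> S -> G2 -> M`, the quiescent state `G0`, plus apoptosis
#' (`APO`), physical damage (`DAMAGED`) and the absorbing `DEAD` state.
#' `G1c` is the committed late-G1 sub-state between the G1 checkpoint and
#' S-phase entry.
#'
#' @export
CYCLE_PHASES <- c("G1", "G1c", "S", "G2", "M", "G0", "APO", "DAMAGED", "DEAD")

#' Attachment phase labels
#'
#' States of the attachment Markov chain for cells interacting with the
#' culture substratum: a freely floating cell (`DETACHED`) makes a first
#' stable contact (`ATTACHED`), flattens out (`SPREADING`) until fully
#' `SPREAD`; mitosis and apoptosis force cells into `DESPREADING`.
#'
#' @export
ATTACH_PHASES <- c("DETACHED", "ATTACHED", "SPREADING", "SPREAD", "DESPREADING")

#' Recognised factor quantities
#'
#' Quantities a [factor_spec()] may read when modulating a transition
#' probability.
#'
#' @export
FACTOR_QUANTITIES <- c("serum_level", "volume", "local_confluence", "vitality",
                       "drug_level", "attachment_state", "gene_presence")

#' Origin and destiny labels for tracked paths
#'
#' How a tracked cell path begins (`start`: present in the first frame;
#' `newborn`: created by a division; `found`: picked up mid-experiment;
#' `gone in`: entered the field of view) and ends (`split`: divided; `dead`;
#' `lost`: tracking ended; `gone out`: left the field of view).
#'
#' @export
ORIGIN_LABELS <- c("start", "newborn", "found", "gone in")

#' @rdname ORIGIN_LABELS
#' @export
DESTINY_LABELS <- c("split", "dead", "lost", "gone out")

#' Adapt a transition probability to the simulation time interval
#'
#' A probability `prob` defined over a reference time `prob_time` is converted
#' to the equivalent per-step probability for a step of length `time_int`,
#' assuming a memoryless hazard:
#' \deqn{p_{\Delta t} = 1 - (1 - p)^{\Delta t / T}}
#' Survival probabilities therefore multiply exactly across sub-steps, so the
#' chain behaves consistently for any update interval between a few minutes
#' and a few hours.
#'
#' @param prob transition probability in `[0, 1]` (vectorised).
#' @param prob_time minutes over which `prob` is defined; must be positive.
#' @param time_int simulation step length in minutes; must be positive.
#' @return adapted probability, same length as the broadcast arguments.
#' @examples
#' adapt_probability(0.5, 60, 120)  # 0.75
#' @export
adapt_probability <- function(prob, prob_time, time_int) {
  if (any(prob < 0 | prob > 1)) stop("`prob` must lie in [0, 1]")
  if (any(prob_time <= 0) || any(time_int <= 0))
    stop("`prob_time` and `time_int` must be positive")
  1 - (1 - prob)^(time_int / prob_time)
}

#' Logistic effect of a factor on a transition
#'
#' Maps the current value of a quantity onto the `(0, 1)` interval:
#' \deqn{eff = 1 / (1 + e^{k (X_c - X_{ref})})}
#' `x_ref` is the value at which the effect is exactly 0.5 and `k_steep` the
#' logistic steepness. With `k_steep > 0` the effect decreases in `x_c`
#' (a limiting factor); an enhancing factor is obtained by negating the
#' steepness (see [factor_spec()]). The exponent is clamped so extreme
#' arguments saturate at 0/1 without overflow.
#'
#' @param x_c current value of the quantity (vectorised).
#' @param x_ref value at which the effect is 0.5, same units as `x_c`.
#' @param k_steep logistic steepness, inverse units of `x_c`; may be negative.
#' @return effect in `(0, 1)`.
#' @examples
#' logistic_effect(5, 5, 2)           # 0.5 at the midpoint
#' logistic_effect(5 - log(9), 5, 1)  # 0.9
#' @export
logistic_effect <- function(x_c, x_ref, k_steep) {
  stopifnot(is.finite(x_ref), is.finite(k_steep))
  z <- pmin(pmax(k_steep * (x_c - x_ref), -700), 700)
  1 / (1 + exp(z))
}

#' Combine factor effects with a base probability
#'
#' Effects attenuate the base probability multiplicatively:
#' `base_prob * prod(effects)`, clamped to `[0, 1]`. An empty effect list
#' returns the base probability unchanged.
#'
#' @param base_prob probability in `[0, 1]`.
#' @param effects numeric vector (or list) of effects in `[0, 1]`.
#' @return combined probability in `[0, 1]`.
#' @export
combine_factor_effects <- function(base_prob, effects) {
  effects <- unlist(effects, use.names = FALSE)
  if (any(base_prob < 0 | base_prob > 1)) stop("`base_prob` must lie in [0, 1]")
  if (length(effects) && any(effects < 0 | effects > 1))
    stop("effects must lie in [0, 1]")
  p <- base_prob * prod(effects)
  pmin(pmax(p, 0), 1)
}

#' Describe one factor modulating a transition probability
#'
#' @param quantity one of [FACTOR_QUANTITIES].
#' @param x_ref value of the quantity at which the effect is 0.5.
#' @param k_steep positive logistic steepness (inverse units of the quantity).
#' @param direction `"limiting"` (effect decreases as the quantity grows) or
#'   `"enhancing"` (effect increases as the quantity grows).
#' @param name for `drug_level` / `gene_presence`, the molecule or gene label.
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(quantity, x_ref, k_steep,
                        direction = c("limiting", "enhancing"), name = NULL) {
  direction <- match.arg(direction)
  quantity <- match.arg(quantity, FACTOR_QUANTITIES)
  stopifnot(is.finite(x_ref), is.finite(k_steep), k_steep >= 0)
  if (quantity %in% c("drug_level", "gene_presence") && is.null(name))
    stop("factors on '", quantity, "' need a `name` (molecule or gene label)")
  structure(list(quantity = quantity, x_ref = x_ref, k_steep = k_steep,
                 direction = direction, name = name),
            class = "factor_spec")
}

# Evaluate a factor for every cell in `ctx`, a list with vectors `volume`,
# `vitality`, `confluence`, `attach`, list-column `genes`, scalar
# `serum_level` and named vector `molecules`. Returns effects in (0,1).
eval_factor <- function(f, ctx, n) {
  x <- switch(f$quantity,
    serum_level      = rep(ctx$serum_level, n),
    volume           = ctx$volume,
    local_confluence = ctx$confluence,
    vitality         = ctx$vitality,
    drug_level       = rep(if (is.null(ctx$molecules[[f$name]])) 0
                           else ctx$molecules[[f$name]], n),
    attachment_state = as.numeric(ctx$attach %in% c("DETACHED", "ATTACHED")),
    gene_presence    = vapply(ctx$genes, function(g) as.numeric(f$name %in% g),
                              numeric(1))
  )
  k <- if (f$direction == "enhancing") -f$k_steep else f$k_steep
  logistic_effect(x, f$x_ref, k)
}

#' Define one edge of a cycle (or attachment) transition table
#'
#' @param from,to phase labels.
#' @param base_prob transition probability over `prob_time` minutes under
#'   optimal conditions (all factor effects = 1).
#' @param prob_time minutes over which `base_prob` is defined.
#' @param factors list of [factor_spec()] objects; their effects multiply the
#'   base probability before interval adaptation.
#' @return an object of class `transition_edge`.
#' @export
transition_edge <- function(from, to, base_prob, prob_time = 20,
                            factors = list()) {
  stopifnot(base_prob >= 0, base_prob <= 1, prob_time > 0)
  structure(list(from = from, to = to, base_prob = base_prob,
                 prob_time = prob_time, factors = factors),
            class = "transition_edge")
}

#' Per-cell-type parameter set
#'
#' Bundles every constant that defines a cell type: motion fractions and the
#' reference displacement, growth rates by phase, the cycle transition table,
#' attachment kinetics, repulsion and gradient-sensing parameters and drug
#' sensitivities. `r_frac + p_frac + b_frac` must equal 1; they are the shares
#' of the maximum potential displacement `d_ref` assigned to the random,
#' persistence and bias components.
#'
#' @param name cell type label.
#' @param d_ref maximum potential displacement, um per reference interval
#'   (`interval_ref` minutes) under optimal conditions.
#' @param r_frac,p_frac,b_frac random / persistence / bias fractions
#'   (sum to 1).
#' @param bias_angle direction of the global bias component, radians.
#' @param interval_ref minutes of the reference interval for `d_ref`.
#' @param alpha_growth per-minute volumetric growth rate under optimal serum.
#' @param phase_growth_mult named multipliers of `alpha_growth` by cycle phase.
#' @param serum_growth factor_spec scaling growth with serum level (or NULL).
#' @param v_birth typical post-division volume, um^3.
#' @param s_duration minutes needed to replicate the genome in S phase.
#' @param transition_edges list of [transition_edge()] for the cycle chain.
#' @param phase_motility,attach_motility named movement multipliers by cycle
#'   and attachment phase (components of the cumulative coefficient k).
#' @param confluence_motility factor_spec scaling movement with local
#'   confluence (or NULL).
#' @param confluence_radius um radius of the local-confluence neighbourhood.
#' @param repulsion_radius um radius within which neighbours repel.
#' @param repulsion_sensitivity dimensionless repulsion strength.
#' @param sensing_distance um span over which attractant gradients are sampled
#'   (the size of the cell body).
#' @param attractant_degradation_rate concentration units removed per minute
#'   per cell from degradable attractant fields near the cell.
#' @param attach_probs named per-`interval_ref` probabilities `attach`
#'   (DETACHED -> ATTACHED) and `spread_start` (ATTACHED -> SPREADING).
#' @param spread_time,despread_time minutes to fully spread / de-spread.
#' @param spread_min minimum spread fraction kept by mitotic cells.
#' @param surface_coef,spread_gain projected-surface law constants: surface =
#'   `surface_coef * V^(2/3) * (1 + (spread_gain - 1) * spread_fraction)`.
#' @param division_asym sd of the Gaussian asymmetry of the daughter volume
#'   split (0 = exact halves).
#' @param growth_modifier_sd sd (log scale) of the per-cell lognormal growth
#'   rate modifier.
#' @param apo_decay_time minutes for an apoptotic cell to lose all vitality.
#' @param damage_death_prob,damage_steepness,damage_decay_rate DAMAGED-state
#'   resolution: per-`interval_ref` probability scale of dying/recovering,
#'   logistic steepness on damage level (midpoint 0.5), and passive damage
#'   decay per minute.
#' @param reporter_rates list with `cdt1` and `p27` elements, each a list of
#'   named per-phase `synth` and `decay` rates (units / min and 1 / min).
#' @param drug_sensitivity named list: molecule label -> list(rate = vitality
#'   loss per concentration unit per minute, resistance_gene = gene label that
#'   confers immunity or NULL).
#' @param gene_growth_rescue optional list(gene, floor): cells carrying
#'   `gene` have their serum growth multiplier floored at `floor`
#'   (constitutive growth signalling, e.g. activated Ras).
#' @param gradient_cap maximum module (um) of a single gradient bias vector;
#'   defaults to `d_ref`.
#' @return an object of class `cell_type_params`.
#' @export
cell_type_params <- function(name, d_ref, r_frac, p_frac, b_frac,
                             bias_angle = 0, interval_ref = 20,
                             alpha_growth, phase_growth_mult,
                             serum_growth = NULL,
                             v_birth = 1000, s_duration = 400,
                             transition_edges = list(),
                             phase_motility, attach_motility,
                             confluence_motility = NULL,
                             confluence_radius = 60,
                             repulsion_radius = 40,
                             repulsion_sensitivity = 0.5,
                             sensing_distance = 30,
                             attractant_degradation_rate = 0.002,
                             attach_probs = c(attach = 0.5, spread_start = 0.6),
                             spread_time = 120, despread_time = 60,
                             spread_min = 0.2,
                             surface_coef = 1.21, spread_gain = 4,
                             division_asym = 0.05,
                             growth_modifier_sd = 0.1,
                             apo_decay_time = 240,
                             damage_death_prob = 0.3,
                             damage_steepness = 8,
                             damage_decay_rate = 0.003,
                             reporter_rates = default_reporter_rates(),
                             drug_sensitivity = list(),
                             gene_growth_rescue = NULL,
                             gradient_cap = NULL) {
  fr <- c(r_frac, p_frac, b_frac)
  if (abs(sum(fr) - 1) > 1e-9)
    stop("r_frac + p_frac + b_frac must equal 1")
  if (any(fr < 0)) stop("component fractions must be non-negative")
  stopifnot(d_ref > 0, v_birth > 0, s_duration > 0, alpha_growth >= 0,
            repulsion_radius > 0, confluence_radius > 0, sensing_distance > 0,
            attractant_degradation_rate >= 0)
  if (any(attach_probs < 0 | attach_probs > 1))
    stop("attachment probabilities must lie in [0, 1]")
  for (e in transition_edges) {
    if (!inherits(e, "transition_edge")) stop("bad transition edge")
    if (!e$from %in% CYCLE_PHASES || !all(e$to %in% c(CYCLE_PHASES, "DIVIDE")))
      stop("unknown phase in transition edge ", e$from, " -> ", e$to)
    if (e$from == "DEAD") stop("no transitions may leave DEAD")
  }
  structure(list(
    name = name, d_ref = d_ref, r_frac = r_frac, p_frac = p_frac,
    b_frac = b_frac, bias_angle = bias_angle, interval_ref = interval_ref,
    alpha_growth = alpha_growth, phase_growth_mult = phase_growth_mult,
    serum_growth = serum_growth, v_birth = v_birth, s_duration = s_duration,
    transition_edges = transition_edges, phase_motility = phase_motility,
    attach_motility = attach_motility,
    confluence_motility = confluence_motility,
    confluence_radius = confluence_radius,
    repulsion_radius = repulsion_radius,
    repulsion_sensitivity = repulsion_sensitivity,
    sensing_distance = sensing_distance,
    attractant_degradation_rate = attractant_degradation_rate,
    attach_probs = attach_probs, spread_time = spread_time,
    despread_time = despread_time, spread_min = spread_min,
    surface_coef = surface_coef, spread_gain = spread_gain,
    division_asym = division_asym, growth_modifier_sd = growth_modifier_sd,
    apo_decay_time = apo_decay_time, damage_death_prob = damage_death_prob,
    damage_steepness = damage_steepness, damage_decay_rate = damage_decay_rate,
    reporter_rates = reporter_rates, drug_sensitivity = drug_sensitivity,
    gene_growth_rescue = gene_growth_rescue,
    gradient_cap = if (is.null(gradient_cap)) d_ref else gradient_cap),
    class = "cell_type_params")
}

#' @export
print.cell_type_params <- function(x, ...) {
  cat("<cell_type_params>", x$name, "\n")
  cat(sprintf("  d_ref %.2f um/%d min; fractions r=%.2f p=%.2f b=%.2f\n",
              x$d_ref, x$interval_ref, x$r_frac, x$p_frac, x$b_frac))
  cat(sprintf("  alpha %.3g/min, v_birth %.0f um^3, S duration %.0f min\n",
              x$alpha_growth, x$v_birth, x$s_duration))
  cat("  cycle edges:", length(x$transition_edges), "\n")
  invisible(x)
}

#' Scalar concentration field on the plate
#'
#' A static lattice of non-negative concentrations covering the plate,
#' sampled by bilinear interpolation at continuous positions. Fields decay
#' exponentially with `half_life` and, when `degradable_by_cells`, are
#' locally consumed by cells, which is what turns a shallow or flat field
#' into a self-generated gradient.
#'
#' @param lattice numeric matrix of concentrations (rows index x nodes,
#'   columns index y nodes); all values must be non-negative.
#' @param cell_size um per lattice node.
#' @param half_life minutes, or `Inf` for a stable field.
#' @param degradable_by_cells can cells consume this field locally?
#' @param bias_gain um of bias per unit concentration difference across the
#'   sensing distance.
#' @param origin plate coordinates (um) of lattice node `[1, 1]`.
#' @param name field label.
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(lattice, cell_size, half_life = Inf,
                         degradable_by_cells = FALSE, bias_gain = 1,
                         origin = c(0, 0), name = "attractant") {
  lattice <- as.matrix(lattice)
  if (any(lattice < 0)) stop("field concentrations must be non-negative")
  stopifnot(cell_size > 0, half_life > 0)
  structure(list(lattice = lattice, cell_size = cell_size,
                 half_life = half_life,
                 degradable_by_cells = degradable_by_cells,
                 bias_gain = bias_gain, origin = origin, name = name),
            class = "scalar_field")
}

#' Make a uniform scalar field covering a plate
#'
#' @param width,height plate size in um.
#' @param value uniform concentration.
#' @param cell_size um per lattice node.
#' @inheritParams scalar_field
#' @return a [scalar_field()].
#' @export
uniform_field <- function(width, height, value, cell_size = 10,
                          half_life = Inf, degradable_by_cells = FALSE,
                          bias_gain = 1, name = "attractant") {
  nx <- max(2L, ceiling(width / cell_size) + 1L)
  ny <- max(2L, ceiling(height / cell_size) + 1L)
  scalar_field(matrix(value, nx, ny), cell_size, half_life,
               degradable_by_cells, bias_gain, name = name)
}

#' Sample a scalar field at continuous positions
#'
#' Bilinear interpolation between the four surrounding lattice nodes;
#' positions outside the lattice are clamped to its border.
#'
#' @param field a [scalar_field()].
#' @param x,y positions in um (vectorised).
#' @return concentrations at the requested positions.
#' @export
sample_field <- function(field, x, y) {
  nx <- nrow(field$lattice); ny <- ncol(field$lattice)
  gx <- (x - field$origin[1]) / field$cell_size
  gy <- (y - field$origin[2]) / field$cell_size
  gx <- pmin(pmax(gx, 0), nx - 1)
  gy <- pmin(pmax(gy, 0), ny - 1)
  i0 <- pmin(floor(gx), nx - 2); j0 <- pmin(floor(gy), ny - 2)
  fx <- gx - i0; fy <- gy - j0
  L <- field$lattice
  idx <- function(i, j) L[cbind(i + 1L, j + 1L)]
  (1 - fx) * (1 - fy) * idx(i0, j0) +
    fx * (1 - fy) * idx(i0 + 1L, j0) +
    (1 - fx) * fy * idx(i0, j0 + 1L) +
    fx * fy * idx(i0 + 1L, j0 + 1L)
}

# ---- neighbour grid ---------------------------------------------------------

#' Bucket spatial index over cell positions
#'
#' A uniform-bucket index used for all neighbour queries (repulsion, local
#' confluence, infection spread). Radius queries return exactly the cells a
#' brute-force all-pairs scan would.
#'
#' @param x,y cell positions in um.
#' @param bucket_size bucket edge length in um.
#' @param ids integer identifiers (defaults to `seq_along(x)`).
#' @return an object of class `neighbor_grid`.
#' @export
neighbor_grid <- function(x, y, bucket_size, ids = seq_along(x)) {
  stopifnot(bucket_size > 0, length(x) == length(y))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 ids = as.integer(ids),
                 bx = as.integer(floor(x / bucket_size)),
                 by = as.integer(floor(y / bucket_size)),
                 bucket_size = bucket_size),
            class = "neighbor_grid")
}

#' All directed neighbour pairs within a radius
#'
#' @param grid a [neighbor_grid()].
#' @param radius query radius in um (must be `<=` the grid bucket size).
#' @return a `data.table` with columns `i`, `j` (positional indices into the
#'   grid's cells), `dist`; both orientations of each pair are present.
#' @export
grid_pairs <- function(grid, radius) {
  n <- length(grid$x)
  if (radius > grid$bucket_size + 1e-9)
    stop("radius exceeds grid bucket size; rebuild the grid")
  empty <- data.table::data.table(i = integer(), j = integer(),
                                  dist = numeric())
  if (n < 2) return(empty)
  cells <- data.table::data.table(idx = seq_len(n), bx = grid$bx, by = grid$by,
                                  key = c("bx", "by"))
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    q <- data.table::data.table(i = seq_len(n),
                                bx = grid$bx + offs$dx[k],
                                by = grid$by + offs$dy[k])
    m <- cells[q, on = c("bx", "by"), nomatch = 0L, allow.cartesian = TRUE]
    out[[k]] <- m[, list(i = i, j = idx)]
  }
  pr <- data.table::rbindlist(out)
  pr <- pr[pr$i != pr$j]
  if (!nrow(pr)) return(empty)
  d2 <- (grid$x[pr$i] - grid$x[pr$j])^2 + (grid$y[pr$i] - grid$y[pr$j])^2
  keep <- d2 <= radius^2
  pr <- pr[keep]
  pr$dist <- sqrt(d2[keep])
  pr
}

#' Cells within a radius of a point
#'
#' @param grid a [neighbor_grid()].
#' @param px,py query point in um.
#' @param radius query radius in um.
#' @return integer ids of cells within `radius` of the point.
#' @export
grid_query <- function(grid, px, py, radius) {
  nb <- ceiling(radius / grid$bucket_size)
  bx0 <- floor(px / grid$bucket_size); by0 <- floor(py / grid$bucket_size)
  cand <- which(grid$bx >= bx0 - nb & grid$bx <= bx0 + nb &
                grid$by >= by0 - nb & grid$by <= by0 + nb)
  d2 <- (grid$x[cand] - px)^2 + (grid$y[cand] - py)^2
  grid$ids[cand[d2 <= radius^2]]
}
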