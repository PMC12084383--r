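# Packaged cell-type parameter library.
#
# The NIH3T3-like set is calibrated, not measured: base probabilities,
# logistic midpoints and steepnesses were tuned once so that a standard
# 10%-serum culture shows a ~24 h mean age at mitosis, a mostly-G1 phase
# composition with a minor G0 pool, serum step-down to 0.5% arrests the
# population in G0, growth at 2.5% serum roughly halves cycling, and dense
# cultures at intermediate serum settle into a ~70% G0 stationary state
# independent of seeding density.

#' NIH3T3-like parameter set
#'
#' The packaged murine-fibroblast-like cell type used by all standard
#' scenarios. See the methods vignette for the calibration rationale of
#' every group of constants.
#'
#' @param ... overrides passed to [cell_type_params()].
#' @return a [cell_type_params()].
#' @export
nih3t3_like_params <- function(...) {
  v_commit <- 1480                # G1 volume checkpoint midpoint, um^3
  edges <- list(
    # commitment: volume checkpoint + serum signalling + contact inhibition
    transition_edge("G1", "G1c", 0.55, factors = list(
      factor_spec("volume", v_commit, 0.02, "enhancing"),
      factor_spec("serum_level", 1.5, 1.5, "enhancing"),
      factor_spec("local_confluence", 0.70, 12, "limiting"))),
    # quiescence entry: serum-sensing and crowding-sensing routes
    transition_edge("G1", "G0", 0.0924, factors = list(
      factor_spec("serum_level", 0, 0.2, "limiting"))),
    transition_edge("G1", "G0", 0.08, factors = list(
      factor_spec("serum_level", 1.0, 2.5, "limiting"))),
    transition_edge("G1", "G0", 0.08, factors = list(
      factor_spec("local_confluence", 0.70, 8, "enhancing"))),
    # re-entry into the cycle once serum is back, space available and the
    # quiescent cell has regained size
    transition_edge("G0", "G1c", 0.12, factors = list(
      factor_spec("serum_level", 2.0, 1.6, "enhancing"),
      factor_spec("local_confluence", 0.75, 8, "limiting"),
      factor_spec("volume", 975, 0.007, "enhancing"))),
    transition_edge("G1c", "S", 0.6),     # gated by rfdDNA
    transition_edge("S", "G2", 0.9),      # gated by complete duplication
    transition_edge("G2", "M", 0.12, factors = list(
      factor_spec("serum_level", 0.8, 2, "enhancing"))),
    transition_edge("M", "DIVIDE", 0.4),
    # apoptosis: small baseline plus starvation- and crowding-driven routes
    transition_edge("G1", "APO", 0.0008),
    transition_edge("G0", "APO", 0.002, factors = list(
      factor_spec("serum_level", 1.2, 2.5, "limiting"))),
    transition_edge("G0", "APO", 0.008, factors = list(
      factor_spec("local_confluence", 0.85, 10, "enhancing"))))
  defaults <- list(
    name = "nih3t3_like",
    d_ref = 12, r_frac = 0.65, p_frac = 0.35, b_frac = 0,
    bias_angle = 0, interval_ref = 20,
    alpha_growth = 4.62e-4,
    phase_growth_mult = c(G1 = 1, G1c = 1, S = 1, G2 = 1, M = 0,
                          G0 = 0.25, APO = 0, DAMAGED = 0.3, DEAD = 0),
    serum_growth = factor_spec("serum_level", 1.4, 1.6, "enhancing"),
    v_birth = 1000, s_duration = 360, spread_gain = 12,
    transition_edges = edges,
    phase_motility = c(G1 = 1, G1c = 1, S = 1, G2 = 1, M = 0.3,
                       G0 = 0.4, APO = 0.2, DAMAGED = 0.3, DEAD = 0),
    attach_motility = c(DETACHED = 0.05, ATTACHED = 0.3, SPREADING = 0.7,
                        SPREAD = 1, DESPREADING = 0.7),
    confluence_motility = factor_spec("local_confluence", 0.85, 4,
                                      "limiting"),
    drug_sensitivity = list(
      antibiotic = list(rate = 5e-4, resistance_gene = "antibiotic_res")))
  over <- list(...)
  defaults[names(over)] <- over    # wholesale replacement, never a merge
  do.call(cell_type_params, defaults)
}

#' VeroE6-like parameter set
#'
#' An epithelial-like type used by the lytic-infection scenario: same cycle
#' machinery as the NIH3T3-like set with slower, less persistent movement.
#'
#' @param ... overrides passed to [cell_type_params()].
#' @return a [cell_type_params()].
#' @export
vero_e6_like_params <- function(...) {
  nih3t3_like_params(name = "vero_e6_like", d_ref = 6,
                     r_frac = 0.75, p_frac = 0.25, b_frac = 0, ...)
}

#' Look up a packaged cell type by name
#'
#' @param name `"nih3t3_like"` or `"vero_e6_like"`.
#' @return a [cell_type_params()].
#' @export
cell_type_library <- function(name) {
  switch(name,
         nih3t3_like = nih3t3_like_params(),
         vero_e6_like = vero_e6_like_params(),
         stop("unknown cell type '", name,
              "'; packaged types: nih3t3_like, vero_e6_like"))
}
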