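---
title: "Models and methods behind culturesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind culturesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

culturesim simulates populations of individual cell agents growing attached
to a flat 2-D culture surface and provides the movement-statistics suite
used to compare simulated populations with tracked experimental ones. This
vignette is the package's own account of the models, the parameters that
matter, the calibration and numerical choices, and what the simulations do
and do not capture about real cultures.

## Cell cycle as a Markov chain

Cycle progression is a discrete-time Markov chain over the states
`G1 -> G1c -> S -> G2 -> M -> division`, with the quiescent state `G0`
reachable from G1 and returning into `G1c`, plus apoptosis (`APO`), physical
damage (`DAMAGED`) and the absorbing `DEAD` state. `G1c` is the committed
late-G1 sub-state: a cell that has passed the G1 checkpoint but not yet
begun replication.

Each transition edge carries a base probability defined over a reference
time (20 min by default). Two primitives shape every draw:

* **Interval adaptation.** A probability `p` over reference time `T` becomes
  `1 - (1 - p)^(dt/T)` for a step of length `dt`. Survival probabilities
  multiply exactly across sub-steps, so the chain gives consistent dynamics
  for any update interval from a few minutes to a few hours. The engine
  default is 20 min.
* **Logistic factor effects.** Internal or external quantities (serum level,
  cell volume, local confluence, vitality, drug levels, gene presence)
  modulate an edge through `eff = 1 / (1 + exp(k (X - X_ref)))`, which is
  0.5 at `X_ref` and saturates at 0/1. A positive steepness makes the factor
  limiting; an enhancing factor simply negates the steepness. Effects
  multiply the base probability. The multiplicative combiner is a design
  choice: it keeps the result in `[0, 1]` and lets any single factor veto a
  transition; "or"-type regulation (e.g. quiescence driven by starvation
  *or* crowding) is expressed as parallel edges between the same states
  rather than by a different combiner.

Hard gates sit on top of the probabilities: S entry requires the genome to
be flagged ready for duplication (set when the cell commits at `G1c`), and
G2 entry requires complete duplication. DNA progress advances
deterministically at `1/s_duration` per minute while in S — the gates are
named by the biology, their kinetics are the package's choice. At most one
transition is drawn per cell per step; with the default interval and
calibrated probabilities the neglected double-jump mass is well under 1%.

## Growth, size control and division

Volume grows exponentially, `V(t + dt) = V e^(alpha dt)`, with `alpha` the
product of a cell-type rate, a phase multiplier (M does not grow, G0 grows
at a quarter rate), a per-cell lognormal growth modifier (sd 0.1 on the log
scale, drawn once per cell — this produces the between-cell variability of
volume/age curves), and a logistic serum multiplier.

Size control emerges from a volume checkpoint on G1 commitment (logistic
midpoint `v_commit = 1480` um^3): small daughters wait in G1 until they have
regrown. A consequence worth knowing when calibrating: the steady-state
cycle length is set almost entirely by `alpha` (the time needed to double
volume), because the checkpoint self-adjusts — moving `v_commit` shifts
birth volumes, not the cycle length. The packaged NIH3T3-like rate
`alpha = 4.62e-4`/min yields a ~24 h mean age at mitosis once the minor G0
detours of a 10%-serum culture are accounted for.

Division splits the parent volume between two G1 daughters (Gaussian
asymmetry, sd 5%), places them one cell radius apart in a random direction,
resets age, DNA and polarity, and re-enters them into the spreading process.
Quiescent cells must regain size before waking (a volume factor on the
`G0 -> G1c` edge); without it, repeated wake-divide rounds at low volume let
lineages shrink without bound in dense cultures.

## Attachment and projected surface

A second Markov chain tracks substratum interaction:
`DETACHED -> ATTACHED -> SPREADING -> SPREAD`, with mitosis and apoptosis
forcing `DESPREADING`. Spreading advances a spread fraction linearly (fully
spread in 2 h by default); de-spreading runs it back to a mitotic minimum
(0.2). The projected surface combines volume and spreading:

    surface = c * V^(2/3) * (1 + (s_max - 1) * spread_fraction)

a sphere-like footprint when detached and up to `s_max`-fold larger when
fully spread. The law's shape is the package's invention (only the
qualitative behaviour — steep early rise from spreading, then
volume-tracking, rapid drop at mitosis — is constrained by observation).
The packaged `s_max = 12` makes a spread fibroblast of ~1100 um^3 occupy
~1500 um^2, a realistic footprint that also sets the carrying capacity of
dense cultures (below).

Attachment states feed back on behaviour: detached cells barely move and a
detached cell's movement coefficient is ~0; the attachment state also enters
the movement coefficient `k` (below).

## The three-component motion model

Each interval, a cell's displacement is the vector sum of three components:

* a **random** vector — the resultant of a ten-step random walk with
  uniform directions, whose step length is calibrated so the *mean*
  resultant length equals the requested module. The exact calibration
  constant for ten steps, `E|R|/step = 2.82033`, was computed by quadrature
  of the Kluyver integral and confirmed by Monte Carlo (4e8 draws); the
  asymptotic `sqrt(10 pi)/2 = 2.8025` is 0.6% low, enough to bias an
  8.7 um module by ~0.05 um;
* a **persistence** vector along the cell's previous displacement (zero on
  the first step of a path);
* a **bias** vector along a configured angle or assembled from the
  environment.

In the extended model the modules are shares of the maximum potential
displacement `d_tot = k * d_ref`, where `d_ref` is the cell type's maximum
under optimal conditions and `k` multiplies phase (quiescent and apoptotic
cells move slower), attachment state, vitality, and a logistic confluence
effect. Extra bias vectors — cell-cell repulsion (linear falloff
`sens * d_ref * (1 - d/R)`, pointing away from each neighbour within `R`)
and one per attractant field (finite-difference gradient over the sensing
distance, scaled by the field's gain and capped at `d_ref`) — are summed
with the global bias; the resulting bias share `b' = |bias|/d_tot` replaces
the configured one and the random and persistence shares are rescaled so
`r' + p' + b' = 1`. Displacements are truncated at plate borders and
blocking constraints (stop-at-wall, no reflection); persistence follows the
realised, post-constraint displacement.

## Estimating components from tracks

The analysis inverts the generator from observed displacements `d_t` with
unit vectors `u_t`. Writing `m = E[u]` (the observable mean unit vector),
the model implies

    E[d]            = b_vec + p m
    E[d_t . u_t-1]  = p + b_vec . m

a linear system in the persistence module `p` and bias vector `b_vec`. The
naive estimator "bias = mean displacement" is biased upward under mixed
movement because persistence aligns with the bias; solving the system
removes that coupling. The random module is the mean length of the residual
`d_t - p u_t-1 - b_vec`, matching the generator's mean-resultant
calibration, so generated populations round-trip: 50 cells x 72 frames at
(8.7, 0, 0) um return the random module within sampling error (~0.06 um),
and mixed populations at persistence = bias = 4 um recover both within
~0.15 um. Degenerate inputs (all displacements identical) collapse to pure
bias by convention.

MSD curves average squared displacements over all cells and all start
frames (overlapping windows), recording pair counts that weight the
nonlinear fits: the anomalous-diffusion law `MSD = k t^alpha` (log-log
start, Levenberg-Marquardt refinement) and the Fürth persistence law
`MSD = 2 S^2 P [t - P(1 - e^(-t/P))]` whose small-lag limit is ballistic
and large-lag limit diffusive; a persistence time pinned at its box bound
is flagged rather than reported as converged. Linearity (net over path
length, averaged per cell), coherence (length of the summed net vector over
summed lengths) and the circular dispersion coefficient R (mean resultant
of unit direction vectors) complete the summary. Windowed component
contributions project each component vector onto the realised displacement
directions; the three contributions sum exactly to the mean displacement
module of the window.

## Fields, self-generated gradients and events

Attractant fields are static lattices (10 um nodes, bilinear sampling, no
diffusion — decay and cell-driven consumption are the only dynamics).
Fields decay exponentially by half-life; degradable fields lose
`rate * dt` at every node within the sensing radius of each healthy cell.
Dense regions therefore dig deeper pits — the self-generated gradient
mechanism that lets cells respond to shallow or flat fields. Damaged and
apoptotic cells do not consume attractant; allowing corpses in a scratch
wound to keep feeding on the field would erase the very gradient that
attracts the front.

Scheduled events cover the perturbations of routine culture work: medium
changes, drug addition, gradient installation, constraint addition/removal,
scratch wounds (cells in the band become fully DAMAGED — giving them the
documented chance to recover or die — and a short-lived "debris" attractant
is deposited in the band), transfection (each live cell independently
acquires a gene at the stated efficiency) and lytic viral infection (a
timer, 9 h by default; on expiry the cell lyses and neighbours within the
infection radius are infected with a stated probability, producing the
wave-like growth of a plaque). An `update` event kind is accepted as a
scheduled no-op marker. The wound scenario combines a flat, long-lived,
degradable "serum" attractant with the transient debris field: consumption
under the intact layer plus the undisturbed band produces an edge gradient
that recruits the front, which is why the windowed bias contribution is
strongest for front cells and fades for middle and inner subpopulations
(`wound_bias_profile()` groups at 0–60/60–150/>150 um from the edge; the
middle band is chosen so that the advancing front reaches it within the
run, keeping all three groups' estimates away from zero-noise ties).

## The engine

Each interval: due events fire; the neighbour bucket grid is rebuilt and
local confluence computed (sum of neighbour surfaces within 60 um over the
disc area, clamped to 1); all cells step through cycle, vitality/damage/
infection, reporters, attachment and motion against the *previous*
interval's grid and fields (synchronous update); fields decay and are
consumed; divisions flagged during the step are resolved; dead cells are
removed with their paths closed. The run returns History (per-time-point
counts and means), Paths (origin/destiny bookkeeping: start/newborn and
split/dead/lost) and Frames (per-interval cell states), exportable as CSV
or as the plain-text track format.

Randomness comes from R's global RNG seeded once per run; every stochastic
operation is drawn vectorised over the whole population in a fixed order
within the step, so runs are bit-identical for a fixed seed. (Per-cell
counter-based RNG substreams would decouple the draws from population
ordering entirely, but R offers no cheap substream mechanism and the
engine's fixed vectorised order achieves the same reproducibility
guarantee.) Scenario configs seed their own layout jitter, so a scenario
object is fully determined by its name and seed.

Reporter kinetics (cdt1, p27) are linear synthesis/decay per phase,
integrated exactly; rates are free parameters set so the quiescent p27
steady state is ~40-fold above the cycling one and cdt1 is degraded in S —
reproducing the standard read-out where cycling cells sit at low p27 and
starved cells accumulate both markers.

## Calibration of the packaged NIH3T3-like set

The cell-type library is calibrated, not measured. Targets (population
behaviour under standard conditions) and the frozen outcome:

* mean age at mitosis ~24 h in a 3-day, 100-cell, 10%-serum run
  (measured 23.8–24.1 h across seeds);
* >1600 live cells after 5 days from 100 (measured ~2200–2400);
* day-3 quiescent fraction ~20% at 10% serum and ~52% at 2.5% (measured
  12–17% and 47–50%);
* G1 occupancy (including the committed sub-state) above 50% with S around
  20% in exponential growth;
* arrest at 79% or more of cells in G0 after step-down to 0.5% FBS
  (measured 84–87% at the plateau);
* a stationary state at 5% serum with ~70% G0 and final counts independent
  of seeding density (measured 73–76% and CV ~2–7% across seedings of
  1/4/10/50 cells per 0.58 mm^2).

The serum dependence is split across routes: a flat serum-limiting
quiescence route active at all serum levels, a steep starvation route that
only engages below ~2% serum, and a crowding route; re-entry requires
serum, free space and regained size. This separation is what lets the three
serum regimes (10%, 2.5%, 0.5%) be tuned almost independently.

Motion defaults (`d_ref` 12 um per 20 min, r/p/b = 0.65/0.35/0) describe an
unbiased fibroblast-like walker; the validation populations for the
estimator use the plain generator directly (8.7 um random module, the
published operating point of the three-component analysis).

## Problem sizes and runtime

The shipped tests and the acceptance script use desk-scale sizes chosen to
finish in minutes: 3–5 day growth runs of 100 starting cells, four 16-day
stationary runs on a 0.58 mm^2 field, a 30-h wound on a 0.54 mm^2 field
(~330 cells) and 50-cell x 72-frame track sets. Populations up to a few
thousand cells simulate at roughly 20–100 ms per interval on one core; cost
is dominated by the neighbour joins, which scale near-linearly at constant
density.

## What passing tests do and do not show

The synthetic populations emulate: exponential growth with realistic phase
composition, serum- and density-dependent quiescence, starvation arrest and
rescue, spreading kinetics, the three-component movement statistics, wound
closure driven by repulsion plus self-generated gradients, drug selection
and plaque formation. They do not emulate: 3-D geometry or matrix
interactions, deformable cell shapes (cells are points with volume and
surface scalars), diffusing attractants (static lattices with decay and
consumption only), sub-cellular signalling beyond two reporter proteins, or
mixed co-cultures (one cell type per experiment; within-type heterogeneity
arises from growth modifiers, acquired genes and local environment).
Passing the packaged checks therefore demonstrates internal consistency
with the calibrated population-level behaviour, not predictive accuracy for
any particular laboratory cell line.

## Known limitations and degenerate inputs

* Transition probabilities are capped so the per-step exit mass of a state
  never exceeds 1; with extreme parameter sets this truncates rather than
  warns.
* Coincident cells repel in a uniformly random direction (documented
  tie-break).
* The persistence fit is unidentifiable on purely diffusive data; the `P`
  bound flag should be checked before interpreting the estimate.
* Track files use the package's own documented dialect; the historical
  tracking tools' binary formats are not parsed.
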