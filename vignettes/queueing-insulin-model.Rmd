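---
title: "A queueing-network model of the adipocyte insulin response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A queueing-network model of the adipocyte insulin response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qsignal)
```

## The model

`qsignal` simulates cellular signalling as a network of interconnected
queues. Each molecular species is a store of indistinguishable molecules —
a non-negative integer count — and each reaction moves molecules between
stores with a probability set by its kinetic rate. This is a discrete-time,
fixed-increment alternative to both deterministic ODE models (which average
away cell-intrinsic fluctuations) and exact event-driven simulation
(Gillespie SSA, which becomes expensive at the 10^5-molecule abundances of
the GLUT4 system; SSA is deliberately *not* the default here and is out of
scope).

At every step of length `dt` (default 1 ms) each reaction's instantaneous
rate is evaluated from the current counts:

* Michaelis-Menten: `v = coef · gate · (kcat · E) · S / (Km + S)`, with `E`
  the enzyme queue (or a plain `vmax` without one);
* mass action: `v = coef · gate · k · Π S_i` over the substrate counts.

The rate is converted to a per-molecule transfer probability
`p = min(v·dt/S_lim, p_max)` on the limiting substrate count `S_lim`, and
the number of transferred molecules is drawn `Binomial(S_lim, p)`
(zeroth-order synthesis draws Poisson). Binomial thinning is
distributionally equivalent to per-molecule Bernoulli trials but tractable
at large counts. Keeping `p_max = 0.99 < 1` guarantees probabilities stay
below one at any user-selected increment; if the clamp ever activates, the
run warns rather than aborts, since a coarser increment is a legitimate
(if biased) choice.

Two properties are enforced structurally rather than checked after the
fact. First, reactions fire in the declared configuration order within a
step, each capped by the remaining counts, so no count can go negative even
when reactions compete for one substrate (the order is part of the packaged
config). Second, conserved pools — the three GLUT4 pools, GAPDH free+busy,
Rheb free+sequestered, and the mTORC1 states — only ever exchange members,
so group totals are invariant to the single molecule over arbitrarily long
runs; the test suite asserts this exactly over more than 10^6 cell-steps.

### The pathway

The packaged network (29 species, 30 reactions) follows the canonical
insulin cascade: insulin activates its receptor; active receptor activates
the relay through IRS1/3 and PI3K that converts PIP2 to PIP3; PIP3 recruits
PDK1 — with a constitutive mTORC2 contribution, modelled as a single
co-activating rate since no mTORC2 kinetics are established — to activate
Akt; Akt acting through AS160 drives GLUT4 out of the reserve and vesicle
pools to the membrane. Membrane GLUT4 adds a facilitated glucose influx
route sized so that the fully stimulated membrane pool carries 30 times the
GLUT4-free basal route. A compact glycolysis fragment (hexokinase, a lumped
upper-glycolysis step, GAPDH binding/turnover of G3P, a glycogen buffer)
makes GAPDH occupancy — the fraction of GAPDH engaged with substrate — an
emergent quantity when desired.

mTORC1 sits on top of this fragment: free GAPDH sequesters Rheb
(`rheb_sequestration`, gated by the free-GAPDH fraction), busy GAPDH
releases it, and free Rheb activates mTORC1. How Rheb activates mTORC1 is
mechanistically unresolved, so the coupling is deliberately phenomenological:
mTORC1-dependent GLUT4 mobilization is gated by
`a = (1 − inhibition) · g(φ)` with `g` the identity by default (the engine
exposes the power family `g(φ) = φ^γ`; γ is a config parameter). Active
mTORC1 phosphorylates S6K, and active S6K accelerates IRS1/3 degradation —
the negative-feedback loop that lowers insulin sensitivity. IRS1/3 turnover
is balanced by a zeroth-order synthesis term so the unstimulated model has
a genuine steady state.

### GLUT4 pools and the calibration anchors

GLUT4 is split into reserve, vesicle and membrane-proximal pools so that
the three anchor statements are simultaneously representable: ~18,200
molecules near the membrane without insulin, ~195,000 under full
stimulation, and the stimulated pool being ~50% of the total — which forces
`total_glut4 = 390,000`. The basal exchange constants are solved exactly
from the basal pool ratios; the two stimulated-branch kcats were solved
from the deterministic steady-state balance at the stimulated target
(195,000 / 97,500 / 97,500) given the cascade's realized Akt drive, then
frozen in the config. The literature reports the mobilized quantity
variously as "in vesicles" and "proximate to the membrane"; this package
consistently reads the reported endpoint as the membrane-proximal pool.

Where the sources give no abundances, order-of-magnitude adipocyte values
were chosen once (receptor ~2×10^4, Akt ~5×10^4, GAPDH ~10^5, PIP2 ~2×10^5
molecules/cell) and not revisited; the config loader also accepts molar
concentrations and converts through a cell-volume parameter (default 1 pL).

## The cell ensemble

An experiment simulates 50 independent cells (configurable). Each cell
draws its initial abundances from a Gaussian with SD equal to 10% of the
declared value, rounded and truncated at zero — the noise emulates
cell-to-cell variability in protein expression. Kinetic constants are *not*
perturbed: the noise model covers abundance heterogeneity only, which is
the stated source of variability, and per-cell kinetic heterogeneity would
be unidentifiable from the endpoints used here. For conserved groups the
noise is applied to the group total and to the split among pools, with the
integer rounding remainder assigned to the largest pool, so each cell's
group invariant holds exactly from the first step.

Each cell's RNG stream is seeded arithmetically from the root seed and the
cell (and chunk) index, so ensembles are reproducible and independent of
execution order. Ensembles therefore satisfy: identical seeds give
bit-identical results, and summary statistics are invariant to cell
permutation.

What the passing tests do *not* show about real adipocytes: the noise
model has no extrinsic temporal fluctuations, no parameter heterogeneity,
no cell-to-cell communication, and the boundary conditions (extracellular
glucose, insulin level, the glycogen buffer) are held fixed rather than
governed by whole-body physiology.

## Occupancy: clamped versus emergent

For calibration and the sweep experiments GAPDH availability is a clamped
boundary condition: the stated fraction of each cell's GAPDH total is held
in the busy pool at every step (re-imposed after the reactions fire, so
recorded states honour it exactly up to integer rounding). This mirrors the
calibration protocol, which fixes "available GAPDH" exogenously at
{0, 20, 50, 100}%. The remaining machinery — Rheb exchange, mTORC1, S6K —
responds dynamically; at steady state the free-Rheb fraction equals the
clamped occupancy, which is why the identity default for `g` is natural.

With the clamp off (`gapdh_availability = NA`), occupancy emerges from
glycolytic flux, and `scenario_demo()` contrasts the fed state (insulin on,
glucose high: occupancy and mTORC1 activity rise, membrane GLUT4 climbs)
with prolonged fasting (no insulin, low glucose, glycogenolysis maintaining
basal G6P: occupancy low, mTORC1 near-inactive, GLUT4 basal). With the
packaged constants the GAPDH release step bounds emergent occupancy to
moderate values (well below 1 even at maximal flux), so the extreme
occupancies of the clamped protocol are indeed unrealistic cell states —
the demos are about ordering, not absolute levels.

## Steady states and endpoints

The sources report endpoint levels without a stopping rule, so the package
defines one: a run is steady when the windowed mean of the readout
(membrane GLUT4 by default) changes by less than 1% between consecutive
2.5 s windows; adaptive runs extend in 5 s chunks until steady (cap 60 s).
The *endpoint* is the mean over the final window. The basal configuration
starts at its own steady state by construction; stimulated runs typically
become steady within ~10 s of simulated time. All headline runs use 1 ms
steps and 50 cells; the ODE-limit validation uses 1000 replicate cells of a
single-reaction toy at dt = 0.2 ms, where the O(dt) mean bias of the
forward thinning scheme sits well inside the Monte-Carlo band of 3
standard errors.

## The deterministic oracle

`ode_reference()` integrates the network's rate laws with deSolve (lsoda by
default, classical RK4 on request), building the derivative from the *same*
reaction and gate objects the stochastic engine executes — the oracle and
the engine cannot drift apart through transcription. It serves three roles:
validation of the engine's large-count limit, fast deterministic fitness
evaluation for GA tests, and the steady-state solves used to fix the
calibrated kcats.

## The genetic algorithm

`calibrate()` evolves chromosomes of positive linear coefficients, one per
tunable reaction, scaling that reaction's probability of occurrence. The
population holds 10 chromosomes; each epoch the two best are kept verbatim
(elitism) and offspring are produced by uniform crossover of the two elites
followed by log-normal multiplicative mutation (positivity is preserved by
construction). Fitness is evaluated under a fixed seed so selection
compares like with like; elites carry their evaluated fitness, making the
best-so-far trajectory non-decreasing by construction.

The default fitness runs one 50-cell ensemble per availability level in
{0, 0.5, 1} — three simulations per chromosome, with the 20% level held out
for validation — and scores each cell on its *own* scale (endpoint membrane
GLUT4 divided by that cell's conserved total, since every cell draws its
own total): `n_max` cells within a ±5%-of-range band of the maximal
mobilization target (half the pool) at availability 1, `n_min` within the
band of the basal fraction at availability 0, and `d_mid` the distance of
the availability-0.5 count of max-reaching cells from the midpoint of the
corresponding counts at 0 and 1. The scalarization `n_max + n_min − d_mid`
is monotone in each stated criterion; the exact combination and the GA
hyperparameters are not prescribed by the sources, so all are exposed in
`ga_config()`. Because the packaged kinetic constants already incorporate
the calibration, the shipped chromosome is the identity scaling; GA
*behaviour* (elitism monotonicity, parameter recovery within 20% on a
branching toy with a grid-known optimum) is exercised on deterministic toy
fitnesses where the truth is known.

## Numerical choices, in one place

* `p_max = 0.99`; clamp activation warns, never aborts.
* Transfer draws: binomial on the limiting substrate; multi-substrate
  mass-action rates use plain count products.
* Competing reactions: declared order, sequential capping.
* Occupancy clamp: `busy = round(φ · total)`, re-imposed after reactions.
* Noise: `round(max(0, N(mean, 0.1·mean)))`; conserved groups renormalized
  with remainder-to-largest-pool.
* Seeds: `(root·48271 + cell·9349 + chunk·6007) mod (2^31 − 19)`.
* Steady rule: 1% relative change of 2.5 s windowed means.
* ODE oracle: lsoda, with the clamped GAPDH pools treated as boundary
  (zero-derivative) species.

## Limitations

The model omits pathways that intersect Akt signalling elsewhere, treats
mTORC2 as constitutive, fixes extracellular conditions, and inherits the
identifiability limits of endpoint-only calibration: distinct kinetic
parameterisations can reproduce the same GLUT4 endpoints. Emergent
occupancy saturates below 1 under the packaged glycolysis constants, so
full Scenario-I extremes are only reachable through the clamp. The
fixed-increment scheme carries an O(dt) mean bias relative to the
continuous-time limit — negligible at 1 ms for the packaged rates, but
worth re-checking (the warning helps) if rates are rescaled substantially.
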